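allowed_consequences <- c("missense", "nonsense", "frameshift", "indel",
                          "splice_site")

#' Flag germline candidate variants against the stringent call filters
#'
#' A variant passes when all of the following hold: population allele
#' frequency below the rarity cutoff (default < 1%), depth >= 10, >= 4
#' alternate reads, VAF >= 40%, consequence among missense / nonsense /
#' frameshift / indel / splice site (synonymous never passes), not in a
#' repetitive genomic region, not matching a somatic call in the same
#' patient, and ACMG class not benign / likely benign.
#'
#' @param variants Germline variant data.frame (dialect `germline_variants`).
#' @param config An [iei_config()] list.
#' @return `variants` with a logical `passed_filters` column added. Pure
#'   flagging: no rows are dropped.
#' @export
filter_candidates <- function(variants, config = iei_config()) {
  variants$passed_filters <-
    variants$population_af < config$rarity_max_af &
    variants$depth >= config$min_depth &
    variants$alt_reads >= config$min_alt_reads &
    variants$vaf >= config$min_germline_vaf &
    variants$consequence %in% allowed_consequences &
    !variants$in_repetitive_region &
    !variants$matches_somatic_call &
    !variants$acmg %in% c("B", "LB")
  variants
}

#' Screen filtered variants for cohort overrepresentation
#'
#' Groups passing variants by identity `(gene, hgvs)` and tests each
#' observed allele count against its expected population frequency with a
#' one-sided upper-tail test (binomial by default; Poisson approximation via
#' config): `trials = 2 * cohort_n`, `p` = population allele frequency
#' (frequencies of exactly 0 are floored at
#' `1 / (2 * reference_cohort_size)`). Benjamini-Hochberg correction is
#' applied over the VUS family only — P/LP variants are selected
#' unconditionally and do not enter the family. A VUS is selected iff its
#' q-value is at most `fdr_alpha`.
#'
#' @param variants Output of [filter_candidates()].
#' @param cohort_n Number of genotyped patients.
#' @param config An [iei_config()] list.
#' @return A list with `variants` (input rows plus `overrep_p`, `overrep_q`,
#'   `selected`) and `by_variant` (one row per distinct tested variant with
#'   `observed_alleles`, `overrep_p`, `overrep_q`, `selected`).
#' @export
overrepresentation_screen <- function(variants, cohort_n,
                                      config = iei_config()) {
  stopifnot(cohort_n > 0)
  key <- paste(variants$patient_id, variants$gene, variants$hgvs, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (patient, variant) rows in germline table", call. = FALSE)
  }
  passed <- variants[variants$passed_filters, , drop = FALSE]
  vkey <- paste(passed$gene, passed$hgvs, sep = "\r")
  alleles <- ifelse(passed$zygosity == "hom", 2L, 1L)
  obs <- tapply(alleles, vkey, sum)
  first <- passed[!duplicated(vkey), , drop = FALSE]
  first <- first[match(names(obs), paste(first$gene, first$hgvs, sep = "\r")), ]

  af <- first$population_af
  af[af == 0] <- 1 / (2 * config$reference_cohort_size)
  tail_fun <- if (config$overrep_test == "poisson") poisson_upper_tail else
    binomial_upper_tail
  p <- tail_fun(as.integer(obs), 2L * as.integer(cohort_n), af)

  by_variant <- data.frame(gene = first$gene, hgvs = first$hgvs,
                           acmg = first$acmg, population_af = first$population_af,
                           observed_alleles = as.integer(obs),
                           overrep_p = as.numeric(p),
                           overrep_q = NA_real_, stringsAsFactors = FALSE)
  is_vus <- by_variant$acmg == "VUS"
  adj <- bh_adjust(by_variant$overrep_p[is_vus], config$fdr_alpha)
  by_variant$overrep_q[is_vus] <- adj$q
  by_variant$selected <- by_variant$acmg %in% c("P", "LP") |
    (is_vus & !is.na(by_variant$overrep_q) &
       by_variant$overrep_q <= config$fdr_alpha)

  idx <- match(paste(variants$gene, variants$hgvs, sep = "\r"),
               paste(by_variant$gene, by_variant$hgvs, sep = "\r"))
  variants$overrep_p <- by_variant$overrep_p[idx]
  variants$overrep_q <- by_variant$overrep_q[idx]
  variants$selected <- variants$passed_filters &
    !is.na(idx) & by_variant$selected[idx]
  list(variants = variants, by_variant = by_variant)
}

#' Classify one patient as a high-confidence deleterious (hcD) carrier
#'
#' The hcD rules, evaluated over a patient's selected variants against the
#' IEI panel inheritance annotation, in precedence order:
#' * **a** — any P/LP variant;
#' * **b** — any heterozygous VUS in a dominant-trait gene (`AD` or
#'   `AD_AR`);
#' * **c** — any homozygous selected variant in a recessive gene (`AR` or
#'   `XL`; hemizygous X-linked calls in males are expected to be coded
#'   `hom`), or >= 2 distinct heterozygous selected variants in the same
#'   recessive gene (presumed compound heterozygote — calls are unphased).
#'
#' @param patient_variants Selected variant rows of a single patient
#'   (columns `gene`, `hgvs`, `acmg`, `zygosity`).
#' @param panel IEI panel data.frame (dialect `iei_panel`).
#' @return List with `is_hcd` (logical) and `rule` (`"a"`, `"b"`, `"c"`, or
#'   `NA` when no rule fires; rule `"c"` from unphased het pairs is tagged
#'   `"c_presumed"`).
#' @export
classify_hcd <- function(patient_variants, panel) {
  if (nrow(patient_variants) == 0L) return(list(is_hcd = FALSE, rule = NA_character_))
  inh <- panel$inheritance[match(patient_variants$gene, panel$gene)]
  if (anyNA(inh)) {
    stop("gene(s) absent from IEI panel: ",
         paste(unique(patient_variants$gene[is.na(inh)]), collapse = ", "),
         call. = FALSE)
  }
  dominant <- inh %in% c("AD", "AD_AR")
  recessive <- inh %in% c("AR", "XL")
  if (any(patient_variants$acmg %in% c("P", "LP"))) {
    return(list(is_hcd = TRUE, rule = "a"))
  }
  if (any(patient_variants$acmg == "VUS" &
          patient_variants$zygosity == "het" & dominant)) {
    return(list(is_hcd = TRUE, rule = "b"))
  }
  if (any(patient_variants$zygosity == "hom" & recessive)) {
    return(list(is_hcd = TRUE, rule = "c"))
  }
  het_rec <- patient_variants[patient_variants$zygosity == "het" & recessive, ,
                              drop = FALSE]
  if (nrow(het_rec)) {
    per_gene <- table(unique(het_rec[, c("gene", "hgvs")])$gene)
    if (any(per_gene >= 2L)) return(list(is_hcd = TRUE, rule = "c_presumed"))
  }
  list(is_hcd = FALSE, rule = NA_character_)
}

#' Run the full germline triage over a cohort
#'
#' Applies [filter_candidates()], [overrepresentation_screen()] and
#' [classify_hcd()] and aggregates per-patient carrier status.
#'
#' @param variants Germline variant table.
#' @param panel IEI panel table.
#' @param cohort_n Number of genotyped patients (may exceed the number of
#'   patients with candidate variants).
#' @param config An [iei_config()] list.
#' @return List with `variants` (flagged rows), `by_variant`, and
#'   `per_patient` (one row per patient appearing in `variants`:
#'   `selected_variant_count`, `is_carrier`, `is_hcd_carrier`, `hcd_rule`),
#'   plus `cohort_n`.
#' @export
triage_cohort <- function(variants, panel, cohort_n, config = iei_config()) {
  flagged <- filter_candidates(variants, config)
  screened <- overrepresentation_screen(flagged, cohort_n, config)
  v <- screened$variants
  pts <- unique(v$patient_id)
  per_patient <- do.call(rbind, lapply(pts, function(pid) {
    sel <- v[v$patient_id == pid & v$selected, , drop = FALSE]
    hcd <- classify_hcd(sel, panel)
    data.frame(patient_id = pid, selected_variant_count = nrow(sel),
               is_carrier = nrow(sel) > 0L, is_hcd_carrier = hcd$is_hcd,
               hcd_rule = hcd$rule, stringsAsFactors = FALSE)
  }))
  list(variants = v, by_variant = screened$by_variant,
       per_patient = per_patient, cohort_n = as.integer(cohort_n))
}

#' Cohort burden statistics with control comparison
#'
#' Reports the individual burden distribution among carriers (median and
#' range of selected variants per carrier), the combined burden (carriers /
#' cohort size), the hcD carrier frequency, the simplified expected carrier
#' probability (sum of the population allele frequencies of the selected
#' variants), and a Pearson chi-square comparison of carrier counts against
#' a control population.
#'
#' @param triage Output of [triage_cohort()].
#' @param control_carriers,control_n Carrier count and size of the control
#'   population.
#' @return List of named statistics; percentages carry numerator and
#'   denominator so they recompute exactly.
#' @export
burden_statistics <- function(triage, control_carriers, control_n) {
  stopifnot(control_n > 0)
  pp <- triage$per_patient
  carriers <- sum(pp$is_carrier)
  if (carriers > triage$cohort_n) {
    stop("more carriers than cohort size", call. = FALSE)
  }
  counts <- pp$selected_variant_count[pp$is_carrier]
  sel <- triage$by_variant[triage$by_variant$selected, , drop = FALSE]
  cmp_tab <- rbind(c(carriers, triage$cohort_n - carriers),
                   c(control_carriers, control_n - control_carriers))
  comparison <- if (carriers == 0 && control_carriers == 0) {
    list(statistic = 0, df = 1, p_value = 1)
  } else {
    chi_square_test(cmp_tab)
  }
  list(
    cohort_n = triage$cohort_n,
    carriers = carriers,
    combined_burden = carriers / triage$cohort_n,
    combined_burden_pct = percent_of(carriers, triage$cohort_n),
    median_variants_in_carriers = if (length(counts)) stats::median(counts) else NA_real_,
    range_variants_in_carriers = if (length(counts)) range(counts) else c(NA_real_, NA_real_),
    hcd_carriers = sum(pp$is_hcd_carrier),
    hcd_rate = sum(pp$is_hcd_carrier) / triage$cohort_n,
    hcd_rate_pct = percent_of(sum(pp$is_hcd_carrier), triage$cohort_n),
    n_selected_variants = nrow(sel),
    n_selected_genes = length(unique(sel$gene)),
    expected_probability = sum(sel$population_af),
    control_carriers = control_carriers,
    control_n = control_n,
    control_burden_pct = percent_of(control_carriers, control_n, digits = 2),
    comparison = comparison
  )
}
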