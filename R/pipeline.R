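# Deterministic demonstration cohort and end-to-end orchestration.

#' Deterministic demonstration cohort
#'
#' Builds, entirely in code, a small T-LGLL-like cohort whose headline
#' summary statistics take the documented values used throughout the
#' package examples and tests: a 241-patient clinical cohort (201 with Ig
#' levels, 64 hypogammaglobulinemic of whom 39 have an acquired-cause
#' history; 186 with the lymphocytopenia/hypogammaglobulinemia composite), a
#' 92-patient exome subcohort carrying 43 selected rare IEI variants in 38
#' genes across 34 carriers (median 1, range 1-3 per carrier; 15 hcD
#' carriers), a control population of 63,026 with 167 carriers, a somatic
#' driver landscape of 91 P/LP variants in 30 genes across 62 patients (42
#' STAT3-mutant, 45 with non-STAT3 drivers; among hcD carriers 4 STAT3 /
#' 9 non-STAT3 / 1 coexistent), and a repertoire whose pathologically
#' expanded clonotypes include 227 reference-matched specificities, 185 of
#' them infection-directed.
#'
#' All tallies emerge from running the pipeline operations on these tables;
#' nothing downstream is hard-coded.
#'
#' @return A named list of input tables: `clinical` (`labs`, `history`),
#'   `germline` (`variants`, `panel`, `cohort_n`), `control` (`carriers`,
#'   `n`), `somatic` (`variants`, `patients`), `repertoire` (`clonotypes`,
#'   `reference`).
#' @export
demo_cohort <- function() {
  cfg <- iei_config()

  ## ---- clinical: 241 patients, 201 with Ig levels -----------------------
  n <- 241L
  pid <- sprintf("C%03d", seq_len(n))
  mid <- function(a) mean(cfg$normal_ranges[[a]])
  labs <- data.frame(patient_id = pid, stringsAsFactors = FALSE)
  # hypogamma patients 1..64: IgG-low 1..29, IgA-low 33..64, IgM-low 1..36
  igg <- rep(mid("IgG"), n); iga <- rep(mid("IgA"), n); igm <- rep(mid("IgM"), n)
  igg[1:29] <- cfg$normal_ranges$IgG[1] - 50
  iga[33:64] <- cfg$normal_ranges$IgA[1] - 10
  igm[1:36] <- cfg$normal_ranges$IgM[1] - 10
  igg[202:241] <- NA; iga[202:241] <- NA; igm[202:241] <- NA  # no Ig data
  labs$igg <- igg; labs$iga <- iga; labs$igm <- igm
  # ALC: lymphocytopenic for the 40 Ig-missing patients and for 82 of the
  # non-hypogamma Ig-measured patients, so the composite resolves for all 241
  alc <- rep(2.0, n)
  alc[202:241] <- 0.6
  alc[65:146] <- 0.6
  labs$alc <- alc
  history <- data.frame(patient_id = pid,
                        prior_hematolymphoid_neoplasm = FALSE,
                        anti_b_cell_therapy = FALSE,
                        other_immunosuppression = FALSE, chemo = FALSE,
                        good_syndrome_or_cvid_like = FALSE, transplant = FALSE,
                        family_history_immune_or_hematolymphoid = FALSE,
                        stringsAsFactors = FALSE)
  history$anti_b_cell_therapy[1:39] <- TRUE  # acquired-cause candidates

  ## ---- germline: 92 exomes, 43 selected variants, 34 carriers ----------
  gpid <- sprintf("P%03d", 1:92)
  genes <- sprintf("IEIG%02d", 1:38)
  # carriers P001..P034; hcD: P001-P003 (LP, rule a), P004-P015 (het VUS in
  # dominant genes, rule b); P016-P034 carry het VUS in recessive genes only
  slot <- c(1:27, rep(28:32, each = 2), rep(33:34, each = 3))  # 43 slots
  vgene <- c(genes[1:38], genes[16:20])                        # 5 genes twice
  # reorder the duplicated alleles so no patient holds 2 variants of 1 gene
  vgene[38:43] <- c(genes[38], genes[16], genes[17], genes[18], genes[19],
                    genes[20])
  acmg <- c(rep("LP", 3), rep("VUS", 40))
  gvar <- data.frame(
    patient_id = gpid[slot],
    gene = vgene,
    hgvs = paste0("c.", 100 + seq_len(43), "A>G"),
    consequence = "missense", population_af = 1e-5,
    acmg = acmg, zygosity = "het", vaf = 0.5, depth = 80L, alt_reads = 40L,
    in_repetitive_region = FALSE, matches_somatic_call = FALSE,
    stringsAsFactors = FALSE)
  panel <- data.frame(
    gene = genes,
    iuis_category = rep(c("combined_TB", "immune_dysregulation", "BMF",
                          "phagocyte", "B_cell", "innate"),
                        length.out = 38),
    inheritance = ifelse(seq_len(38) %in% 4:15, "AD", "AR"),
    onset = "adult",
    dysregulation_vs_deficiency = "dysregulation", stringsAsFactors = FALSE)

  ## ---- somatic: 91 P/LP driver variants, 62 mutated of 92 --------------
  other_genes <- c("STAT5B", "STAT6", "KMT2C", "KMT2D", "KDM6A", "KMT5C",
                   "TET2", "DNMT3A", "CREBBP", "DDX3X", "TP53", "CSMD3",
                   "POT1", "NOTCH1", "NRAS", "STAG2", "CACNA1E", "SEPTIN4",
                   "CHD2", "LRP1B", "TTN", "PCLO", "VCAN", "XIRP2", "UBA1",
                   "KRAS", "KDR", "TNFAIP3", "NEB")
  config_of <- c(rep("stat3_only", 3), "coexistence", rep("other_only", 8),
                 rep("none", 3),                       # P001-P015 (hcD)
                 rep("stat3_only", 14), rep("coexistence", 24),
                 rep("other_only", 12), rep("none", 27))  # P016-P092
  stat3_pts <- gpid[config_of %in% c("stat3_only", "coexistence")]
  other_pts <- gpid[config_of %in% c("other_only", "coexistence")]
  # 45 patients with non-STAT3 drivers; the first 4 carry two each -> 49
  other_rows <- c(other_pts, other_pts[1:4])
  somatic <- data.frame(
    patient_id = c(stat3_pts, other_rows),
    gene = c(rep("STAT3", length(stat3_pts)),
             rep(other_genes, length.out = length(other_rows))),
    consequence = "missense", pathogenicity = "P",
    vaf = 0.25, stringsAsFactors = FALSE)

  ## ---- repertoire: 227 matched expanded specificities, 185 infection ---
  cats <- c(rep("infection", 185), rep("autoimmunity", 22),
            rep("tumor_surveillance", 20))
  matched_cdr3 <- sprintf("CASSDEMO%04dF", seq_len(227))
  reference <- data.frame(cdr3_aa = matched_cdr3, condition_category = cats,
                          condition_label = paste0("cond_", seq_len(227)),
                          stringsAsFactors = FALSE)
  clonotypes <- data.frame(
    sample_id = "S1",
    cdr3_aa = c(matched_cdr3, sprintf("CASSNOHIT%04dF", seq_len(773)),
                sprintf("CASSSMALL%04dF", seq_len(500))),
    templates = c(rep(12L, 227), rep(8L, 773), rep(1L, 500)),
    in_frame = TRUE, has_stop = FALSE, stringsAsFactors = FALSE)

  list(
    clinical = list(labs = labs, history = history),
    germline = list(variants = gvar, panel = panel, cohort_n = 92L),
    control = list(carriers = 167L, n = 63026L),
    somatic = list(variants = somatic, patients = gpid),
    repertoire = list(clonotypes = clonotypes, reference = reference)
  )
}

#' Run the cohort pipeline end to end
#'
#' Executes, for whichever sections of `cohort` are present: clinical
#' phenotyping (flags, acquired-cause screen, tallies), germline triage
#' (filters, overrepresentation screen, hcD classification, burden
#' statistics with control comparison), the somatic driver landscape, and
#' repertoire specificity annotation. Stages run in dependency order;
#' partial inputs produce a partial summary. Deterministic given the
#' config: rerunning yields an identical summary.
#'
#' @param cohort A list shaped like [demo_cohort()].
#' @param config An [iei_config()] list.
#' @return A list with per-stage results (`phenotypes`, `triage`, `burden`,
#'   `somatic`, `specificity`) and `summary`, a cohort summary data.frame
#'   (see [summarize_pipeline()]).
#' @export
run_pipeline <- function(cohort, config = iei_config()) {
  out <- list()
  if (!is.null(cohort$clinical)) {
    ph <- classify_labs(cohort$clinical$labs, config)
    ph <- screen_hypogamma_cause(ph, cohort$clinical$history)
    out$phenotypes <- ph
    out$phenotype_summary <- summarize_cohort_phenotypes(ph)
  }
  if (!is.null(cohort$germline)) {
    out$triage <- triage_cohort(cohort$germline$variants,
                                cohort$germline$panel,
                                cohort$germline$cohort_n, config)
    if (!is.null(cohort$control)) {
      out$burden <- burden_statistics(out$triage, cohort$control$carriers,
                                      cohort$control$n)
    }
  }
  if (!is.null(cohort$somatic)) {
    kept <- filter_driver_mutations(cohort$somatic$variants,
                                    unique(cohort$somatic$variants$gene))
    out$somatic <- summarize_somatic(kept, cohort$somatic$patients)
  }
  if (!is.null(cohort$repertoire)) {
    out$specificity <- annotate_specificities(
      cohort$repertoire$clonotypes, cohort$repertoire$reference,
      scope = "pathological_only")
  }
  out$summary <- summarize_pipeline(out)
  out
}

summary_row <- function(statistic, numerator = NA, denominator = NA,
                        value = NA, p_value = NA) {
  pct <- if (!is.na(numerator) && !is.na(denominator) && denominator > 0) {
    percent_of(numerator, denominator)
  } else NA_real_
  if (is.na(value) && !is.na(numerator) && !is.na(denominator) &&
      denominator > 0) {
    value <- numerator / denominator
  }
  data.frame(statistic = statistic, numerator = as.integer(numerator),
             denominator = as.integer(denominator), value = value,
             percent = pct, p_value = p_value, stringsAsFactors = FALSE)
}

#' Assemble the cohort summary table
#'
#' Every percentage row stores its numerator and denominator so the printed
#' integer percent (half-up) recomputes exactly from the stored counts.
#'
#' @param results Per-stage results list as built by [run_pipeline()].
#' @return Data.frame with columns `statistic`, `numerator`, `denominator`,
#'   `value`, `percent`, `p_value`.
#' @export
summarize_pipeline <- function(results) {
  rows <- list()
  add <- function(r) rows[[length(rows) + 1L]] <<- r
  ps <- results$phenotype_summary
  if (!is.null(ps)) {
    for (stat in c("immune_defect", "hypogamma_any", "lymphocytopenia",
                   "low_or_normal_alc", "low_iga", "low_igg", "low_igm",
                   "hypogamma_acquired_candidate", "hypogamma_unexplained")) {
      r <- ps[ps$statistic == stat, ]
      if (nrow(r)) add(summary_row(stat, r$numerator, r$denominator))
    }
  }
  b <- results$burden
  if (!is.null(b)) {
    add(summary_row("combined_burden", b$carriers, b$cohort_n,
                    p_value = b$comparison$p_value))
    add(summary_row("control_burden", b$control_carriers, b$control_n))
    add(summary_row("hcd_rate", b$hcd_carriers, b$cohort_n))
    add(summary_row("median_variants_in_carriers",
                    value = b$median_variants_in_carriers))
    add(summary_row("expected_probability", value = b$expected_probability))
    add(summary_row("n_selected_variants", value = b$n_selected_variants))
    add(summary_row("n_selected_genes", value = b$n_selected_genes))
  }
  s <- results$somatic
  if (!is.null(s)) {
    add(summary_row("driver_mutated", s$mutated, s$n))
    add(summary_row("stat3_mt", s$stat3_mt, s$n))
    add(summary_row("other_driver_mt", s$other_mt, s$n))
    add(summary_row("mean_driver_burden", value = s$mean_burden))
  }
  sp <- results$specificity
  if (!is.null(sp)) {
    add(summary_row("expanded_specificity_matched", sp$n_matched,
                    sp$n_in_scope))
    inf <- as.integer(sp$category_counts["infection"])
    if (!is.na(inf)) {
      add(summary_row("expanded_specificity_infection", inf, sp$n_matched))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
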