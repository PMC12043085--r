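# Synthetic cohort generator: every pipeline input can be produced with
# controlled, documented statistical structure, so each downstream stage is
# testable against planted truth without any external data.

random_cdr3 <- function(n, len_range = c(10L, 18L)) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) {
    len <- sample(seq(len_range[1], len_range[2]), 1L)
    paste0("CASS", paste(sample(aa, len - 5L, replace = TRUE), collapse = ""), "F")
  }, character(1))
}

#' Simulate a germline variant table with planted overrepresented variants
#'
#' Each variant `v` with population allele frequency `af_v` and cohort
#' enrichment factor `e_v` appears in a patient (heterozygous) with
#' probability `2 * af_v * e_v`; null variants use `e_v = 1`. Depth is
#' negative binomial (mean 80, size 5) and heterozygous VAF is Beta(20, 20),
#' so the stringent call filters pass most but not all rows, as in real
#' exome data. Truth labels record which variants were planted.
#'
#' @param n_patients Cohort size (default 92, a WES subcohort scale).
#' @param planted Data.frame of planted variants: `gene`, `population_af`,
#'   `enrichment` (>= 1), `acmg`, `inheritance`. Default: 5 VUS at
#'   MAF 1e-3 with enrichment 50 in dominant-trait genes.
#' @param n_null Number of unenriched null VUS (default 40).
#' @param null_af Population allele frequency of null variants
#'   (default 5e-3, rare but common enough to be observed).
#' @param seed Integer seed.
#' @return List with `variants` (dialect `germline_variants`), `panel`
#'   (dialect `iei_panel`) and `truth` (per-variant planted flag).
#' @export
simulate_germline <- function(n_patients = 92L,
                              planted = NULL,
                              n_null = 40L,
                              null_af = 5e-3,
                              seed = 1L) {
  set.seed(seed)
  if (is.null(planted)) {
    planted <- data.frame(
      gene = paste0("IEIP", 1:5), population_af = 1e-3, enrichment = 50,
      acmg = "VUS", inheritance = "AD", stringsAsFactors = FALSE)
  }
  nulls <- if (n_null > 0) data.frame(
    gene = paste0("IEIN", seq_len(n_null)), population_af = null_af,
    enrichment = 1, acmg = "VUS", inheritance = "AR",
    stringsAsFactors = FALSE) else NULL
  all_v <- rbind(planted, nulls)
  empty_variants <- data.frame(
    patient_id = character(0), gene = character(0), hgvs = character(0),
    consequence = character(0), population_af = numeric(0),
    acmg = character(0), zygosity = character(0), vaf = numeric(0),
    depth = integer(0), alt_reads = integer(0),
    in_repetitive_region = logical(0), matches_somatic_call = logical(0),
    planted = logical(0), stringsAsFactors = FALSE)
  if (nrow(all_v) == 0L) {
    return(list(variants = empty_variants,
                panel = data.frame(gene = character(0)),
                truth = data.frame(gene = character(0), hgvs = character(0),
                                   planted = logical(0))))
  }
  all_v$hgvs <- paste0("c.", 100 + seq_len(nrow(all_v)), "A>G")
  prob <- 2 * all_v$population_af * all_v$enrichment
  if (any(prob > 1)) stop("carrier probability cap exceeded: 2*af*enrichment > 1",
                          call. = FALSE)
  rows <- list()
  for (i in seq_len(nrow(all_v))) {
    carriers <- which(stats::runif(n_patients) < prob[i])
    if (!length(carriers)) next
    k <- length(carriers)
    depth <- stats::rnbinom(k, mu = 80, size = 5) + 1L
    vaf <- stats::rbeta(k, 20, 20)
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = sprintf("P%03d", carriers),
      gene = all_v$gene[i], hgvs = all_v$hgvs[i],
      consequence = "missense", population_af = all_v$population_af[i],
      acmg = all_v$acmg[i], zygosity = "het", vaf = vaf,
      depth = depth, alt_reads = stats::rbinom(k, depth, vaf),
      in_repetitive_region = FALSE, matches_somatic_call = FALSE,
      planted = all_v$enrichment[i] > 1, stringsAsFactors = FALSE)
  }
  variants <- if (length(rows)) do.call(rbind, rows) else empty_variants
  panel <- data.frame(
    gene = all_v$gene,
    iuis_category = "immune_dysregulation",
    inheritance = all_v$inheritance,
    onset = "adult", dysregulation_vs_deficiency = "dysregulation",
    stringsAsFactors = FALSE)
  truth <- all_v[, c("gene", "hgvs", "population_af", "enrichment")]
  truth$planted <- truth$enrichment > 1
  list(variants = variants, panel = panel, truth = truth)
}

#' Simulate a TCR repertoire with planted hyperexpanded clones
#'
#' Clone sizes follow a discrete power law (Zipf, probability proportional
#' to `k^-exponent` over 1..`max_size`), matching the heavy-tailed clone
#' size distributions of real repertoires. Planted hyperexpanded clones get
#' stated template counts (> 10). A fraction of clones copy their CDR3 from
#' a generated specificity reference with the stated category mix.
#'
#' @param n_clonotypes Number of clonotypes (default 10000).
#' @param exponent Power-law exponent (default 2.5).
#' @param max_size Clone size support upper bound (default 1000).
#' @param planted_hyperexpanded Integer vector of planted clone sizes, each
#'   > 10 (default none).
#' @param n_reference Reference clonotype count (default 2000).
#' @param reference_match_fraction Fraction of repertoire clonotypes whose
#'   CDR3 is copied from the reference (default 0.04).
#' @param category_mix Named numeric mix of condition categories among
#'   reference entries (default infection-dominated).
#' @param seed Integer seed.
#' @return List with `repertoire` (dialect `repertoire`), `reference`
#'   (dialect `specificity_reference`) and `truth` (planted/matched flags).
#' @export
simulate_repertoire <- function(n_clonotypes = 10000L,
                                exponent = 2.5,
                                max_size = 1000L,
                                planted_hyperexpanded = integer(0),
                                n_reference = 2000L,
                                reference_match_fraction = 0.04,
                                category_mix = c(infection = 0.7,
                                                 autoimmunity = 0.15,
                                                 tumor_surveillance = 0.15),
                                seed = 1L) {
  set.seed(seed)
  if (length(planted_hyperexpanded) && any(planted_hyperexpanded <= 10L)) {
    stop("planted hyperexpanded clones must have > 10 templates", call. = FALSE)
  }
  sizes <- sample(seq_len(max_size), n_clonotypes, replace = TRUE,
                  prob = seq_len(max_size)^(-exponent))
  cdr3 <- random_cdr3(n_clonotypes + length(planted_hyperexpanded))
  categories <- sample(names(category_mix), n_reference, replace = TRUE,
                       prob = category_mix)
  reference <- data.frame(
    cdr3_aa = random_cdr3(n_reference),
    condition_category = categories,
    condition_label = paste0("condition_", seq_len(n_reference)),
    stringsAsFactors = FALSE)
  n_match <- round(reference_match_fraction * n_clonotypes)
  matched_idx <- if (n_match > 0) sample.int(n_clonotypes, n_match) else integer(0)
  cdr3[matched_idx] <- sample(reference$cdr3_aa, n_match, replace = FALSE)
  all_sizes <- c(sizes, as.integer(planted_hyperexpanded))
  n_total <- length(all_sizes)
  repertoire <- data.frame(
    sample_id = "S1",
    cdr3_aa = cdr3[seq_len(n_total)],
    v_gene = NA_character_, j_gene = NA_character_,
    templates = all_sizes,
    in_frame = TRUE, has_stop = FALSE, stringsAsFactors = FALSE)
  truth <- data.frame(
    cdr3_aa = repertoire$cdr3_aa,
    planted_hyperexpanded = c(rep(FALSE, n_clonotypes),
                              rep(TRUE, length(planted_hyperexpanded))),
    reference_matched = seq_len(n_total) %in% matched_idx,
    stringsAsFactors = FALSE)
  list(repertoire = repertoire, reference = reference, truth = truth)
}

#' Simulate a cells x genes expression matrix with a planted set-gene shift
#'
#' Gene values are Normal(`baseline`, `noise_sd`); cells of the designated
#' groups receive an additive shift `delta` on the set genes. Cell
#' annotations carry clone ids and template counts marking hyperexpanded
#' clones.
#'
#' @param n_cells_per_group Named integer vector of cells per group
#'   (default 200 each of STAT3mt, STAT3wt, healthy_control).
#' @param n_genes Number of genes (default 500).
#' @param set_genes Genes carrying the shift (default the first 15 genes,
#'   named `SETG1..`).
#' @param delta Additive shift on set genes (default 1) applied to
#'   `shifted_groups`.
#' @param shifted_groups Groups receiving the shift (default `"STAT3mt"`).
#' @param baseline,noise_sd Normal parameters (defaults 0 and 1).
#' @param seed Integer seed.
#' @return List with `matrix` (cells x genes), `annotation` (dialect
#'   `cell_annotation`) and `set_genes`.
#' @export
simulate_expression <- function(n_cells_per_group = c(STAT3mt = 200L,
                                                      STAT3wt = 200L,
                                                      healthy_control = 200L),
                                n_genes = 500L,
                                set_genes = NULL,
                                delta = 1,
                                shifted_groups = "STAT3mt",
                                baseline = 0, noise_sd = 1,
                                seed = 1L) {
  set.seed(seed)
  genes <- paste0("G", seq_len(n_genes))
  if (is.null(set_genes)) {
    set_genes <- paste0("SETG", 1:15)
    genes[1:15] <- set_genes
  }
  groups <- rep(names(n_cells_per_group), n_cells_per_group)
  n_cells <- length(groups)
  mat <- matrix(stats::rnorm(n_cells * n_genes, baseline, noise_sd),
                nrow = n_cells, dimnames = list(
                  paste0("cell", seq_len(n_cells)), genes))
  shifted <- groups %in% shifted_groups
  mat[shifted, set_genes] <- mat[shifted, set_genes] + delta
  annotation <- data.frame(
    cell_id = rownames(mat),
    clone_id = paste0("clone_", as.integer(factor(groups))),
    clone_templates = 20L,
    group = groups, stringsAsFactors = FALSE)
  list(matrix = mat, annotation = annotation, set_genes = set_genes)
}

#' Simulate clinical laboratory tables around the configured normal ranges
#'
#' Each analyte is lognormal, parameterized so that a stated fraction of
#' patients falls below the lower normal bound:
#' `meanlog = log(low) - qnorm(frac_low) * sdlog`. History flags are
#' independent Bernoulli draws.
#'
#' @param n_patients Cohort size (default 241, a clinical cohort scale).
#' @param frac_low Named fractions below the lower bound per analyte
#'   (defaults roughly matching a T-LGLL presentation mix).
#' @param sdlog Lognormal sd on the log scale (default 0.45).
#' @param history_rates Named Bernoulli rates for the acquired-cause flags.
#' @param config An [iei_config()] list (normal ranges).
#' @param seed Integer seed.
#' @return List with `labs` (dialect `clinical`) and `history` tables.
#' @export
simulate_clinical <- function(n_patients = 241L,
                              frac_low = c(CD3 = 0.10, CD4 = 0.35, CD8 = 0.10,
                                           NK = 0.58, B = 0.44, IgG = 0.14,
                                           IgA = 0.16, IgM = 0.18),
                              sdlog = 0.45,
                              history_rates = c(prior_hematolymphoid_neoplasm = 0.15,
                                                anti_b_cell_therapy = 0.10,
                                                other_immunosuppression = 0.15,
                                                chemo = 0.10,
                                                good_syndrome_or_cvid_like = 0.05,
                                                transplant = 0.03),
                              config = iei_config(),
                              seed = 1L) {
  set.seed(seed)
  labs <- data.frame(patient_id = sprintf("P%03d", seq_len(n_patients)),
                     stringsAsFactors = FALSE)
  labs$alc <- stats::rlnorm(n_patients, meanlog = log(1.8), sdlog = 0.5)
  labs$lgl_count <- stats::rlnorm(n_patients, meanlog = log(0.8), sdlog = 0.6)
  for (analyte in names(frac_low)) {
    low <- config$normal_ranges[[analyte]][1]
    meanlog <- log(low) - stats::qnorm(frac_low[[analyte]]) * sdlog
    labs[[tolower(analyte)]] <- stats::rlnorm(n_patients, meanlog, sdlog)
  }
  history <- data.frame(patient_id = labs$patient_id, stringsAsFactors = FALSE)
  for (flag in names(history_rates)) {
    history[[flag]] <- stats::runif(n_patients) < history_rates[[flag]]
  }
  history$family_history_immune_or_hematolymphoid <-
    stats::runif(n_patients) < 0.1
  list(labs = labs, history = history)
}
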