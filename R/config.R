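#' Run configuration for the T-LGLL immunogenomic pipeline
#'
#' Collects every tunable threshold used across the pipeline stages in one
#' validated list, mirroring the structure of a YAML run configuration.
#'
#' Defaults encode the analysis constants of the study design: rare variants
#' are those with population minor allele frequency below 1%; germline calls
#' require depth >= 10, >= 4 alternate reads and VAF >= 40%; the VUS
#' overrepresentation screen is corrected by Benjamini-Hochberg at FDR 0.05;
#' TCR repertoires are downsampled to 5,420 templates; expression-score
#' high/low calls use the 90th percentile.
#'
#' @param rarity_max_af Maximum population allele frequency for a variant to
#'   count as rare (fraction, default 0.01).
#' @param min_depth Minimum sequencing depth for a germline call (default 10).
#' @param min_alt_reads Minimum reads supporting the alternate allele
#'   (default 4).
#' @param min_germline_vaf Minimum variant allele fraction for a germline call
#'   (default 0.40).
#' @param fdr_alpha FDR level for the Benjamini-Hochberg corrected
#'   overrepresentation screen (default 0.05).
#' @param downsample_templates Fixed repertoire depth used to normalize TCR
#'   samples (templates, default 5420).
#' @param score_percentile Quantile defining "high" expression-score calls
#'   (default 0.90).
#' @param lymphopenia_alc Lower normal bound for the absolute lymphocyte count
#'   in 1e9 cells/L; counts below it flag lymphocytopenia (default 1.0).
#' @param low_normal_alc_max Upper bound of the "low/normal" ALC band in 1e9
#'   cells/L (default 4.0).
#' @param cn_gain_log2,cn_loss_log2 Weighted mean segment log2 thresholds for
#'   gene-level copy-number gain / loss calls (defaults +0.3 / -0.3).
#' @param blacklist_overlap_frac Fraction of a gene's length that must overlap
#'   a blacklist interval for the gene call to be excluded (default 0.5).
#' @param reference_cohort_size Size of the reference population used to floor
#'   a population allele frequency of exactly zero at
#'   `1 / (2 * reference_cohort_size)` (default 63026).
#' @param overrep_test `"binomial"` (exact upper tail, default) or `"poisson"`
#'   (approximation) for the observed-versus-expected frequency screen.
#' @param seeds Named list of integer seeds, one per stochastic stage.
#' @param normal_ranges Named list of `c(low, high)` laboratory normal ranges.
#'   Defaults are the clinical ranges the pipeline reports against:
#'   lymphocyte subsets in 1e9 cells/L (CD3 0.96-2.39, CD4 0.53-1.67,
#'   CD8 0.28-0.96, NK 0.10-0.57, B 0.08-0.66) and immunoglobulins in mg/dL
#'   (IgG 717-1411, IgA 78-391, IgM 53-334).
#' @param gene_sets Named list of gene-symbol vectors used for expression
#'   scoring. The shipped 15-gene TCR signalosome set and 9-gene STAT3
#'   activation set are editable reconstructions assembled from genes of the
#'   TCR complex/signalosome and canonical STAT3 target genes; they are not a
#'   published list and should be replaced with study-specific sets when
#'   available.
#'
#' @return A validated list of class `"iei_config"`.
#' @examples
#' cfg <- iei_config()
#' cfg$downsample_templates
#' @export
iei_config <- function(rarity_max_af = 0.01,
                       min_depth = 10L,
                       min_alt_reads = 4L,
                       min_germline_vaf = 0.40,
                       fdr_alpha = 0.05,
                       downsample_templates = 5420L,
                       score_percentile = 0.90,
                       lymphopenia_alc = 1.0,
                       low_normal_alc_max = 4.0,
                       cn_gain_log2 = 0.3,
                       cn_loss_log2 = -0.3,
                       blacklist_overlap_frac = 0.5,
                       reference_cohort_size = 63026L,
                       overrep_test = c("binomial", "poisson"),
                       seeds = list(),
                       normal_ranges = NULL,
                       gene_sets = NULL) {
  overrep_test <- match.arg(overrep_test)
  if (is.null(normal_ranges)) normal_ranges <- default_normal_ranges()
  if (is.null(gene_sets)) gene_sets <- default_gene_sets()

  cfg <- list(
    rarity_max_af = rarity_max_af,
    min_depth = as.integer(min_depth),
    min_alt_reads = as.integer(min_alt_reads),
    min_germline_vaf = min_germline_vaf,
    fdr_alpha = fdr_alpha,
    downsample_templates = as.integer(downsample_templates),
    score_percentile = score_percentile,
    lymphopenia_alc = lymphopenia_alc,
    low_normal_alc_max = low_normal_alc_max,
    cn_gain_log2 = cn_gain_log2,
    cn_loss_log2 = cn_loss_log2,
    blacklist_overlap_frac = blacklist_overlap_frac,
    reference_cohort_size = as.integer(reference_cohort_size),
    overrep_test = overrep_test,
    seeds = seeds,
    normal_ranges = normal_ranges,
    gene_sets = gene_sets
  )
  validate_config(cfg)
  class(cfg) <- "iei_config"
  cfg
}

validate_config <- function(cfg) {
  frac_fields <- c("rarity_max_af", "min_germline_vaf", "fdr_alpha",
                   "score_percentile", "blacklist_overlap_frac")
  for (f in frac_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("config field '", f, "' must be a single fraction in [0, 1]",
           call. = FALSE)
    }
  }
  if (cfg$downsample_templates <= 0L) {
    stop("downsample_templates must be positive", call. = FALSE)
  }
  for (nm in names(cfg$normal_ranges)) {
    r <- cfg$normal_ranges[[nm]]
    if (length(r) != 2L || !is.numeric(r) || any(is.na(r)) || r[1] >= r[2]) {
      stop("normal range for '", nm, "' must be c(low, high) with low < high",
           call. = FALSE)
    }
  }
  invisible(cfg)
}

#' @rdname iei_config
#' @export
default_normal_ranges <- function() {
  list(
    CD3 = c(0.96, 2.39),
    CD4 = c(0.53, 1.67),
    CD8 = c(0.28, 0.96),
    NK  = c(0.10, 0.57),
    B   = c(0.08, 0.66),
    IgG = c(717, 1411),
    IgA = c(78, 391),
    IgM = c(53, 334)
  )
}

# Reconstructed defaults: TCR complex (GO:0042101) + signalosome (GO:0036398)
# members, and canonical STAT3-induced targets. Editable via iei_config().
#' @rdname iei_config
#' @export
default_gene_sets <- function() {
  list(
    tcr_score = c("TRAC", "TRDC", "CD247", "CD2", "CD3D", "CD3E", "CD3G",
                  "CD5", "CD8A", "LAT", "LCK", "ZAP70", "SYK", "FYN", "ITK"),
    stat3_score = c("SOCS3", "BCL3", "JUNB", "PIM1", "MYC", "MCL1",
                    "IER3", "OSMR", "TNFRSF1B")
  )
}

#' Read a run configuration from YAML
#'
#' The YAML file mirrors the arguments of [iei_config()]; absent keys fall
#' back to the defaults.
#'
#' @param path Path to a YAML file.
#' @return An `"iei_config"` list.
#' @export
read_iei_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$normal_ranges)) {
    raw$normal_ranges <- lapply(raw$normal_ranges, function(r) as.numeric(unlist(r)))
  }
  if (!is.null(raw$gene_sets)) {
    raw$gene_sets <- lapply(raw$gene_sets, function(g) as.character(unlist(g)))
  }
  do.call(iei_config, raw)
}

# Integer percentage with half-up rounding (base round() is banker's).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a proportion as the integer percent the pipeline reports
#'
#' Percentages are rounded half-up so that, e.g., 34/92 reports as 37.
#'
#' @param num,den Numerator and denominator counts.
#' @param digits Decimal digits to keep (default 0).
#' @return Numeric percent value.
#' @export
percent_of <- function(num, den, digits = 0) {
  round_half_up(100 * num / den, digits)
}
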