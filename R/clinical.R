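#' Classify immune-defect phenotypes from laboratory values
#'
#' Flags each analyte as low when its value falls below the lower bound of
#' the configured normal range. Works on a clinical table with one row per
#' patient; analyte columns are the lower-cased range names (`cd3`, `cd4`,
#' `cd8`, `nk`, `b` in 1e9 cells/L; `igg`, `iga`, `igm` in mg/dL) plus `alc`
#' and optionally `lgl_count` (1e9 cells/L). Missing analytes yield `NA`
#' flags — absent, never implicitly normal.
#'
#' Derived calls:
#' * `lymphocytopenia`: `alc` below the configured lower bound
#'   (default 1.0 x 1e9/L; the clinical band the cohort reports).
#' * `low_or_normal_alc`: `alc <= 4.0` x 1e9/L (configurable upper bound).
#' * `hypogamma_any`: any Ig isotype below its lower bound.
#' * `immune_defect`: lymphocytopenia OR hypogammaglobulinemia (the
#'   composite; subset deficits are reported but do not enter it by default).
#'
#' @param labs Clinical data.frame (dialect `clinical`).
#' @param config An [iei_config()] list (normal ranges + ALC bounds).
#' @return A data.frame of per-patient logical flags (`NA` where the analyte
#'   was not measured): `low_<analyte>` for each range, plus the derived
#'   calls above.
#' @export
classify_labs <- function(labs, config = iei_config()) {
  stopifnot(is.data.frame(labs), nrow(labs) > 0)
  ranges <- config$normal_ranges
  num_cols <- intersect(names(labs),
                        c("alc", "lgl_count", tolower(names(ranges))))
  for (col in num_cols) {
    v <- labs[[col]]
    if (any(!is.na(v) & v < 0)) {
      stop("negative laboratory value in column '", col, "'", call. = FALSE)
    }
  }
  out <- data.frame(patient_id = labs$patient_id, stringsAsFactors = FALSE)
  for (analyte in names(ranges)) {
    col <- tolower(analyte)
    flag <- paste0("low_", col)
    out[[flag]] <- if (col %in% names(labs)) {
      labs[[col]] < ranges[[analyte]][1]
    } else {
      rep(NA, nrow(labs))
    }
  }
  ig_flags <- out[, intersect(c("low_igg", "low_iga", "low_igm"), names(out)),
                  drop = FALSE]
  out$hypogamma_any <- apply(ig_flags, 1, any_or_na)
  alc <- if ("alc" %in% names(labs)) labs$alc else rep(NA_real_, nrow(labs))
  out$lymphocytopenia <- alc < config$lymphopenia_alc
  out$low_or_normal_alc <- alc <= config$low_normal_alc_max
  out$immune_defect <- mapply(or_na, out$lymphocytopenia, out$hypogamma_any)
  out
}

# OR with three-valued logic: TRUE dominates, FALSE|NA -> NA.
or_na <- function(a, b) {
  if (isTRUE(a) || isTRUE(b)) return(TRUE)
  if (is.na(a) || is.na(b)) return(NA)
  FALSE
}

any_or_na <- function(x) {
  if (any(x %in% TRUE)) return(TRUE)
  if (all(is.na(x))) return(NA)
  if (any(is.na(x))) return(NA)
  FALSE
}

acquired_cause_flags <- c("prior_hematolymphoid_neoplasm", "anti_b_cell_therapy",
                          "other_immunosuppression", "chemo",
                          "good_syndrome_or_cvid_like", "transplant")

#' Screen hypogammaglobulinemic patients for acquired causes
#'
#' A patient with hypogammaglobulinemia is an `acquired_candidate` when any
#' acquired-cause history flag is set (prior hemato-lymphoid neoplasm,
#' anti-B cell therapy, other immunosuppression, chemotherapy, Good
#' syndrome / CVID-like condition, transplant); `unexplained` when none is;
#' `not_applicable` without hypogammaglobulinemia.
#'
#' @param phenotypes Output of [classify_labs()].
#' @param history Data.frame with `patient_id` and the logical history flags.
#' @return `phenotypes` with a `hypogamma_cause` factor column added.
#' @export
screen_hypogamma_cause <- function(phenotypes, history) {
  idx <- match(phenotypes$patient_id, history$patient_id)
  flags <- history[idx, intersect(acquired_cause_flags, names(history)),
                   drop = FALSE]
  any_flag <- apply(flags, 1, function(x) any(x %in% TRUE))
  cause <- ifelse(!phenotypes$hypogamma_any %in% TRUE, "not_applicable",
                  ifelse(any_flag, "acquired_candidate", "unexplained"))
  phenotypes$hypogamma_cause <- factor(
    cause, levels = c("acquired_candidate", "unexplained", "not_applicable"))
  phenotypes
}

#' Tally cohort immune-defect phenotypes
#'
#' Counts and proportions for every phenotype flag. Denominators include only
#' patients with the analyte measured (non-`NA` flag); percentages are
#' rounded half-up to integers for reporting, with the raw
#' numerator/denominator retained so every percentage can be recomputed.
#'
#' @param phenotypes Output of [classify_labs()] (optionally after
#'   [screen_hypogamma_cause()]).
#' @return Data.frame with columns `statistic`, `numerator`, `denominator`,
#'   `value`, `percent`.
#' @export
summarize_cohort_phenotypes <- function(phenotypes) {
  stopifnot(nrow(phenotypes) > 0)
  flag_cols <- names(phenotypes)[vapply(phenotypes, is.logical, logical(1))]
  rows <- lapply(flag_cols, function(col) {
    f <- phenotypes[[col]]
    den <- sum(!is.na(f))
    num <- sum(f, na.rm = TRUE)
    data.frame(statistic = col, numerator = num, denominator = den,
               value = if (den > 0) num / den else NA_real_,
               percent = if (den > 0) percent_of(num, den) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if ("hypogamma_cause" %in% names(phenotypes)) {
    hg <- phenotypes$hypogamma_cause[phenotypes$hypogamma_any %in% TRUE]
    den <- length(hg)
    for (lev in c("acquired_candidate", "unexplained")) {
      num <- sum(hg == lev, na.rm = TRUE)
      out <- rbind(out, data.frame(
        statistic = paste0("hypogamma_", lev), numerator = num,
        denominator = den,
        value = if (den > 0) num / den else NA_real_,
        percent = if (den > 0) percent_of(num, den) else NA_real_,
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}
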