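#' Exact binomial upper-tail probability
#'
#' `P(X >= observed)` for `X ~ Binomial(trials, p)` — the one-sided test
#' behind the observed-versus-expected allele-frequency screen, where
#' `trials` is twice the number of genotyped patients and `p` the population
#' allele frequency.
#'
#' @param observed Observed success count (allele count), `0 <= observed <=
#'   trials`.
#' @param trials Number of trials (alleles genotyped).
#' @param p Success probability per trial (population allele frequency).
#' @return The upper-tail p-value in `[0, 1]`; `observed = 0` returns exactly
#'   1.
#' @examples
#' binomial_upper_tail(2, 184, 0.001)
#' @export
binomial_upper_tail <- function(observed, trials, p) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  if (any(observed < 0 | observed > trials)) {
    stop("observed must lie in [0, trials]", call. = FALSE)
  }
  ifelse(observed == 0, 1,
         stats::pbinom(observed - 1, size = trials, prob = p,
                       lower.tail = FALSE))
}

#' Poisson upper-tail approximation to the overrepresentation test
#'
#' `P(X >= observed)` for `X ~ Poisson(trials * p)`; offered as a config
#' switch for very rare variants where the Poisson approximation is standard.
#'
#' @inheritParams binomial_upper_tail
#' @return Upper-tail p-value.
#' @export
poisson_upper_tail <- function(observed, trials, p) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  ifelse(observed == 0, 1,
         stats::ppois(observed - 1, lambda = trials * p, lower.tail = FALSE))
}

#' Benjamini-Hochberg step-up adjustment with rejection flags
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return A list with `q` (BH-adjusted q-values, input order) and `reject`
#'   (logical, `q <= alpha`). Empty input yields empty results.
#' @export
bh_adjust <- function(pvalues, alpha = 0.05) {
  if (any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (length(pvalues) == 0L) {
    return(list(q = numeric(0), reject = logical(0)))
  }
  q <- stats::p.adjust(pvalues, method = "BH")
  list(q = q, reject = q <= alpha)
}

check_contingency <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("contingency table must hold non-negative integers", call. = FALSE)
  }
  if (all(rowSums(tab) == 0)) {
    stop("contingency table needs at least one positive row total",
         call. = FALSE)
  }
  tab
}

#' Pearson chi-square test on an r x 2 contingency table
#'
#' No continuity correction by default, matching how Pearson's chi-square is
#' conventionally reported for cohort comparisons.
#'
#' @param tab An r x 2 (or 2 x 2) matrix of non-negative counts.
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return List with `statistic`, `df`, `p_value`.
#' @examples
#' chi_square_test(rbind(c(34, 58), c(167, 62859)))$p_value
#' @export
chi_square_test <- function(tab, correct = FALSE) {
  tab <- check_contingency(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-square undefined with a zero marginal; use fisher_exact_2x2()",
         call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value))
}

#' Fisher's exact test on a 2 x 2 table
#'
#' @param tab A 2 x 2 matrix of non-negative counts.
#' @param alternative Alternative hypothesis (default two-sided).
#' @return Two-sided (by default) exact p-value.
#' @export
fisher_exact_2x2 <- function(tab, alternative = "two.sided") {
  tab <- check_contingency(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("table must be 2 x 2", call. = FALSE)
  stats::fisher.test(tab, alternative = alternative)$p.value
}

#' Mann-Whitney U test (Wilcoxon rank-sum)
#'
#' @param group_a,group_b Numeric vectors of observations, non-empty.
#' @return Two-sided p-value.
#' @export
mann_whitney <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  suppressWarnings(stats::wilcox.test(group_a, group_b)$p.value)
}
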