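#' Per-cell gene-set module score with binned control genes
#'
#' For each cell, the score is the mean expression over the set genes minus
#' the mean over matched control genes. Controls are drawn per set gene:
#' genes are ranked by their dataset-wide mean expression and cut into
#' `n_bins` equal-size bins; each set gene contributes `n_ctrl` control
#' genes sampled uniformly without replacement from its own bin (the whole
#' bin if smaller). The draw is deterministic given `seed`. Because set and
#' control means shift equally, the score is invariant to adding a constant
#' to the whole matrix.
#'
#' @param mat Numeric matrix, cells in rows, genes in columns (named).
#' @param genes Character vector of set gene symbols; genes absent from the
#'   matrix are reported and dropped, but at least one must be present.
#' @param n_bins Number of average-expression bins (default 24).
#' @param n_ctrl Control genes drawn per set gene (default 100).
#' @param seed Integer seed for the control draw.
#' @return Named numeric vector of per-cell scores.
#' @export
module_score <- function(mat, genes, n_bins = 24L, n_ctrl = 100L, seed = 1L) {
  present <- intersect(genes, colnames(mat))
  if (!length(present)) {
    stop("no set gene present in matrix; missing: ",
         paste(genes, collapse = ", "), call. = FALSE)
  }
  if (length(present) < length(genes)) {
    warning("set genes absent from matrix: ",
            paste(setdiff(genes, present), collapse = ", "))
  }
  gene_means <- colMeans(mat)
  ngenes <- length(gene_means)
  n_bins <- min(n_bins, ngenes)
  # equal-size bins over the mean-expression ranking
  rk <- rank(gene_means, ties.method = "first")
  bin <- ceiling(rk / (ngenes / n_bins))
  set.seed(seed)
  ctrl <- unlist(lapply(present, function(g) {
    pool <- names(gene_means)[bin == bin[[g]]]
    if (length(pool) <= n_ctrl) pool else sample(pool, n_ctrl)
  }))
  set_mean <- rowMeans(mat[, present, drop = FALSE])
  ctrl_mean <- rowMeans(mat[, ctrl, drop = FALSE])
  out <- set_mean - ctrl_mean
  # the realized control draw is exposed so results can be audited/recomputed
  attr(out, "controls") <- ctrl
  out
}

#' Geometric-mean gene-set score for bulk expression
#'
#' `exp(mean(log(x + pseudocount)))` over the set genes, per sample.
#'
#' @param bulk Numeric matrix, samples in rows, genes in columns (named);
#'   values must be non-negative.
#' @param genes Set gene symbols (must be present in the matrix).
#' @param pseudocount Added before the log (default 0).
#' @return Named numeric vector of per-sample scores.
#' @export
geometric_mean_score <- function(bulk, genes, pseudocount = 0) {
  missing <- setdiff(genes, colnames(bulk))
  if (length(missing)) {
    stop("set genes absent from matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- bulk[, genes, drop = FALSE]
  if (any(x < 0)) stop("expression values must be non-negative", call. = FALSE)
  exp(rowMeans(log(x + pseudocount)))
}

#' Build a STAT3 activation signature by list intersection
#'
#' Intersects the genes upregulated in STAT3-mutant versus wild-type cells
#' with the union of external upregulated-gene lists (e.g. curated STAT3
#' target collections, cell-line contrasts), keeping the order of the first
#' list and deduplicating.
#'
#' @param up_in_mt Character vector: genes up in STAT3-mutant cells.
#' @param external_up_lists List of character vectors of external
#'   upregulated-gene lists.
#' @return A character vector (possibly empty, with a warning).
#' @export
build_stat3_signature <- function(up_in_mt, external_up_lists) {
  if (!length(up_in_mt) || !length(external_up_lists)) {
    stop("gene lists must be non-empty", call. = FALSE)
  }
  ext <- unique(unlist(external_up_lists))
  sig <- unique(up_in_mt[up_in_mt %in% ext])
  if (!length(sig)) warning("signature intersection is empty")
  sig
}

#' High/low calls at an empirical percentile threshold
#'
#' A cell is called high iff its score strictly exceeds the empirical
#' `pct` quantile computed over all cells pooled; scores tied with the
#' threshold are low.
#'
#' @param scores Numeric vector of per-cell scores (>= 10 cells).
#' @param pct Quantile defining the threshold (default 0.90).
#' @return Logical vector of high calls.
#' @export
percentile_threshold <- function(scores, pct = 0.90) {
  if (length(scores) < 10L) stop("need at least 10 cells", call. = FALSE)
  thr <- stats::quantile(scores, pct, names = FALSE)
  if (max(scores) == min(scores)) {
    warning("constant scores: no cell exceeds the threshold")
  }
  scores > thr
}

#' Coexpression contingency of two high-score flags across cell groups
#'
#' Per group, the proportion of cells high for score A, high for score B,
#' and double-high, each with stored numerator/denominator; an r x 2
#' Pearson chi-square across groups is computed per flag. Groups with zero
#' cells are excluded with a warning.
#'
#' @param high_a,high_b Logical per-cell flags (same length, aligned).
#' @param groups Character/factor vector of group labels per cell.
#' @return List with `per_group` (data.frame) and `p_a`, `p_b`, `p_double`
#'   (chi-square p-values; `NA` with fewer than two groups).
#' @export
coexpression_contingency <- function(high_a, high_b, groups) {
  stopifnot(length(high_a) == length(high_b),
            length(high_a) == length(groups))
  groups <- as.factor(groups)
  empty <- levels(groups)[tabulate(groups, nbins = nlevels(groups)) == 0L]
  if (length(empty)) {
    warning("excluding empty group(s): ", paste(empty, collapse = ", "))
    groups <- droplevels(groups)
  }
  per_group <- do.call(rbind, lapply(levels(groups), function(g) {
    i <- groups == g
    n <- sum(i)
    data.frame(group = g, n = n,
               a_high = sum(high_a[i]), a_high_frac = mean(high_a[i]),
               b_high = sum(high_b[i]), b_high_frac = mean(high_b[i]),
               double_high = sum(high_a[i] & high_b[i]),
               double_high_frac = mean(high_a[i] & high_b[i]),
               stringsAsFactors = FALSE)
  }))
  chi_p <- function(high) {
    if (nlevels(groups) < 2L) return(NA_real_)
    tab <- cbind(tapply(high, groups, sum),
                 tapply(!high, groups, sum))
    if (any(colSums(tab) == 0)) return(NA_real_)
    chi_square_test(tab)$p_value
  }
  list(per_group = per_group,
       p_a = chi_p(high_a), p_b = chi_p(high_b),
       p_double = chi_p(high_a & high_b),
       double_high_overall = mean(high_a & high_b))
}
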