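#' Keep only productive rearrangements
#'
#' A clonotype is productive when it is in-frame and carries no stop codon.
#'
#' @param clones Clonotype data.frame (dialect `repertoire`).
#' @return The productive rows.
#' @export
filter_productive <- function(clones) {
  clones[clones$in_frame %in% TRUE & !clones$has_stop %in% TRUE, , drop = FALSE]
}

# Clonotype identity: (cdr3_aa, v_gene, j_gene) when V/J are present,
# else the CDR3 amino-acid sequence alone.
clonotype_key <- function(clones) {
  if (all(c("v_gene", "j_gene") %in% names(clones)) &&
      !all(is.na(clones$v_gene)) && !all(is.na(clones$j_gene))) {
    paste(clones$cdr3_aa, clones$v_gene, clones$j_gene, sep = "|")
  } else {
    clones$cdr3_aa
  }
}

#' Downsample a repertoire to a fixed template depth
#'
#' Normalizes sampling depth by drawing exactly `n` templates uniformly
#' without replacement from the multiset of the repertoire's templates
#' (default 5,420, the rarefaction depth used to normalize samples).
#' Clonotypes with zero sampled templates are dropped. A repertoire with
#' fewer than `n` templates cannot be normalized and raises a classed
#' condition (`iei_insufficient_depth`) so callers can record the exclusion.
#'
#' @param clones Productive-filtered clonotype data.frame.
#' @param n Target depth (default 5420).
#' @param seed Integer seed; the draw is bit-reproducible given the seed.
#' @param unit `"templates"` (default): `n` counts sequenced templates, the
#'   standard rarefaction unit. `"clonotypes"`: `n` whole clonotype rows are
#'   drawn uniformly without replacement instead.
#' @return The downsampled data.frame; with `unit = "templates"` the updated
#'   `templates` column sums to exactly `n`.
#' @export
downsample_repertoire <- function(clones, n = 5420L, seed = 1L,
                                  unit = c("templates", "clonotypes")) {
  if (n <= 0) stop("downsampling depth must be positive", call. = FALSE)
  unit <- match.arg(unit)
  if (unit == "clonotypes") {
    if (nrow(clones) < n) {
      stop(structure(class = c("iei_insufficient_depth", "error", "condition"),
                     list(message = sprintf(
                       "insufficient depth: %d clonotypes < target %d",
                       nrow(clones), n), call = NULL)))
    }
    if (nrow(clones) == n) return(clones)
    set.seed(seed)
    return(clones[sort(sample.int(nrow(clones), n)), , drop = FALSE])
  }
  total <- sum(clones$templates)
  if (total < n) {
    stop(structure(class = c("iei_insufficient_depth", "error", "condition"),
                   list(message = sprintf(
                     "insufficient depth: %d templates < target %d", total, n),
                     call = NULL)))
  }
  if (total == n) return(clones)
  set.seed(seed)
  cum <- cumsum(as.numeric(clones$templates))
  idx <- sample.int(total, n)                 # which templates survive
  owner <- findInterval(idx - 0.5, c(0, cum)) # clonotype owning each template
  counts <- tabulate(owner, nbins = nrow(clones))
  out <- clones[counts > 0L, , drop = FALSE]
  out$templates <- counts[counts > 0L]
  out
}

#' Repertoire diversity metrics
#'
#' Unique clonotype count, inverse Simpson index `1 / sum(p_i^2)` with
#' `p_i` the template share of clonotype `i` (bounded below by 1 and above
#' by the number of clonotypes), and mean clone size (templates per unique
#' clonotype).
#'
#' @param clones Clonotype data.frame with >= 1 row.
#' @return List with `unique_clonotypes`, `inverse_simpson`,
#'   `mean_clone_size`, `total_templates`.
#' @export
diversity_metrics <- function(clones) {
  if (nrow(clones) == 0L) stop("empty repertoire", call. = FALSE)
  sizes <- tapply(clones$templates, clonotype_key(clones), sum)
  total <- sum(sizes)
  p <- sizes / total
  list(unique_clonotypes = length(sizes),
       inverse_simpson = 1 / sum(p^2),
       mean_clone_size = total / length(sizes),
       total_templates = total)
}

#' Clonal expansion classes from template counts
#'
#' Classes: nonexpanded (1 template), normally expanded (2-5),
#' pathologically expanded (> 5), hyperexpanded (> 10). Hyperexpanded is
#' nested inside pathologically expanded, so both flags are reported
#' alongside the finest class.
#'
#' @param templates Integer vector of template counts, all >= 1.
#' @return Data.frame with `class` (factor: nonexpanded / normal /
#'   pathological / hyperexpanded), `pathological` (templates > 5) and
#'   `hyperexpanded` (templates > 10).
#' @export
classify_expansion <- function(templates) {
  if (any(templates < 1L)) stop("templates must be >= 1", call. = FALSE)
  cls <- ifelse(templates > 10L, "hyperexpanded",
          ifelse(templates > 5L, "pathological",
           ifelse(templates >= 2L, "normal", "nonexpanded")))
  data.frame(
    class = factor(cls, levels = c("nonexpanded", "normal", "pathological",
                                   "hyperexpanded")),
    pathological = templates > 5L,
    hyperexpanded = templates > 10L)
}

#' Annotate clonotype specificities by exact CDR3 match
#'
#' Matches sample CDR3 amino-acid sequences against a reference of
#' condition-annotated clonotypes by exact string equality (no V/J
#' constraint). The scope is either the whole repertoire or only the
#' pathologically expanded clonotypes (> 5 templates). A clonotype matching
#' reference entries in several condition categories counts once per
#' category and is flagged ambiguous.
#'
#' @param clones Clonotype data.frame.
#' @param reference Specificity reference data.frame (dialect
#'   `specificity_reference`).
#' @param scope `"whole"` or `"pathological_only"`.
#' @return List with `matches` (clonotype x category match table),
#'   `n_in_scope`, `n_matched`, `match_fraction` (matched clonotypes over
#'   clonotypes in scope), `category_counts` and `category_fraction_of_matched`
#'   (shares of matched clonotypes per category).
#' @export
annotate_specificities <- function(clones, reference,
                                   scope = c("whole", "pathological_only")) {
  scope <- match.arg(scope)
  if (nrow(reference) == 0L) stop("reference must be non-empty", call. = FALSE)
  in_scope <- if (scope == "pathological_only") {
    clones[clones$templates > 5L, , drop = FALSE]
  } else clones
  cats <- sort(unique(reference$condition_category))
  ref_by_cat <- split(reference$cdr3_aa, reference$condition_category)
  match_rows <- lapply(seq_len(nrow(in_scope)), function(i) {
    cdr3 <- in_scope$cdr3_aa[i]
    hit <- vapply(ref_by_cat, function(x) cdr3 %in% x, logical(1))
    if (!any(hit)) return(NULL)
    data.frame(cdr3_aa = cdr3, templates = in_scope$templates[i],
               condition_category = names(ref_by_cat)[hit],
               ambiguous = sum(hit) > 1L, stringsAsFactors = FALSE)
  })
  matches <- do.call(rbind, match_rows)
  n_matched <- sum(!vapply(match_rows, is.null, logical(1)))
  category_counts <- if (is.null(matches)) {
    stats::setNames(integer(length(cats)), cats)
  } else {
    table(factor(matches$condition_category, levels = cats))
  }
  list(matches = matches,
       n_in_scope = nrow(in_scope),
       n_matched = n_matched,
       match_fraction = if (nrow(in_scope)) n_matched / nrow(in_scope) else NA_real_,
       category_counts = category_counts,
       category_fraction_of_matched = if (n_matched > 0) {
         as.numeric(category_counts) / n_matched
       } else rep(NA_real_, length(cats)))
}

#' Normalize and summarize a set of repertoires
#'
#' Productive-filters and downsamples each sample; samples below the target
#' depth are excluded (recorded, mirroring how under-sequenced repertoires
#' drop out of a normalized analysis) and diversity metrics are computed on
#' the rest.
#'
#' @param reps Named list of clonotype data.frames, one per sample.
#' @param n Downsampling depth (default 5420).
#' @param seed Base seed; sample `i` uses `seed + i`.
#' @return List with `metrics` (data.frame per retained sample) and
#'   `excluded` (character vector of sample names below depth).
#' @export
normalize_repertoires <- function(reps, n = 5420L, seed = 1L) {
  excluded <- character(0)
  rows <- list()
  for (i in seq_along(reps)) {
    nm <- names(reps)[i]
    prod <- filter_productive(reps[[i]])
    ds <- tryCatch(downsample_repertoire(prod, n = n, seed = seed + i),
                   iei_insufficient_depth = function(e) NULL)
    if (is.null(ds)) {
      excluded <- c(excluded, nm)
      next
    }
    d <- diversity_metrics(ds)
    rows[[nm]] <- data.frame(sample_id = nm,
                             unique_clonotypes = d$unique_clonotypes,
                             inverse_simpson = d$inverse_simpson,
                             mean_clone_size = d$mean_clone_size,
                             stringsAsFactors = FALSE)
  }
  metrics <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(metrics)) rownames(metrics) <- NULL
  list(metrics = metrics, excluded = excluded)
}
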