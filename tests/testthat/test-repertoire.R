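make_rep <- function(templates, cdr3 = NULL) {
  n <- length(templates)
  data.frame(sample_id = "S1",
             cdr3_aa = if (is.null(cdr3)) sprintf("CASSX%03dF", seq_len(n))
                       else cdr3,
             templates = as.integer(templates),
             in_frame = TRUE, has_stop = FALSE, stringsAsFactors = FALSE)
}

test_that("productive filtering drops out-of-frame and stop-containing reads", {
  clones <- make_rep(c(5, 3, 2, 1))
  clones$in_frame <- c(TRUE, FALSE, TRUE, TRUE)
  clones$has_stop <- c(FALSE, FALSE, TRUE, FALSE)
  prod <- filter_productive(clones)
  expect_equal(nrow(prod), 2L)
  expect_setequal(prod$templates, c(5L, 1L))
  all_ok <- make_rep(c(2, 2))
  expect_identical(filter_productive(all_ok), all_ok)
})

test_that("downsampling conserves identity and hits the target exactly", {
  # exact depth is an identity
  clones <- make_rep(c(3000, 2420))
  expect_identical(downsample_repertoire(clones, 5420, seed = 1), clones)
  # a single dominant clone is forced to exactly n templates
  one <- make_rep(10000)
  ds1 <- downsample_repertoire(one, 5420, seed = 2)
  expect_equal(ds1$templates, 5420L)
  # general case: totals exact, per-clone counts bounded by originals
  big <- make_rep(c(4000, 2500, 1500, 800, 200, rep(1, 50)))
  ds <- downsample_repertoire(big, 5420, seed = 3)
  expect_equal(sum(ds$templates), 5420L)
  expect_true(all(ds$templates <=
                    big$templates[match(ds$cdr3_aa, big$cdr3_aa)]))
  # bit-reproducible under the same seed, different under another
  expect_identical(downsample_repertoire(big, 5420, seed = 3), ds)
  expect_false(identical(downsample_repertoire(big, 5420, seed = 4), ds))
  # insufficient depth is a classed signal, not a silent truncation
  expect_error(downsample_repertoire(make_rep(c(100, 100)), 5420),
               class = "iei_insufficient_depth")
  expect_error(downsample_repertoire(clones, 0), "positive")
  # clonotype-unit mode draws whole clonotype rows instead of templates
  cl <- downsample_repertoire(big, 10, seed = 5, unit = "clonotypes")
  expect_equal(nrow(cl), 10L)
  expect_true(all(cl$cdr3_aa %in% big$cdr3_aa))
  expect_identical(cl$templates,
                   big$templates[match(cl$cdr3_aa, big$cdr3_aa)])
  expect_error(downsample_repertoire(big, 1000, unit = "clonotypes"),
               class = "iei_insufficient_depth")
})

test_that("downsampled clone shares follow the hypergeometric expectation", {
  # two clones 8000/2000, n = 5420: sampled share of clone 1 is
  # hypergeometric with mean n*K/N and known variance
  clones <- make_rep(c(8000, 2000))
  n <- 5420; K <- 8000; N <- 10000
  n_rep <- 200
  shares <- vapply(seq_len(n_rep), function(s) {
    ds <- downsample_repertoire(clones, n, seed = s)
    ds$templates[ds$cdr3_aa == clones$cdr3_aa[1]] / n
  }, numeric(1))
  mu <- K / N
  var1 <- n * (K / N) * (1 - K / N) * (N - n) / (N - 1) / n^2
  se_mean <- sqrt(var1 / n_rep)
  expect_lt(abs(mean(shares) - mu), 3 * se_mean)
})

test_that("diversity metrics obey their closed forms", {
  # k singleton clonotypes -> inverse Simpson k (its upper bound)
  unif <- make_rep(rep(1, 17))
  d <- diversity_metrics(unif)
  expect_equal(d$inverse_simpson, 17, tolerance = 1e-12)
  expect_equal(d$unique_clonotypes, 17)
  # one clonotype -> index hits its lower bound 1
  expect_equal(diversity_metrics(make_rep(50))$inverse_simpson, 1,
               tolerance = 1e-12)
  # {4,1}: 1/((0.8)^2 + (0.2)^2) = 25/17
  expect_equal(diversity_metrics(make_rep(c(4, 1)))$inverse_simpson, 25 / 17,
               tolerance = 1e-12)
  expect_equal(diversity_metrics(make_rep(c(4, 1)))$mean_clone_size, 2.5)
  # always within [1, richness]
  set.seed(23)
  for (i in 1:10) {
    r <- make_rep(sample(1:50, sample(2:30, 1), replace = TRUE))
    d <- diversity_metrics(r)
    expect_gte(d$inverse_simpson, 1)
    expect_lte(d$inverse_simpson, d$unique_clonotypes + 1e-9)
  }
  expect_error(diversity_metrics(make_rep(1)[0, ]), "empty")
})

test_that("expansion classes follow the template thresholds and nest", {
  got <- classify_expansion(c(1L, 2L, 5L, 6L, 10L, 11L, 100L))
  expect_equal(as.character(got$class),
               c("nonexpanded", "normal", "normal", "pathological",
                 "pathological", "hyperexpanded", "hyperexpanded"))
  expect_identical(got$pathological, c(F, F, F, T, T, T, T))
  expect_identical(got$hyperexpanded, c(F, F, F, F, F, T, T))
  expect_true(all(got$pathological[got$hyperexpanded]))
  expect_error(classify_expansion(0L), ">= 1")
})

test_that("specificity annotation matches exact CDR3s within scope", {
  reference <- data.frame(
    cdr3_aa = c("CASSAAF", "CASSBBF", "CASSAAF"),
    condition_category = c("infection", "autoimmunity", "tumor_surveillance"),
    condition_label = c("flu", "t1d", "melanoma"), stringsAsFactors = FALSE)
  clones <- make_rep(c(20, 8, 1, 3),
                     cdr3 = c("CASSAAF", "CASSBBF", "CASSCCF", "CASSDDF"))
  whole <- annotate_specificities(clones, reference, scope = "whole")
  expect_equal(whole$n_matched, 2)
  expect_equal(whole$match_fraction, 0.5)
  # CASSAAF hits two categories: counted once per category, ambiguous
  expect_true(all(whole$matches$ambiguous[whole$matches$cdr3_aa == "CASSAAF"]))
  expect_equal(as.integer(whole$category_counts["infection"]), 1)
  path_only <- annotate_specificities(clones, reference,
                                      scope = "pathological_only")
  expect_equal(path_only$n_in_scope, 2)  # templates 20 and 8
  expect_equal(path_only$n_matched, 2)
  none <- annotate_specificities(make_rep(5, cdr3 = "CASSZZF"), reference)
  expect_equal(none$n_matched, 0)
  expect_equal(none$match_fraction, 0)
})

test_that("repertoire normalization excludes under-sequenced samples", {
  reps <- list(deep = make_rep(c(4000, 3000)),
               shallow = make_rep(c(100, 50)))
  out <- normalize_repertoires(reps, n = 5420, seed = 1)
  expect_identical(out$excluded, "shallow")
  expect_equal(out$metrics$sample_id, "deep")
  expect_equal(out$metrics$unique_clonotypes, 2)
})
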