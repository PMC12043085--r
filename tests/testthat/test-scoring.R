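make_matrix <- function(n_cells, n_genes, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n_cells * n_genes), nrow = n_cells,
         dimnames = list(paste0("c", seq_len(n_cells)),
                         paste0("G", seq_len(n_genes))))
}

test_that("module score has its closed forms in degenerate designs", {
  # set genes constant c, all others constant d -> score c - d everywhere
  m <- matrix(2, nrow = 20, ncol = 50,
              dimnames = list(paste0("c", 1:20), paste0("G", 1:50)))
  m[, 1:5] <- 7
  sc <- module_score(m, paste0("G", 1:5), n_bins = 1, n_ctrl = 100, seed = 1)
  # with one bin the control pool is all genes: mean = (5*7 + 45*2)/50
  expect_equal(unname(sc), rep(7 - mean(c(rep(7, 5), rep(2, 45))), 20),
               tolerance = 1e-12, ignore_attr = TRUE)
  # a set identical to its own controls self-subtracts to ~0: constant matrix
  flat <- matrix(3, 15, 30, dimnames = list(paste0("c", 1:15),
                                            paste0("G", 1:30)))
  sc0 <- module_score(flat, paste0("G", 1:3), n_bins = 1, seed = 1)
  expect_equal(unname(sc0), rep(0, 15), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(module_score(flat, c("NOPE1", "NOPE2")), "NOPE1")
})

test_that("module score equals an independent dense recomputation", {
  m <- make_matrix(200, 300, seed = 8)
  genes <- paste0("G", c(3, 50, 120, 250))
  sc <- module_score(m, genes, n_bins = 24, n_ctrl = 30, seed = 5)
  ctrl <- attr(sc, "controls")
  # straight per-cell loop over the realized control draw
  want <- vapply(seq_len(nrow(m)), function(i) {
    mean(m[i, genes]) - mean(m[i, ctrl])
  }, numeric(1))
  expect_equal(unname(sc), want, tolerance = 1e-10, ignore_attr = TRUE)
  # deterministic given the seed
  expect_identical(module_score(m, genes, n_bins = 24, n_ctrl = 30, seed = 5),
                   sc)
  # invariant under adding a constant to the whole matrix
  sc_shift <- module_score(m + 3.7, genes, n_bins = 24, n_ctrl = 30, seed = 5)
  expect_equal(unname(sc_shift), unname(sc), tolerance = 1e-10,
               ignore_attr = TRUE)
  # invariant under cell permutation
  perm <- sample(nrow(m))
  sc_perm <- module_score(m[perm, ], genes, n_bins = 24, n_ctrl = 30, seed = 5)
  expect_equal(unname(sc_perm), unname(sc)[perm], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("geometric-mean score matches the log-domain oracle", {
  bulk <- matrix(c(1, 4, 2, 8), nrow = 2, byrow = TRUE,
                 dimnames = list(c("s1", "s2"), c("GA", "GB")))
  expect_equal(unname(geometric_mean_score(bulk, c("GA", "GB"))), c(2, 4),
               tolerance = 1e-12)
  # all set genes equal v -> score v at zero pseudocount
  bulk2 <- matrix(5, 3, 4, dimnames = list(paste0("s", 1:3), paste0("G", 1:4)))
  expect_equal(unname(geometric_mean_score(bulk2, paste0("G", 1:4))),
               rep(5, 3))
  set.seed(12)
  r <- matrix(rexp(40), 5, 8, dimnames = list(paste0("s", 1:5),
                                              paste0("G", 1:8)))
  got <- geometric_mean_score(r, paste0("G", 1:8), pseudocount = 1)
  want <- exp(rowMeans(log(r + 1)))
  expect_equal(got, want, tolerance = 1e-12)
  r[1, 1] <- -1
  expect_error(geometric_mean_score(r, "G1"), "non-negative")
})

test_that("signature construction is the documented set algebra", {
  suppressWarnings(
    expect_equal(build_stat3_signature(c("A", "B"), list(c("C", "D"))),
                 character(0)))
  expect_warning(build_stat3_signature(c("A"), list("B")), "empty")
  up <- c("S1", "S2", "S3", "X1", "S4", "S2")
  ext <- list(c("S2", "S1"), c("S4", "S3", "Z9"))
  expect_equal(build_stat3_signature(up, ext), c("S1", "S2", "S3", "S4"))
  set.seed(2)
  for (i in 1:10) {
    a <- sample(LETTERS, 10)
    b <- list(sample(LETTERS, 8), sample(LETTERS, 5))
    got <- suppressWarnings(build_stat3_signature(a, b))
    expect_setequal(got, intersect(a, unique(unlist(b))))
  }
})

test_that("percentile thresholding calls exactly the top tail", {
  expect_equal(sum(percentile_threshold(1:100, 0.90)), 10)
  expect_equal(sum(percentile_threshold(sample(1:1000, 200), 0.90)), 20)
  expect_warning(hi <- percentile_threshold(rep(1, 50), 0.90), "constant")
  expect_equal(sum(hi), 0)
  # agrees with a sort-based oracle on random draws
  set.seed(19)
  x <- rnorm(257)
  hi <- percentile_threshold(x, 0.90)
  thr <- quantile(x, 0.90, names = FALSE)
  expect_identical(hi, x > thr)
  expect_error(percentile_threshold(1:5), "10 cells")
})

test_that("coexpression contingency stores recomputable proportions", {
  groups <- rep(c("STAT3mt", "STAT3wt", "healthy_control"), each = 1000)
  set.seed(4)
  high_a <- c(runif(1000) < 0.14, runif(1000) < 0.08, runif(1000) < 0.02)
  high_b <- rep(FALSE, 3000)
  res <- coexpression_contingency(high_a, high_b, groups)
  expect_lt(res$p_a, 0.0001)
  expect_true(is.na(res$p_b))          # no variation in flag B
  pg <- res$per_group
  expect_equal(pg$a_high_frac, pg$a_high / pg$n, tolerance = 1e-12)
  expect_equal(res$double_high_overall, 0)
  # all-false flags give zero proportions everywhere
  zero <- coexpression_contingency(rep(FALSE, 30), rep(FALSE, 30),
                                   rep(c("a", "b"), 15))
  expect_true(all(zero$per_group$a_high_frac == 0))
  # single group: proportions only, no test
  one <- coexpression_contingency(c(TRUE, FALSE), c(FALSE, TRUE),
                                  c("g", "g"))
  expect_true(is.na(one$p_a))
  expect_warning(
    coexpression_contingency(high_a[1:2], high_b[1:2],
                             factor(c("a", "a"), levels = c("a", "b"))),
    "empty group")
})
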