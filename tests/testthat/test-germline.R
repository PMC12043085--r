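cfg <- iei_config()

test_that("candidate filters enforce every exclusion clause", {
  cases <- list(
    list(row = germline_row(), pass = TRUE),
    list(row = germline_row(depth = 9L, alt_reads = 5L), pass = FALSE),
    list(row = germline_row(alt_reads = 3L), pass = FALSE),
    list(row = germline_row(vaf = 0.35), pass = FALSE),
    list(row = germline_row(population_af = 0.02), pass = FALSE),
    list(row = germline_row(population_af = 0.01), pass = FALSE),  # strict <
    list(row = germline_row(consequence = "synonymous"), pass = FALSE),
    list(row = germline_row(consequence = "splice_site"), pass = TRUE),
    list(row = germline_row(in_repetitive_region = TRUE), pass = FALSE),
    list(row = germline_row(matches_somatic_call = TRUE), pass = FALSE),
    list(row = germline_row(acmg = "B"), pass = FALSE),
    list(row = germline_row(acmg = "LB"), pass = FALSE),
    list(row = germline_row(acmg = "LP"), pass = TRUE))
  for (cs in cases) {
    got <- filter_candidates(cs$row, cfg)$passed_filters
    expect_identical(got, cs$pass, label = paste(deparse(cs$row), collapse = ""))
  }
})

test_that("overrepresentation screen selects P/LP unconditionally and VUS by q", {
  # a common P/LP variant (large AF -> p ~ 1) must still be selected;
  # a singleton rare VUS is selected iff its BH q clears alpha
  v <- rbind(
    germline_row(patient_id = "P001", gene = "G1", hgvs = "c.1A>G",
                 acmg = "LP", population_af = 0.009),
    germline_row(patient_id = "P002", gene = "G2", hgvs = "c.2A>G",
                 population_af = 1e-5),
    germline_row(patient_id = "P003", gene = "G3", hgvs = "c.3A>G",
                 population_af = 0.009))
  flagged <- filter_candidates(v, cfg)
  res <- overrepresentation_screen(flagged, cohort_n = 92, cfg)
  bv <- res$by_variant
  expect_true(bv$selected[bv$gene == "G1"])      # P/LP regardless of q
  expect_true(is.na(bv$overrep_q[bv$gene == "G1"]))  # not in the VUS family
  # verify VUS q-values against the summation + step-up oracle
  p2 <- binom_tail_oracle(1, 184, 1e-5)
  p3 <- binom_tail_oracle(1, 184, 0.009)
  want <- bh_oracle(c(p2, p3), cfg$fdr_alpha)
  expect_equal(bv$overrep_p[bv$gene == "G2"], p2, tolerance = 1e-12)
  expect_equal(sort(bv$overrep_q[bv$acmg == "VUS"]), sort(want$q),
               tolerance = 1e-12)
  expect_identical(bv$selected[bv$gene == "G2"],
                   want$reject[1])
  expect_identical(bv$selected[bv$gene == "G3"], want$reject[2])
  # duplicate (patient, variant) rows are a data error
  expect_error(overrepresentation_screen(rbind(flagged, flagged[1, ]), 92, cfg),
               "duplicate")
})

test_that("selection is monotone in the FDR level", {
  set.seed(13)
  v <- do.call(rbind, lapply(1:20, function(i) {
    germline_row(patient_id = sprintf("P%03d", i), gene = paste0("G", i),
                 hgvs = sprintf("c.%dA>G", i),
                 population_af = runif(1, 1e-5, 9e-3))
  }))
  flagged <- filter_candidates(v, cfg)
  for (alpha_pair in list(c(0.05, 0.01), c(0.2, 0.05))) {
    hi <- overrepresentation_screen(flagged, 92,
                                    iei_config(fdr_alpha = alpha_pair[1]))
    lo <- overrepresentation_screen(flagged, 92,
                                    iei_config(fdr_alpha = alpha_pair[2]))
    expect_true(all(lo$by_variant$selected <= hi$by_variant$selected))
  }
})

test_that("hcD classifier agrees with the decision-table oracle", {
  panel <- tiny_panel(genes = c("GAD", "GAR", "GXL", "GADAR"),
                      inheritance = c("AD", "AR", "XL", "AD_AR"))
  acmgs <- c("LP", "VUS")
  zygs <- c("het", "hom")
  genes <- panel$gene
  # single-variant patients: every (acmg, zygosity, gene) combination
  for (a in acmgs) for (z in zygs) for (g in genes) {
    v <- germline_row(gene = g, acmg = a, zygosity = z)
    got <- classify_hcd(v, panel)
    expect_identical(got$is_hcd, hcd_oracle(v, panel),
                     label = paste(a, z, g))
  }
  # two-variant patients: all pairs (same or different gene)
  combos <- expand.grid(a1 = acmgs, z1 = zygs, g1 = genes,
                        a2 = acmgs, z2 = zygs, g2 = genes,
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    cb <- combos[i, ]
    v <- rbind(germline_row(gene = cb$g1, acmg = cb$a1, zygosity = cb$z1,
                            hgvs = "c.1A>G"),
               germline_row(gene = cb$g2, acmg = cb$a2, zygosity = cb$z2,
                            hgvs = "c.2A>G"))
    got <- classify_hcd(v, panel)
    expect_identical(got$is_hcd, hcd_oracle(v, panel),
                     label = paste(unlist(cb), collapse = " "))
  }
  # rule precedence and tags
  expect_equal(classify_hcd(germline_row(acmg = "LP"), tiny_panel())$rule, "a")
  expect_equal(classify_hcd(germline_row(gene = "GAR", acmg = "VUS"),
                            panel)$is_hcd, FALSE)
  two_het <- rbind(germline_row(gene = "GAR", hgvs = "c.1A>G"),
                   germline_row(gene = "GAR", hgvs = "c.2A>G"))
  expect_equal(classify_hcd(two_het, panel)$rule, "c_presumed")
  expect_error(classify_hcd(germline_row(gene = "NOPE"), panel), "panel")
})

test_that("burden statistics recompute carrier tallies with control comparison", {
  co <- demo_cohort()
  tri <- triage_cohort(co$germline$variants, co$germline$panel, 92, cfg)
  b <- burden_statistics(tri, co$control$carriers, co$control$n)
  expect_equal(b$carriers, 34)
  expect_equal(b$median_variants_in_carriers, 1)
  expect_equal(b$range_variants_in_carriers, c(1, 3))
  expect_equal(b$hcd_carriers, 15)
  expect_equal(b$n_selected_variants, 43)
  expect_equal(b$n_selected_genes, 38)
  expect_equal(b$expected_probability, 43e-5, tolerance = 1e-12)
  expect_lt(b$comparison$p_value, 0.001)
  # zero carriers degrade gracefully
  tri0 <- tri
  tri0$per_patient <- tri$per_patient[0, ]
  b0 <- burden_statistics(tri0, 0, 1000)
  expect_equal(b0$combined_burden, 0)
  expect_equal(b0$comparison$p_value, 1)
})
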