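# Independent brute-force oracles used to verify the statistical primitives.
# These deliberately avoid the code paths (and library calls) they check.

# Upper binomial tail by direct summation of the mass function.
binom_tail_oracle <- function(observed, trials, p) {
  if (observed == 0) return(1)
  sum(vapply(observed:trials, function(k) {
    choose(trials, k) * p^k * (1 - p)^(trials - k)
  }, numeric(1)))
}

# Benjamini-Hochberg by exhaustive step-up over all rank cutoffs.
bh_oracle <- function(pvalues, alpha) {
  m <- length(pvalues)
  ord <- order(pvalues)
  ps <- pvalues[ord]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * alpha / m) k <- i
  reject_sorted <- seq_len(m) <= k
  # adjusted values: running minimum of m*p/i from the top
  q_sorted <- rev(cummin(rev(m * ps / seq_len(m))))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m); reject <- logical(m)
  q[ord] <- q_sorted
  reject[ord] <- reject_sorted
  list(q = q, reject = reject)
}

# Two-sided Fisher exact p by enumerating all 2x2 tables with fixed margins.
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  prob <- function(a) {
    choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(support, prob, numeric(1))
  p_obs <- prob(tab[1, 1])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# hcD truth table evaluated straight from the written rules, one
# (acmg, zygosity, inheritance) tuple per variant.
hcd_oracle <- function(variants, panel) {
  inh <- panel$inheritance[match(variants$gene, panel$gene)]
  rule_a <- any(variants$acmg %in% c("P", "LP"))
  rule_b <- any(variants$acmg == "VUS" & variants$zygosity == "het" &
                  inh %in% c("AD", "AD_AR"))
  rec <- inh %in% c("AR", "XL")
  rule_c_hom <- any(variants$zygosity == "hom" & rec)
  het_rec_genes <- variants$gene[variants$zygosity == "het" & rec]
  hgvs_rec <- variants$hgvs[variants$zygosity == "het" & rec]
  rule_c_comp <- any(tapply(hgvs_rec, het_rec_genes,
                            function(h) length(unique(h))) >= 2)
  rule_c_comp <- isTRUE(rule_c_comp)
  rule_a || rule_b || rule_c_hom || rule_c_comp
}

# A tiny valid germline variant row, overridable field by field.
germline_row <- function(...) {
  row <- data.frame(
    patient_id = "P001", gene = "GENE1", hgvs = "c.100A>G",
    consequence = "missense", population_af = 0.005, acmg = "VUS",
    zygosity = "het", vaf = 0.5, depth = 60L, alt_reads = 28L,
    in_repetitive_region = FALSE, matches_somatic_call = FALSE,
    stringsAsFactors = FALSE)
  override <- list(...)
  for (nm in names(override)) row[[nm]] <- override[[nm]]
  row
}

tiny_panel <- function(genes = "GENE1", inheritance = "AD") {
  data.frame(gene = genes, iuis_category = "immune_dysregulation",
             inheritance = inheritance, onset = "adult",
             dysregulation_vs_deficiency = "dysregulation",
             stringsAsFactors = FALSE)
}
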