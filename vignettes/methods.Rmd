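---
title: "Immunogenomic triage of inborn errors of immunity in T-LGLL cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immunogenomic triage of inborn errors of immunity in T-LGLL cohorts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ieilgl)
```

## The scientific problem

T cell large granular lymphocyte leukemia (T-LGLL) is a chronic clonal
expansion of cytotoxic T lymphocytes, often carrying gain-of-function
*STAT3* mutations. Although it is formally a leukemia, patients frequently
present with immunodeficiency signs — low or merely normal lymphocyte
counts, hypogammaglobulinemia, lymphocyte subset deficits. `ieilgl`
implements the cohort analysis needed to test whether cryptic germline
defects in inborn-errors-of-immunity (IEI) genes underlie a fraction of
these expansions: triage of rare germline variants, classification of
high-confidence deleterious (hcD) carriers, and the clinical, somatic,
repertoire and expression analyses used to characterize carriers.

The package operates on annotated tables (variant calls with ACMG tiers and
population frequencies, copy-number segments, ImmunoSEQ-style clonotype
tables, expression matrices, laboratory panels); it deliberately does not
perform alignment, variant calling, ACMG classification, segmentation,
clustering or differential expression — those are upstream tools' jobs and
their outputs are this package's inputs.

## Germline triage model

### Call filters

A candidate variant passes iff all hold: population allele frequency
< `rarity_max_af` (default 0.01); depth ≥ 10; alternate reads ≥ 4;
VAF ≥ 0.40 (germline heterozygous calls cluster near 0.5; lower VAF
suggests somatic origin or artifact); consequence in {missense, nonsense,
frameshift, indel, splice site}; not in a repetitive region; not matching a
somatic call in the same patient; ACMG class not benign/likely benign.
Filtering is pure flagging — no rows are dropped, so an audit trail
remains.

### Overrepresentation screen

The screen compares observed versus expected variant frequencies. The
expected model is the minimal exact one: under the population frequency
`AF`, the allele count among `n` diploid patients is
`X ~ Binomial(2n, AF)`, and the one-sided p-value is `P(X ≥ k)`. This was a
genuinely open design point — the comparison could also be framed as a
Poisson tail, which we expose behind `iei_config(overrep_test = "poisson")`;
for `AF` in the rare-variant regime the two agree to within a couple of
percent. A population frequency of exactly zero is floored at
`1/(2 × reference_cohort_size)` (default reference size 63,026, the scale
of the control population used for the burden comparison) so the tail test
stays defined; the floor is configurable because reference panels differ.

Benjamini–Hochberg correction at `fdr_alpha = 0.05` runs over the family of
*tested VUS only*: P/LP variants are selected unconditionally, so including
them in the family would only dilute it. Variants are grouped by
`(gene, HGVS)` — the unit at which population frequencies are defined.
Selection is monotone in the FDR level (tested by property).

### hcD classification

Rules in precedence order: (a) any P/LP variant; (b) heterozygous VUS in a
dominant-trait gene (`AD` or `AD_AR`); (c) homozygous variant in a
recessive gene, or two or more distinct heterozygous variants in the same
recessive gene. Exome calls are unphased, so rule (c) pairs are *presumed*
compound heterozygotes and tagged `c_presumed`. Hemizygous X-linked calls
in males should be coded `hom` by the caller, which makes them fire
rule (c) — the biologically sensible convention. The classifier is verified
against an exhaustive decision-table oracle over every
(ACMG, zygosity, inheritance, multiplicity) combination.

## Clinical phenotyping

Analytes are flagged low strictly below the lower bound of their normal
range (subsets in 10⁹ cells/L: CD3 0.96–2.39, CD4 0.53–1.67, CD8 0.28–0.96,
NK 0.10–0.57, B 0.08–0.66; immunoglobulins in mg/dL: IgG 717–1411,
IgA 78–391, IgM 53–334). Missing analytes yield `NA` flags, never an
implicit "normal", and every denominator counts only measured patients.
Two thresholds deserve comment:

* the "low/normal" lymphocyte band is bounded above at 4.0 × 10⁹/L;
* lymphocytopenia proper uses a configurable lower bound with default
  1.0 × 10⁹/L, the standard clinical cutoff — only the 4.0 upper bound of
  the band is externally fixed, so the lower bound is an explicit package
  default.

The immune-defect composite is `lymphocytopenia OR hypogammaglobulinemia`.
Whether subset deficits should enter the composite is not externally
specified; we keep the narrow definition and report subset flags
separately, so any wider composite can be recomputed from the stored
flags. Secondary-hypogammaglobulinemia screening calls a patient an
`acquired_candidate` if any acquired-cause history flag is set (prior
hemato-lymphoid neoplasm, anti-B-cell therapy, other immunosuppression,
chemotherapy, Good syndrome/CVID-like condition, transplant), and
`unexplained` otherwise. Reported percentages are rounded half-up to
integers (matching clinical reporting), with raw counts retained.

## Somatic landscape

Driver SNVs are restricted to P/LP calls in the configured driver panel
with coding-relevant consequences. Mutational configuration per patient is
the partition {STAT3-only, other-only, coexistence, none}.

Gene-level copy number is aggregated from segments by mapping each gene
onto the per-patient segment calls and taking the overlap-length-weighted
mean of segment log₂ ratios. Intervals are 0-based half-open throughout
(BED convention); interval arithmetic uses GenomicRanges. Thresholds
default to ±0.3 log₂ for gain/loss — roughly a single-copy change at
moderate tumor purity; no external threshold exists, so they are config
options. A gene whose interval overlaps blacklist regions (hypervariable
regions, common population CNVs) by ≥ 50 % of its length is excluded; the
fraction is likewise configurable because only the exclusion itself, not
the fraction, is externally specified. Genes with no overlapping segment
are reported neutral with missing log₂ and a `no_coverage` flag rather
than silently omitted.

## TCR repertoire

Analysis is restricted to productive rearrangements (in-frame, no stop
codon). Depth normalization downsamples each repertoire to exactly 5,420
templates, drawn uniformly without replacement from the template multiset;
samples below the target are excluded with a classed condition rather than
silently truncated. We interpret the normalization unit as *templates*
(the standard rarefaction unit); a unique-clonotype interpretation would
change the marginal distribution of per-clone counts, so the choice is an
explicit default, with the alternative available via
`downsample_repertoire(unit = "clonotypes")`. Single-clone sampled counts are
hypergeometric by construction, which the calibration suite checks against
the closed-form mean.

Diversity metrics are the unique clonotype count, inverse Simpson index
`1/Σ p²` (bounded by 1 and the clonotype count) and mean clone size.
Expansion classes: 1 template (nonexpanded), 2–5 (normal), >5
(pathological), >10 (hyperexpanded, nested within pathological — both
flags are reported). Specificity annotation is exact CDR3 amino-acid
equality against the reference, without a V/J constraint; clonotype
identity is `(CDR3, V, J)` when V/J are present and CDR3 alone otherwise.
Multi-category matches count once per category and are flagged ambiguous.

## Expression scoring

The per-cell module score is the binned-control algorithm: genes are
ranked by dataset-wide mean expression and cut into `n_bins = 24`
equal-size bins; each set gene contributes `n_ctrl = 100` control genes
drawn without replacement from its bin (the whole bin if smaller), and the
score is the set-gene mean minus the control-gene mean per cell. The
defaults are the conventional ones for this method. The score is invariant
to adding a constant to the matrix and to cell permutation, and the
realized control draw is exposed (`attr(,"controls")`) so any score can be
audited by direct recomputation — the test suite does exactly that to
1e-10. Scores are computed on log-normalized expression by default; input
scaling is the caller's choice.

High/low calls use the empirical 90th percentile over all cells pooled
(matching thresholds applied to one combined embedding); ties at the
threshold are low. The STAT3 activation signature is built by intersecting
the genes upregulated in STAT3-mutant cells with the union of external
upregulated-gene lists. The shipped 15-gene TCR signalosome and 9-gene
STAT3 sets are *reconstructions* assembled from TCR complex/signalosome
members and canonical STAT3 targets — full published memberships are not
available — and are plain configuration (`iei_config(gene_sets = ...)`)
meant to be replaced by study-specific lists.

## Synthetic cohorts: what they emulate, and what they do not

The generator produces every pipeline input with planted truth:

* **Germline**: a planted variant with frequency `AF` and enrichment `e`
  appears per patient with probability `2·AF·e` (error if the cap exceeds
  1); depth ~ NegBin(mean 80, size 5), heterozygous VAF ~ Beta(20, 20) —
  realistic exome sampling noise, which makes a small fraction of true
  rows fail the call filters, as in real data. Default planted variants
  use `AF = 1e-3` with enrichment 50: at a cohort of 92 this yields ~9
  expected carrier alleles per planted variant, a regime in which a
  detection power claim is meaningful. (At `AF = 1e-4` and the same
  enrichment, the expected carrier count is below one; no screen can
  recover such variants reliably, so that regime is not a sensible default
  for calibration.) Null variants default to `AF = 5e-3`, common enough to
  be observed and thus to exercise the false-discovery control.
* **Repertoire**: Zipf clone sizes (exponent 2.5), planted hyperexpanded
  clones, and a stated fraction of clones copying reference CDR3s.
* **Expression**: Normal noise with an additive set-gene shift δ in
  designated groups.
* **Clinical**: lognormal analytes parameterized to put a stated fraction
  below the lower normal bound.

The simulations are calibration instruments, not biological replicas: they
omit linkage between variants, V/J usage structure, cell-type expression
programs, batch effects and analyte correlations. Passing calibration
therefore shows that the *procedures* control error and recover planted
effects under their stated models — not that any particular biological
dataset will behave identically.

## Problem sizes and numerical choices

The shipped calibration suite uses 200 germline replicates at n = 92, 500
downsampling draws of 5,420 from 10,000 templates, and 20 expression
replicates of 600 cells × 500 genes — sizes chosen to estimate the
calibrated quantities with comfortable Monte-Carlo margins while keeping a
default run in tens of seconds on one core. Percent reporting rounds
half-up (base `round()` is banker's); the binomial tail is computed via
`pbinom` on the complement scale, exact to 1e-12 against direct summation
for trials ≤ 1000; chi-square tests use no continuity correction, matching
conventional Pearson χ² reporting, and refuse tables with zero marginals
(directing to Fisher's exact test). All stochastic steps take explicit
integer seeds and are bit-reproducible.

## Known limitations

* ACMG tiers, somatic pathogenicity and population frequencies are input
  annotations; the package does not query ClinVar/VarSome/COSMIC/gnomAD.
* Compound heterozygosity is presumed from unphased pairs; true phasing
  could reclassify rule-c carriers.
* The overrepresentation screen tests each variant marginally; it does not
  model linkage or gene-level burden beyond the per-variant tally.
* Gene-level CN calls inherit segmentation quality; no purity/ploidy
  modeling is attempted.
* The demonstration cohort (`demo_cohort()`) is a synthetic worked
  example constructed so that its tallies take round documented values; it
  is not patient data.
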