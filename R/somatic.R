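#' Filter somatic calls down to high-stringency driver mutations
#'
#' Keeps a variant iff its gene is on the driver panel, its consequence is
#' missense / nonsense / frameshift / indel, and its pathogenicity
#' annotation is P or LP (only pathogenic / likely pathogenic calls are
#' retained for stringency).
#'
#' @param variants Somatic variant data.frame (dialect `somatic_variants`).
#' @param panel Character vector of driver gene symbols.
#' @return The kept rows.
#' @export
filter_driver_mutations <- function(variants, panel) {
  if (!length(panel)) stop("driver panel must be non-empty", call. = FALSE)
  keep <- variants$gene %in% panel &
    variants$pathogenicity %in% c("P", "LP") &
    variants$consequence %in% c("missense", "nonsense", "frameshift", "indel")
  variants[keep, , drop = FALSE]
}

#' Per-patient mutational configuration in STAT3 and other drivers
#'
#' @param kept Output of [filter_driver_mutations()].
#' @param patients Character vector of all cohort patient ids (so patients
#'   without any kept mutation are counted).
#' @return Data.frame per patient: `configuration` in
#'   `{stat3_only, other_only, coexistence, none}` and `burden` (number of
#'   kept variants).
#' @export
mutational_configuration <- function(kept, patients) {
  has_stat3 <- patients %in% kept$patient_id[kept$gene == "STAT3"]
  has_other <- patients %in% kept$patient_id[kept$gene != "STAT3"]
  configuration <- ifelse(has_stat3 & has_other, "coexistence",
                    ifelse(has_stat3, "stat3_only",
                      ifelse(has_other, "other_only", "none")))
  burden <- as.integer(table(factor(kept$patient_id, levels = patients)))
  data.frame(patient_id = patients, configuration = configuration,
             burden = burden, stringsAsFactors = FALSE)
}

#' Gene-level copy-number calls from segment tables
#'
#' Maps genes onto per-patient segment calls and computes, for each gene,
#' the overlap-length-weighted average of the segment log2 read-depth
#' ratios: `sum(overlap_bp * log2) / sum(overlap_bp)` over the segments
#' intersecting the gene. Calls gain when the weighted log2 reaches the
#' gain threshold, loss when it falls to the loss threshold. A gene whose
#' interval overlaps blacklist intervals (hypervariable regions, common
#' population CNVs) by at least `blacklist_overlap_frac` of its length is
#' excluded. All coordinates are 0-based half-open.
#'
#' @param segments Segment data.frame (dialect `cn_segments`), non-overlapping
#'   per patient and chromosome.
#' @param genes Gene coordinate data.frame (dialect `gene_coords`).
#' @param blacklist Optional data.frame of `chrom`, `start`, `end` intervals
#'   (e.g. from [read_bed()]).
#' @param config An [iei_config()] list (thresholds).
#' @return Data.frame per patient x gene: `weighted_log2`, `call` in
#'   `{gain, loss, neutral, excluded}`, and `no_coverage` flagging genes with
#'   zero segment overlap (reported neutral with missing log2).
#' @export
gene_level_cn <- function(segments, genes, blacklist = NULL,
                          config = iei_config()) {
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
  excluded <- rep(FALSE, nrow(genes))
  if (!is.null(blacklist) && nrow(blacklist)) {
    bl_gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      blacklist$chrom, IRanges::IRanges(blacklist$start + 1L, blacklist$end)))
    cov <- rep(0L, nrow(genes))
    hits <- GenomicRanges::findOverlaps(gene_gr, bl_gr)
    if (length(hits)) {
      ov <- GenomicRanges::pintersect(
        gene_gr[S4Vectors::queryHits(hits)], bl_gr[S4Vectors::subjectHits(hits)])
      w <- tapply(GenomicRanges::width(ov), S4Vectors::queryHits(hits), sum)
      cov[as.integer(names(w))] <- as.integer(w)
    }
    excluded <- cov >= config$blacklist_overlap_frac * (genes$end - genes$start)
  }

  out <- lapply(split(segments, segments$patient_id), function(seg) {
    seg_gr <- GenomicRanges::GRanges(
      seg$chrom, IRanges::IRanges(seg$start + 1L, seg$end))
    hits <- GenomicRanges::findOverlaps(gene_gr, seg_gr)
    wlog2 <- rep(NA_real_, nrow(genes))
    if (length(hits)) {
      ov <- GenomicRanges::width(GenomicRanges::pintersect(
        gene_gr[S4Vectors::queryHits(hits)], seg_gr[S4Vectors::subjectHits(hits)]))
      num <- tapply(ov * seg$log2[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits), sum)
      den <- tapply(ov, S4Vectors::queryHits(hits), sum)
      wlog2[as.integer(names(num))] <- as.numeric(num) / as.numeric(den)
    }
    call <- ifelse(excluded, "excluded",
             ifelse(is.na(wlog2), "neutral",
              ifelse(wlog2 >= config$cn_gain_log2, "gain",
               ifelse(wlog2 <= config$cn_loss_log2, "loss", "neutral"))))
    data.frame(patient_id = seg$patient_id[1], gene = genes$gene,
               weighted_log2 = wlog2, call = call,
               no_coverage = is.na(wlog2) & !excluded,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize the somatic driver landscape of a cohort
#'
#' @param kept Output of [filter_driver_mutations()].
#' @param patients All cohort patient ids.
#' @return List of headline tallies: mutated fraction, STAT3-mutant rate,
#'   non-STAT3 rate, configuration counts, burden distribution.
#' @export
summarize_somatic <- function(kept, patients) {
  cfgs <- mutational_configuration(kept, patients)
  n <- length(patients)
  mutated <- sum(cfgs$configuration != "none")
  stat3 <- sum(cfgs$configuration %in% c("stat3_only", "coexistence"))
  other <- sum(cfgs$configuration %in% c("other_only", "coexistence"))
  list(
    n = n,
    n_variants = nrow(kept),
    n_genes = length(unique(kept$gene)),
    mutated = mutated,
    mutated_pct = percent_of(mutated, n),
    stat3_mt = stat3,
    stat3_mt_pct = percent_of(stat3, n),
    other_mt = other,
    other_mt_pct = percent_of(other, n),
    configurations = table(factor(cfgs$configuration,
      levels = c("stat3_only", "other_only", "coexistence", "none"))),
    mean_burden = mean(cfgs$burden),
    burden_range = range(cfgs$burden),
    per_patient = cfgs
  )
}
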