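# EST-evidence-based evaluation of predicted introns, with the
# homology-supported correction for retained-intron ESTs.

merge_intervals <- function(df) {
  if (nrow(df) == 0) return(df)
  out <- list()
  for (ctg in unique(df$contig)) {
    d <- df[df$contig == ctg, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    s <- d$start[1]; e <- d$end[1]
    for (k in seq_len(nrow(d))[-1]) {
      if (d$start[k] <= e) e <- max(e, d$end[k])
      else { out[[length(out) + 1L]] <- data.frame(contig = ctg, start = s, end = e); s <- d$start[k]; e <- d$end[k] }
    }
    out[[length(out) + 1L]] <- data.frame(contig = ctg, start = s, end = e)
  }
  do.call(rbind, out)
}

#' EST evidence container
#'
#' @param introns data.frame of EST-supported introns with columns
#'   `contig`, `start`, `end` (0-based half-open genomic interval of the
#'   intron), `strand`.
#' @param exons data.frame of spliced-EST exonic coverage (`contig`,
#'   `start`, `end`); intervals are merged per contig.
#' @return An object of class `est_evidence`.
#' @export
est_evidence <- function(introns, exons) {
  introns <- unique(introns[, c("contig", "start", "end", "strand")])
  structure(list(introns = introns, exons = merge_intervals(exons)),
            class = "est_evidence")
}

#' Read EST evidence from BED files
#'
#' @param intron_bed6 BED6 of supported introns (one record per intron).
#' @param exon_bed3 BED3 of exonic coverage intervals.
#' @return An [est_evidence()].
#' @export
read_est_evidence <- function(intron_bed6, exon_bed3) {
  gi <- rtracklayer::import(intron_bed6)
  ge <- rtracklayer::import(exon_bed3)
  est_evidence(
    data.frame(contig = as.character(GenomicRanges::seqnames(gi)),
               start = GenomicRanges::start(gi) - 1L,
               end = GenomicRanges::end(gi),
               strand = as.character(GenomicRanges::strand(gi))),
    data.frame(contig = as.character(GenomicRanges::seqnames(ge)),
               start = GenomicRanges::start(ge) - 1L,
               end = GenomicRanges::end(ge)))
}

#' Derive (synthetic) EST evidence from a set of gene structures
#'
#' Converts gene structures into perfect evidence: every implied intron
#' becomes a supported intron and every exon becomes exonic coverage.
#' Used to build evaluation fixtures from simulated truth.
#'
#' @param genes list of [gene_structure()].
#' @return An [est_evidence()].
#' @export
evidence_from_genes <- function(genes) {
  introns <- list(); exons <- list()
  for (gs in genes) {
    ii <- intron_intervals(gs)
    if (nrow(ii) > 0) {
      introns[[length(introns) + 1L]] <-
        data.frame(contig = gs$contig, start = ii$start, end = ii$end,
                   strand = gs$strand)
    }
    exons[[length(exons) + 1L]] <-
      data.frame(contig = gs$contig, start = gs$exons[, 1],
                 end = gs$exons[, 2])
  }
  est_evidence(
    if (length(introns)) do.call(rbind, introns)
    else data.frame(contig = character(), start = integer(),
                    end = integer(), strand = character()),
    do.call(rbind, exons))
}

overlaps_any <- function(contig, start, end, df) {
  any(df$contig == contig & df$start < end & df$end > start)
}

covered_by <- function(contig, start, end, df) {
  sel <- df[df$contig == contig & df$start < end & df$end > start, ,
            drop = FALSE]
  if (nrow(sel) == 0) return(FALSE)
  # merged intervals: containment means one interval covers the whole span
  any(sel$start <= start & sel$end >= end)
}

#' Classify predicted introns against EST evidence
#'
#' A true positive intron matches a supported intron exactly at both
#' ends; a false positive lies entirely inside EST-exonic coverage; a
#' false negative is a supported intron lying entirely inside predicted
#' exons.  `NoIntR` counts supported introns overlapping predicted genic
#' regions, `NoIntQ` predicted introns overlapping any EST genic area;
#' `JncTP` counts predicted junctions matching a supported intron end.
#'
#' @param genes list of predicted [gene_structure()]s.
#' @param evidence an [est_evidence()].
#' @return list with `counts` (named integers) and `fp` (data.frame of
#'   false-positive introns: gene id, interval, ordinal index).
#' @export
classify_introns <- function(genes, evidence) {
  sup <- evidence$introns
  est_genic <- merge_intervals(rbind(
    evidence$exons,
    sup[, c("contig", "start", "end"), drop = FALSE]))
  pred <- list(); genic <- list(); pred_ex <- list()
  for (gs in genes) {
    ii <- intron_intervals(gs)
    if (nrow(ii) > 0) {
      pred[[length(pred) + 1L]] <-
        data.frame(gene_id = gs$gene_id, contig = gs$contig,
                   start = ii$start, end = ii$end, strand = gs$strand,
                   index = seq_len(nrow(ii)))
    }
    genic[[length(genic) + 1L]] <-
      data.frame(contig = gs$contig, start = min(gs$exons[, 1]),
                 end = max(gs$exons[, 2]))
    pred_ex[[length(pred_ex) + 1L]] <-
      data.frame(contig = gs$contig, start = gs$exons[, 1],
                 end = gs$exons[, 2])
  }
  pred <- if (length(pred)) do.call(rbind, pred)
          else data.frame(gene_id = character(), contig = character(),
                          start = integer(), end = integer(),
                          strand = character(), index = integer())
  genic <- merge_intervals(do.call(rbind, genic))
  pred_ex <- merge_intervals(do.call(rbind, pred_ex))

  sup_key <- paste(sup$contig, sup$start, sup$end, sup$strand)
  pred_key <- paste(pred$contig, pred$start, pred$end, pred$strand)

  NoIntR <- sum(vapply(seq_len(nrow(sup)), function(k) {
    overlaps_any(sup$contig[k], sup$start[k], sup$end[k], genic)
  }, logical(1)))
  in_est <- vapply(seq_len(nrow(pred)), function(k) {
    overlaps_any(pred$contig[k], pred$start[k], pred$end[k], est_genic)
  }, logical(1))
  NoIntQ <- sum(in_est)
  tp <- pred_key %in% sup_key
  IntTP <- sum(tp)
  fp_mask <- !tp & vapply(seq_len(nrow(pred)), function(k) {
    covered_by(pred$contig[k], pred$start[k], pred$end[k], evidence$exons)
  }, logical(1))
  IntFP <- sum(fp_mask)
  IntFN <- sum(vapply(seq_len(nrow(sup)), function(k) {
    !(sup_key[k] %in% pred_key) &&
      covered_by(sup$contig[k], sup$start[k], sup$end[k], pred_ex)
  }, logical(1)))
  JncTP <- 0L
  if (nrow(pred) > 0) {
    sk <- paste(sup$contig, sup$start, sup$strand)
    ek <- paste(sup$contig, sup$end, sup$strand)
    JncTP <- sum(paste(pred$contig, pred$start, pred$strand) %in% sk) +
      sum(paste(pred$contig, pred$end, pred$strand) %in% ek)
  }
  list(counts = c(NoIntR = NoIntR, NoIntQ = NoIntQ, IntTP = IntTP,
                  IntFP = as.integer(IntFP), IntFN = as.integer(IntFN),
                  JncTP = as.integer(JncTP), IntHS_TP = 0L),
       fp = pred[fp_mask, , drop = FALSE])
}

#' Homology-supported correction of false-positive introns
#'
#' A nominally false-positive intron whose (alignment column, phase) is
#' concordant with at least one other cluster member is reclassified as a
#' homology-supported true positive: likely the EST represents a
#' retained-intron isoform.  Lonesome false positives stay false.
#'
#' @param classified result of [classify_introns()].
#' @param msa the cluster `gsa_msa` containing the genes.
#' @return Updated counts vector with `IntHS_TP` set and `IntTP`,
#'   `JncTP`, `IntFP` corrected.
#' @export
homology_correction <- function(classified, msa) {
  counts <- classified$counts
  fp <- classified$fp
  hs <- 0L
  conc <- intron_concordance(msa)
  if (nrow(fp) > 0 && nrow(conc$marks) > 0) {
    for (k in seq_len(nrow(fp))) {
      id <- fp$gene_id[k]
      marks <- msa$introns[[id]]
      if (is.null(marks) || nrow(marks) < fp$index[k]) next
      col <- marks$column[fp$index[k]]
      ph <- marks$phase[fp$index[k]]
      m <- conc$marks
      if (any(m$member == id & m$column == col & m$phase == ph &
              m$concordant)) hs <- hs + 1L
    }
  }
  counts["IntHS_TP"] <- hs
  counts["IntTP"] <- counts["IntTP"] + hs
  counts["JncTP"] <- counts["JncTP"] + 2L * hs
  counts["IntFP"] <- counts["IntFP"] - hs
  counts
}

rate_or_na <- function(num, den) {
  if (is.na(den) || den == 0) NA_real_ else num / den
}

#' Intron-level sensitivity/specificity metrics
#'
#' `IntSn = 100 IntTP / NoIntR`, `IntSp = 100 IntTP / NoIntQ`,
#' `JncSn = 50 JncTP / NoIntR`, `JncSp = 50 JncTP / NoIntQ`,
#' `FPR = 100 IntFP / NoIntQ`, `FNR = 100 IntFN / NoIntR`.  Undefined
#' denominators yield `NA` rather than an error.
#'
#' @param counts named counts as from [classify_introns()] (raw) or
#'   [homology_correction()] (corrected).
#' @return Named numeric vector of percentages.
#' @export
est_metrics <- function(counts) {
  c(IntSn = 100 * rate_or_na(counts[["IntTP"]], counts[["NoIntR"]]),
    IntSp = 100 * rate_or_na(counts[["IntTP"]], counts[["NoIntQ"]]),
    JncSn = 50 * rate_or_na(counts[["JncTP"]], counts[["NoIntR"]]),
    JncSp = 50 * rate_or_na(counts[["JncTP"]], counts[["NoIntQ"]]),
    FPR = 100 * rate_or_na(counts[["IntFP"]], counts[["NoIntQ"]]),
    FNR = 100 * rate_or_na(counts[["IntFN"]], counts[["NoIntR"]]))
}

#' Full EST evaluation report (raw and corrected)
#'
#' @param genes predicted gene structures.
#' @param evidence an [est_evidence()].
#' @param msa optional cluster alignment enabling the homology-supported
#'   correction.
#' @return data.frame with one row per variant (`raw`, `corrected`)
#'   holding the counts and the six rates.
#' @export
est_report <- function(genes, evidence, msa = NULL) {
  cl <- classify_introns(genes, evidence)
  raw <- cl$counts
  rows <- list(cbind(data.frame(variant = "raw"),
                     as.data.frame(t(raw)),
                     as.data.frame(t(est_metrics(raw)))))
  if (!is.null(msa)) {
    corr <- homology_correction(cl, msa)
    rows[[2]] <- cbind(data.frame(variant = "corrected"),
                       as.data.frame(t(corr)),
                       as.data.frame(t(est_metrics(corr))))
  }
  do.call(rbind, rows)
}
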