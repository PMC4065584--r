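# Iterative refinement of gene structures: assess the cluster alignment,
# choose a template per mode (M1 / CR / PR), re-predict each visited gene
# by spliced alignment over its genomic window, update the alignment,
# and repeat until the structures stop changing.

structure_digest <- function(gs) {
  paste(gs$contig, gs$strand,
        paste(gs$exons[, 1], gs$exons[, 2], sep = "-", collapse = ","),
        sep = "|")
}

#' Refinement schedule
#'
#' An ordered list of template modes with no two consecutive modes equal.
#'
#' @param modes character vector over `c("M1","CR","PR")`, length 1..3.
#' @param max_rounds cap on passes within each mode.
#' @return An object of class `gsa_schedule`.
#' @export
gsa_schedule <- function(modes = c("CR", "M1", "PR"), max_rounds = 3L) {
  modes <- match.arg(modes, c("M1", "CR", "PR"), several.ok = TRUE)
  stopifnot(length(modes) >= 1, length(modes) <= 3)
  if (length(modes) > 1 && any(modes[-1] == modes[-length(modes)]))
    stop("no two consecutive modes may be identical")
  structure(list(modes = modes, max_rounds = as.integer(max_rounds)),
            class = "gsa_schedule")
}

#' Run one template mode over a cluster
#'
#' M1 visits every member in turn; CR and PR visit only the members
#' labelled "Q".  Each visit chooses the template, selects the genomic
#' window (extended on flagged ends), re-predicts the gene by spliced
#' alignment, replaces the member in the alignment, and re-assesses.
#' The pass repeats until the structures stop changing or `max_rounds`
#' passes.
#'
#' @param msa the cluster `gsa_msa`.
#' @param report its `gsa_assessment`.
#' @param mode `"M1"`, `"CR"`, or `"PR"`.
#' @param genome the genome.
#' @param cfg a [gsa_config()].
#' @param params scoring parameters.
#' @param model a [splice_model()].
#' @return `list(msa=, report=, log=)`; `log` is a data.frame with one
#'   row per visit.
#' @export
run_mode <- function(msa, report, mode, genome, cfg = gsa_config(),
                     params = score_params(), model = splice_model()) {
  genome <- as_genome(genome)
  log <- list()
  for (pass in seq_len(cfg$max_rounds)) {
    changed <- FALSE
    targets <- if (mode == "M1") msa$ids
               else report$members$id[report$members$label == "Q"]
    if (length(targets) == 0) break
    for (q in targets) {
      old_gene <- msa$proteins[[q]]$gene
      old_digest <- if (!is.null(old_gene)) structure_digest(old_gene) else ""
      old_points <- report$members[q, "defect_points"]
      entry <- data.frame(member = q, mode = mode, pass = pass,
                          accepted = FALSE, old_digest = old_digest,
                          new_digest = old_digest,
                          points_before = old_points,
                          points_after = old_points,
                          note = "", stringsAsFactors = FALSE)
      tmpl <- tryCatch(choose_template(q, msa, report, mode),
                       error = function(e) NULL)
      if (is.null(tmpl) || is.null(old_gene)) {
        entry$note <- "no reliable template"
        log[[length(log) + 1L]] <- entry
        next
      }
      region <- select_target_region(old_gene, genome, cfg,
                                     flag5 = report$members[q, "flag5"],
                                     flag3 = report$members[q, "flag3"])
      res <- spliced_align(tmpl, region, genome, model, params, cfg,
                           gene_id = q)
      if (!res$ok) {
        entry$note <- "no positive-scoring alignment"
        log[[length(log) + 1L]] <- entry
        next
      }
      res$gene$genome_id <- old_gene$genome_id
      new_digest <- structure_digest(res$gene)
      entry$new_digest <- new_digest
      entry$accepted <- TRUE
      if (new_digest != old_digest) changed <- TRUE
      msa <- update_msa(msa, list(res$protein), params,
                        refine_rounds = 1L, refine_scope = "revised")
      report <- assess_msa(msa, cfg, params)
      entry$points_after <- report$members[q, "defect_points"]
      log[[length(log) + 1L]] <- entry
    }
    if (!changed) break
  }
  log <- if (length(log)) do.call(rbind, log)
         else data.frame(member = character(), mode = character(),
                         pass = integer(), accepted = logical(),
                         old_digest = character(), new_digest = character(),
                         points_before = integer(), points_after = integer(),
                         note = character())
  list(msa = msa, report = report, log = log)
}

#' Run a refinement schedule over a cluster
#'
#' Executes the modes in order.  After each mode pass the cluster nWSP is
#' compared against the value before the pass; a drop larger than
#' `cfg$nwsp_tolerance` reverts the whole pass (the consensus evidently
#' degraded).  The schedule terminates early when a full mode pass leaves
#' every structure unchanged or no "Q" member remains (and the remaining
#' modes would only visit "Q" members).
#'
#' @param msa the cluster `gsa_msa` (assessed internally).
#' @param genome the genome.
#' @param schedule a [gsa_schedule()].
#' @param cfg,params,model see [run_mode()].
#' @return `list(msa=, report=, log=)` with the full visit log.
#' @export
run_schedule <- function(msa, genome, schedule = gsa_schedule(),
                         cfg = gsa_config(), params = score_params(),
                         model = splice_model()) {
  report <- assess_msa(msa, cfg, params)
  logs <- list()
  for (mode in schedule$modes) {
    before_msa <- msa
    before_report <- report
    before_nwsp <- report$cluster$nWSP
    cfg_mode <- cfg
    cfg_mode$max_rounds <- schedule$max_rounds
    step <- run_mode(msa, report, mode, genome, cfg_mode, params, model)
    if (step$report$cluster$nWSP < before_nwsp - cfg$nwsp_tolerance) {
      step$log$note <- paste0(step$log$note, "[pass reverted: nWSP drop]")
      logs[[length(logs) + 1L]] <- step$log
      msa <- before_msa
      report <- before_report
      next
    }
    msa <- step$msa
    report <- step$report
    logs[[length(logs) + 1L]] <- step$log
    any_change <- nrow(step$log) > 0 && any(step$log$accepted &
      step$log$old_digest != step$log$new_digest)
    no_q <- !any(report$members$label == "Q")
    if (!any_change && no_q) break
  }
  log <- if (length(logs)) do.call(rbind, logs) else NULL
  list(msa = msa, report = report, log = log)
}

#' Re-map a protein onto its genomic locus
#'
#' Used when an annotated protein disagrees non-trivially with the
#' translation of its recorded structure: the protein itself becomes a
#' single-sequence template for spliced alignment over the hinted locus,
#' and the resulting structure replaces the annotation.
#'
#' @param protein amino-acid string.
#' @param genome the genome.
#' @param locus_hint list with `contig`, `start`, `end`, `strand`.
#' @param cfg,params,model see [spliced_align()].
#' @param gene_id id for the re-mapped structure.
#' @return A [gene_structure()], or `NULL` (with a warning) if no
#'   positive-scoring alignment exists.
#' @export
remap_gene <- function(protein, genome, locus_hint, cfg = gsa_config(),
                       params = score_params(), model = splice_model(),
                       gene_id = "remapped") {
  genome <- as_genome(genome)
  clen <- nchar(genome[[locus_hint$contig]])
  region <- list(contig = locus_hint$contig,
                 start = max(0L, locus_hint$start - cfg$flank_margin),
                 end = min(clen, locus_hint$end + cfg$flank_margin),
                 strand = locus_hint$strand)
  tmpl <- annotated_protein(gene_id, protein)
  res <- spliced_align(tmpl, region, genome, model, params, cfg,
                       gene_id = gene_id)
  if (!res$ok) {
    warning("remap of ", gene_id, " found no positive-scoring alignment")
    return(NULL)
  }
  res$gene
}
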