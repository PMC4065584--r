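# Spliced alignment of genomic DNA against a protein or a generalized
# profile template, producing a refined gene structure.  Introns are
# canonical GT..AG only; frameshifts and in-frame stops are accommodated
# with heavy penalties and recorded as defect events.

#' Splice model
#'
#' @param min_intron_len minimal intron length (nt, default 30).
#' @param intron_open,intron_logext intron penalty
#'   `intron_open + intron_logext * log(length)` in score units.
#' @return An object of class `splice_model`.
#' @export
splice_model <- function(min_intron_len = 30L, intron_open = 8,
                         intron_logext = 1) {
  structure(list(min_intron_len = as.integer(min_intron_len),
                 intron_open = intron_open, intron_logext = intron_logext),
            class = "splice_model")
}

#' Select the genomic window for re-predicting a gene
#'
#' The gene span extended by `flank_margin` on each side; a terminal
#' 5'/3' deletion flag doubles the margin on that side (the alignment
#' suggested missing sequence there).  Clipped to contig bounds.
#'
#' @param gene a [gene_structure()].
#' @param genome the genome.
#' @param cfg a [gsa_config()].
#' @param flag5,flag3 terminal-deletion flags from the assessment.
#' @return list with `contig`, `start`, `end` (0-based half-open),
#'   `strand`.
#' @export
select_target_region <- function(gene, genome, cfg = gsa_config(),
                                 flag5 = FALSE, flag3 = FALSE) {
  genome <- as_genome(genome)
  if (!gene$contig %in% names(genome))
    stop("contig ", gene$contig, " not in genome")
  clen <- nchar(genome[[gene$contig]])
  span <- c(min(gene$exons[, 1]), max(gene$exons[, 2]))
  m5 <- cfg$flank_margin * (1L + as.integer(flag5))
  m3 <- cfg$flank_margin * (1L + as.integer(flag3))
  if (gene$strand == "+") {
    start <- span[1] - m5; end <- span[2] + m3
  } else {
    start <- span[1] - m3; end <- span[2] + m5
  }
  list(contig = gene$contig, start = max(0L, start),
       end = min(clen, end), strand = gene$strand)
}

# template -> column scores / bonus / per-column deletion costs used by
# the spliced DP; template is an annotated_protein or a gsa_profile.
# Profile columns occupied by fewer than `min_occ` of the members are
# dropped: they stem from isolated insertions (often annotation errors
# under refinement) and would otherwise offer nearly free deletions that
# attract intronic sequence of the gene being re-predicted.
template_arrays <- function(template, params, min_occ = 0.5) {
  M <- params$matrix
  aa <- aa_alphabet()
  if (inherits(template, "annotated_protein")) {
    chars <- strsplit(template$residues, "")[[1]]
    P <- length(chars)
    PS <- M[, match(chars, aa), drop = FALSE]
    bonus <- matrix(0, 3, P)
    ir <- template$introns
    if (nrow(ir) > 0) {
      for (r in seq_len(nrow(ir))) {
        j <- min(ir$aa_index[r] + 1L, P)
        bonus[ir$phase[r] + 1L, j] <- params$intron_bonus
      }
    }
    occ <- rep(1, P)
  } else if (inherits(template, "gsa_profile")) {
    W <- max(template$weight, 1e-12)
    occ <- template$occ / W
    keep <- occ >= min_occ
    if (!any(keep)) keep <- occ >= max(occ) / 2
    fr <- template$freq[, keep, drop = FALSE] / W
    PS <- M %*% fr
    bonus <- params$intron_bonus * template$intron[, keep, drop = FALSE] / W
    occ <- occ[keep]
    P <- ncol(fr)
  } else stop("template must be an annotated_protein or a gsa_profile")
  list(PS = PS, bonus = bonus,
       pg_open = params$gap_open * occ,
       pg_ext = params$gap_ext * occ, P = P)
}

is_stop_codon <- function(chars) {
  paste(chars, collapse = "") %in% c("TAA", "TAG", "TGA")
}

#' Spliced alignment of a genomic window against a template
#'
#' Dynamic programming over exon/intron/gap states: translated codons are
#' scored against the template columns, introns are allowed only at
#' GT..AG with length >= `min_intron_len` and cost affine in log-length,
#' and a predicted intron whose (template residue, phase) coincides with
#' a template intron earns the intron bonus (scaled by the template's
#' intron frequency for profiles).  Frameshifts (codons of 3 +/- 1 or 2
#' nt) and in-frame stops are admitted with heavy penalties and recorded
#' as events.  The alignment is global in the template and local in the
#' window; a stop codon immediately after the last exon is absorbed into
#' it.
#'
#' @param template an [annotated_protein()] or a `gsa_profile`.
#' @param region window as returned by [select_target_region()].
#' @param genome the genome.
#' @param model a [splice_model()].
#' @param params scoring parameters from [score_params()].
#' @param cfg a [gsa_config()] (frameshift/stop penalties).
#' @param allow_frameshifts permit frameshifted codons.
#' @param gene_id id given to the refined structure.
#' @return An object of class `spliced_alignment`: list with `ok`,
#'   `score`, `gene` (refined [gene_structure()], `source = "refined"`),
#'   `protein` (its translation), `events`, and
#'   `template_intron_matches`.
#' @export
spliced_align <- function(template, region, genome,
                          model = splice_model(),
                          params = score_params(), cfg = gsa_config(),
                          allow_frameshifts = TRUE,
                          gene_id = "refined") {
  genome <- as_genome(genome)
  ctg <- genome[[region$contig]]
  win <- toupper(substr(ctg, region$start + 1L, region$end))
  chars <- strsplit(win, "")[[1]]
  if (region$strand == "-") chars <- revcomp_chars(chars)
  if (length(chars) < 3) stop("window shorter than 3 nt")

  ta <- template_arrays(template, params)
  r <- .spliced_core(encode_nt(chars), codon_aa_table(), ta$PS, ta$bonus,
                     ta$pg_open, ta$pg_ext,
                     params$gap_open, params$gap_ext,
                     cfg$fs_pen, cfg$stop_pen, allow_frameshifts,
                     model$intron_open, model$intron_logext,
                     model$min_intron_len)
  empty <- list(ok = FALSE, score = if (is.null(r$score)) -Inf else r$score,
                gene = NULL, protein = NULL,
                events = list(), template_intron_matches = 0L)
  class(empty) <- "spliced_alignment"
  if (!isTRUE(r$ok) || r$score <= 0 || length(r$exon_start) == 0)
    return(empty)

  ex_s <- r$exon_start; ex_e <- r$exon_end
  # absorb a terminal stop codon into the last exon
  last <- length(ex_e)
  if (ex_e[last] + 3L <= length(chars) &&
      is_stop_codon(chars[(ex_e[last] + 1L):(ex_e[last] + 3L)])) {
    ex_e[last] <- ex_e[last] + 3L
  }
  # window coordinates -> contig coordinates
  wlen <- length(chars)
  if (region$strand == "+") {
    g_s <- region$start + ex_s
    g_e <- region$start + ex_e
    fs_pos <- region$start + r$fs_pos
  } else {
    g_s <- region$end - ex_e
    g_e <- region$end - ex_s
    fs_pos <- region$end - 1L - r$fs_pos
  }
  fs <- data.frame(pos = as.integer(fs_pos), offset = as.integer(r$fs_off))
  gene <- gene_structure(gene_id = gene_id,
                         genome_id = NA_character_,
                         contig = region$contig, strand = region$strand,
                         exons = cbind(as.integer(g_s), as.integer(g_e)),
                         frameshift_events = fs, source = "refined")
  protein <- translate_cds(gene, genome)
  protein$protein_id <- gene_id
  events <- list()
  if (nrow(fs) > 0) events$frameshifts <- fs
  if (protein$defects$n_premature_stops > 0)
    events$premature_stops <- protein$defects$n_premature_stops
  structure(list(ok = TRUE, score = r$score, gene = gene,
                 protein = protein, events = events,
                 template_intron_matches = r$n_template_intron_matches),
            class = "spliced_alignment")
}

#' @export
print.spliced_alignment <- function(x, ...) {
  if (!x$ok) { cat("spliced_alignment: no positive-scoring path\n") }
  else {
    cat("spliced_alignment: score", format(x$score), "with",
        nrow(x$gene$exons), "exon(s),",
        x$template_intron_matches, "template intron match(es)\n")
  }
  invisible(x)
}

#' Choose the re-prediction template for a member
#'
#' Template selection modes: `"CR"` (closest reliable) picks the
#' R-labelled member with the highest percent identity to the query
#' (ties broken lexicographically); `"PR"` (reliable profile) builds the
#' generalized profile of all R members; `"M1"` (minus one) builds the
#' profile of every member except the query.
#'
#' @param q_id query member id.
#' @param msa the cluster `gsa_msa`.
#' @param report a `gsa_assessment` of `msa`.
#' @param mode `"CR"`, `"PR"`, or `"M1"`.
#' @return An [annotated_protein()] (CR) or `gsa_profile` (PR, M1).
#' @export
choose_template <- function(q_id, msa, report, mode = c("CR", "PR", "M1")) {
  mode <- match.arg(mode)
  if (mode == "M1") {
    rest <- setdiff(msa$ids, q_id)
    if (length(rest) == 0) stop("no other members for M1 template")
    m <- new_msa(rest, msa$aln[rest, , drop = FALSE], msa$introns[rest],
                 proteins = msa$proteins[rest], seq_w = msa$seq_w)
    m <- drop_allgap_columns(m)
    return(build_profile(m, seq_w = msa$seq_w))
  }
  rmem <- setdiff(report$members$id[report$members$label == "R"], q_id)
  if (length(rmem) == 0) stop("no reliable template: zero R members")
  if (mode == "CR") {
    pid <- vapply(rmem, function(o) msa_pid(msa, q_id, o), numeric(1))
    best <- rmem[order(-pid, rmem)][1]
    return(msa$proteins[[best]])
  }
  m <- new_msa(rmem, msa$aln[rmem, , drop = FALSE], msa$introns[rmem],
               proteins = msa$proteins[rmem], seq_w = msa$seq_w)
  m <- drop_allgap_columns(m)
  build_profile(m, seq_w = msa$seq_w)
}
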