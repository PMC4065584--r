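#' Analysis configuration
#'
#' Collects the tunable parameters of the pipeline.  Defaults follow the
#' settings used for the cytochrome P450 study conditions: proteins must be
#' longer than 400 residues (`min_protein_len = 0` disables the length
#' filter, the ribosomal-protein setting), gene regions with 10 or more
#' ambiguous nucleotides are dropped, the UPGMA tree is cut at 120 PAM,
#' clusters hold between 3 and 50 members, and a member becomes a
#' pseudogene candidate at `max_defect = 2` defect points.
#'
#' @param min_protein_len proteins of length `<= min_protein_len` are
#'   filtered out; 0 disables the filter.
#' @param max_ambiguous_nt genes whose genomic span contains at least this
#'   many `N`s are filtered out.
#' @param max_height tree-cutting height in PAM units.
#' @param max_cluster maximal cluster size after cutting.
#' @param min_cluster minimal cluster size; smaller subtrees go unclustered.
#' @param max_defect defect-point threshold separating "Q" from "P".
#' @param alpha significance level of the Dixon outlier test.
#' @param gap_open,gap_ext affine gap penalties (positive costs) of the
#'   protein alignment; a gap of length L costs
#'   `gap_open + gap_ext * L`.
#' @param gap_open2,gap_ext2 optional second affine regime for long gaps
#'   (`gap_open2 >= gap_open`, `gap_ext2 <= gap_ext`); `NULL` disables it.
#' @param intron_bonus score bonus b for a pair of introns aligned at the
#'   same column with the same phase; default 2x the average positive
#'   entry of the substitution matrix.
#' @param min_intron_len minimal intron length (nt) of the splice model.
#' @param intron_open,intron_logext intron penalty `intron_open +
#'   intron_logext * log(length)` in score units.
#' @param fs_pen,stop_pen penalties for a frameshifted codon and an
#'   in-frame stop codon kept inside an exon; defaults `2 * gap_open` and
#'   twice the magnitude of the worst substitution score.
#' @param flank_margin nt added on each side of a gene span when selecting
#'   the genomic window for re-prediction; doubled on a side with a
#'   terminal-deletion flag.
#' @param max_rounds cap on refinement sweeps (both within the aligner's
#'   iterative refinement and within a template mode pass).
#' @param block_window,block_theta,block_max_gap conserved-block search:
#'   minimal run length, column-score threshold (default half the average
#'   positive substitution score), and maximal gap fraction.
#' @param ambiguous_per_residue if `TRUE`, every ambiguous residue counts
#'   as its own defect event; default counts one event per gene.
#' @param nwsp_tolerance maximal drop in cluster nWSP tolerated before a
#'   whole refinement pass is reverted.
#' @param kmer k-mer size of the alignment-free distance.
#' @return An object of class `gsa_config` (a list).
#' @export
gsa_config <- function(min_protein_len = 400L,
                       max_ambiguous_nt = 10L,
                       max_height = 120,
                       max_cluster = 50L,
                       min_cluster = 3L,
                       max_defect = 2L,
                       alpha = 0.1,
                       gap_open = 11,
                       gap_ext = 1,
                       gap_open2 = NULL,
                       gap_ext2 = NULL,
                       intron_bonus = NULL,
                       min_intron_len = 30L,
                       intron_open = 8,
                       intron_logext = 1,
                       fs_pen = NULL,
                       stop_pen = NULL,
                       flank_margin = 3000L,
                       max_rounds = 3L,
                       block_window = 6L,
                       block_theta = NULL,
                       block_max_gap = 0.2,
                       ambiguous_per_residue = FALSE,
                       nwsp_tolerance = 0.1,
                       kmer = 3L) {
  m <- sub_matrix()
  if (is.null(intron_bonus)) intron_bonus <- 2 * avg_positive_score(m)
  if (is.null(fs_pen)) fs_pen <- 2 * gap_open
  if (is.null(stop_pen)) stop_pen <- 2 * abs(min(m[1:20, 1:20]))
  if (is.null(block_theta)) block_theta <- avg_positive_score(m) / 2
  stopifnot(min_protein_len >= 0, max_ambiguous_nt >= 0,
            max_cluster >= 1, min_cluster >= 2,
            alpha > 0, alpha < 1, max_defect >= 0,
            gap_open >= 0, gap_ext >= 0, min_intron_len >= 4,
            max_rounds >= 1)
  if (!is.null(gap_open2)) {
    stopifnot(gap_open2 >= gap_open, !is.null(gap_ext2),
              gap_ext2 <= gap_ext)
  }
  structure(list(
    min_protein_len = as.integer(min_protein_len),
    max_ambiguous_nt = as.integer(max_ambiguous_nt),
    max_height = max_height,
    max_cluster = as.integer(max_cluster),
    min_cluster = as.integer(min_cluster),
    max_defect = as.integer(max_defect),
    alpha = alpha,
    gap_open = gap_open, gap_ext = gap_ext,
    gap_open2 = gap_open2, gap_ext2 = gap_ext2,
    intron_bonus = intron_bonus,
    min_intron_len = as.integer(min_intron_len),
    intron_open = intron_open, intron_logext = intron_logext,
    fs_pen = fs_pen, stop_pen = stop_pen,
    flank_margin = as.integer(flank_margin),
    max_rounds = as.integer(max_rounds),
    block_window = as.integer(block_window),
    block_theta = block_theta,
    block_max_gap = block_max_gap,
    ambiguous_per_residue = isTRUE(ambiguous_per_residue),
    nwsp_tolerance = nwsp_tolerance,
    kmer = as.integer(kmer)
  ), class = "gsa_config")
}

#' Scoring-parameter bundle derived from a config
#'
#' Attaches the substitution matrix to the gap/intron parameters so the
#' alignment routines need only one object.
#'
#' @param cfg a [gsa_config()].
#' @return A list of scoring parameters.
#' @export
score_params <- function(cfg = gsa_config()) {
  list(matrix = sub_matrix(),
       gap_open = cfg$gap_open, gap_ext = cfg$gap_ext,
       gap_open2 = cfg$gap_open2, gap_ext2 = cfg$gap_ext2,
       intron_bonus = cfg$intron_bonus,
       fs_pen = cfg$fs_pen, stop_pen = cfg$stop_pen,
       intron_open = cfg$intron_open, intron_logext = cfg$intron_logext,
       min_intron_len = cfg$min_intron_len)
}
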