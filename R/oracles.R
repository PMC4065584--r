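# Independent validation oracles: exhaustive enumeration counterparts of
# the alignment DPs and a direct-definition UPGMA.  These recompute
# results by different algorithms than the production code and exist to
# verify it; they are exponential-time and only usable on tiny inputs.

#' Exhaustive pairwise alignment score (enumeration oracle)
#'
#' Recursively enumerates every global alignment of two short sequences
#' under affine gap costs (first gap column costs open + ext) plus the
#' intron-position bonus, and returns the best score.  Exponential; use
#' only for sequences of length <= 8.
#'
#' @param seqA,seqB amino-acid strings.
#' @param params scoring parameters from [score_params()].
#' @param intronsA,intronsB optional intron marks
#'   (data.frame `aa_index`, `phase`).
#' @return Best alignment score.
#' @export
enum_align_score <- function(seqA, seqB, params = score_params(),
                             intronsA = NULL, intronsB = NULL) {
  a <- strsplit(seqA, "")[[1]]
  b <- strsplit(seqB, "")[[1]]
  S <- params$matrix[a, b, drop = FALSE]
  add_bonus <- function(S, ia, ib) {
    if (is.null(ia) || is.null(ib) || nrow(ia) == 0 || nrow(ib) == 0)
      return(S)
    for (u in seq_len(nrow(ia))) for (v in seq_len(nrow(ib))) {
      if (ia$phase[u] == ib$phase[v]) {
        i <- min(ia$aa_index[u] + 1L, length(a))
        j <- min(ib$aa_index[v] + 1L, length(b))
        S[i, j] <- S[i, j] + params$intron_bonus
      }
    }
    S
  }
  S <- add_bonus(S, intronsA, intronsB)
  .enum_pair_align(S, params$gap_open, params$gap_ext)
}

# production counterpart on the same inputs (single sequences)
single_pair_align <- function(seqA, seqB, params = score_params(),
                              intronsA = NULL, intronsB = NULL) {
  mk <- function(s, ir) {
    if (is.null(ir)) ir <- data.frame(aa_index = integer(), phase = integer())
    msa_from_protein(annotated_protein("q", s, introns = ir))
  }
  a <- mk(seqA, intronsA)
  b <- mk(seqB, intronsB)
  align_groups(build_profile(a), build_profile(b), params)
}

#' Exhaustive spliced-alignment score (structure-enumeration oracle)
#'
#' Enumerates every window start and every compatible chain of GT..AG
#' introns, scores each implied spliced CDS against the template by a
#' plain affine codon-level alignment (junction codons forced to match),
#' and returns the best total.  Frameshifts are not modelled; only
#' usable on windows of a few dozen nt.
#'
#' @param window nucleotide string.
#' @param template an [annotated_protein()] or `gsa_profile`.
#' @param model a [splice_model()].
#' @param params scoring parameters.
#' @param cfg a [gsa_config()] (stop penalty).
#' @return Best spliced alignment score.
#' @export
enum_spliced_score <- function(window, template, model = splice_model(),
                               params = score_params(), cfg = gsa_config()) {
  chars <- strsplit(toupper(window), "")[[1]]
  ta <- template_arrays(template, params)
  .enum_spliced(encode_nt(chars), codon_aa_table(), ta$PS, ta$bonus,
                ta$pg_open, ta$pg_ext, params$gap_open, params$gap_ext,
                cfg$stop_pen, model$intron_open, model$intron_logext,
                model$min_intron_len)
}

#' Direct-definition UPGMA (naive oracle)
#'
#' At every step the distance between two clusters is recomputed from
#' scratch as the mean of all original leaf-pair distances (the UPGMA
#' definition), instead of the incremental update used by [upgma()].
#' Same tie-breaking.
#'
#' @param dm symmetric distance matrix.
#' @return A `gsa_tree`.
#' @export
upgma_oracle <- function(dm) {
  n <- nrow(dm)
  ids <- rownames(dm)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  clusters <- lapply(seq_len(n), function(i) i)
  trees <- lapply(ids, tree_leaf)
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- Inf; bi <- 1L; bj <- 2L
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      d <- mean(dm[clusters[[i]], clusters[[j]]])
      if (d < best - 1e-12) { best <- d; bi <- i; bj <- j }
    }
    trees[[bi]] <- tree_node(trees[[bi]], trees[[bj]], best / 2)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    trees <- trees[-bj]; clusters <- clusters[-bj]
  }
  trees[[1]]
}

#' Canonical string form of a guide tree (for topology comparison)
#' @param tree a `gsa_tree`.
#' @param digits height rounding.
#' @return Character scalar unique up to child order.
#' @export
tree_canonical <- function(tree, digits = 6) {
  rec <- function(node) {
    if (node$leaf) return(node$id)
    kids <- sort(vapply(node$children, rec, character(1)))
    paste0("(", kids[1], ",", kids[2], "):",
           format(round(node$height, digits), nsmall = digits))
  }
  rec(tree)
}

#' Exon-level F-measure of predicted against true gene structures
#'
#' An exon counts as correct only with exactly matching genomic
#' coordinates.  Returns sensitivity, specificity (precision), and the
#' F-measure over the union of genes.
#'
#' @param pred_genes,true_genes named lists of [gene_structure()];
#'   compared by shared names.
#' @return list with `sn`, `sp`, `f`.
#' @export
exon_f_measure <- function(pred_genes, true_genes) {
  tp <- 0L; np <- 0L; nt <- 0L
  for (id in names(true_genes)) {
    tr <- true_genes[[id]]
    pr <- pred_genes[[id]]
    tkey <- paste(tr$exons[, 1], tr$exons[, 2])
    nt <- nt + length(tkey)
    if (is.null(pr)) next
    pkey <- paste(pr$exons[, 1], pr$exons[, 2])
    np <- np + length(pkey)
    tp <- tp + sum(pkey %in% tkey)
  }
  sn <- if (nt > 0) tp / nt else NA_real_
  sp <- if (np > 0) tp / np else NA_real_
  f <- if (!is.na(sn) && !is.na(sp) && sn + sp > 0)
    2 * sn * sp / (sn + sp) else 0
  list(sn = sn, sp = sp, f = f)
}
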