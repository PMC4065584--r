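# Convenience drivers tying the modules together.

#' Cluster a set of annotated proteins
#'
#' All-by-all k-mer distances, optional PAM rescaling (skipped when there
#' are fewer than 20 pairs to calibrate on), UPGMA, and tree cutting.
#'
#' @param proteins named list of [annotated_protein()]s.
#' @param cfg a [gsa_config()].
#' @param pam_rescaled rescale distances to PAM before cutting.
#' @return `list(clusters=, unclustered=, tree=, dist=)`.
#' @export
build_clusters <- function(proteins, cfg = gsa_config(),
                           pam_rescaled = TRUE) {
  seqs <- vapply(proteins, function(p) p$residues, character(1))
  dm <- kmer_distance_matrix(seqs, cfg$kmer)
  n <- length(seqs)
  if (pam_rescaled && n * (n - 1) / 2 >= 20) {
    dm <- pam_rescale(dm, seqs)
  } else {
    dm <- dm * 300  # keep everything on a roughly comparable scale
  }
  tree <- upgma(dm)
  cut <- cut_tree(tree, cfg)
  list(clusters = cut$clusters, unclustered = cut$unclustered,
       tree = tree, dist = dm)
}

#' Build the gene-structure-aware alignment of one cluster
#'
#' Progressive alignment along the cluster's guide subtree followed by
#' restricted-partitioning refinement.
#'
#' @param cluster cluster from [build_clusters()] (or any list with
#'   `members` and `tree`).
#' @param proteins named list of [annotated_protein()]s.
#' @param cfg a [gsa_config()].
#' @param params scoring parameters.
#' @return A refined `gsa_msa`.
#' @export
align_cluster <- function(cluster, proteins, cfg = gsa_config(),
                          params = score_params()) {
  msa <- progressive_align(proteins[cluster$members], cluster$tree, params)
  iterate_refine(msa, params, max_rounds = cfg$max_rounds)
}
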