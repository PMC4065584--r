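# Clustering of homologous annotated proteins: alignment-free distances,
# PAM rescaling by polynomial regression against pairwise alignments,
# UPGMA guide tree, height/size-based tree cutting, and de-duplication of
# isoforms from the same locus.

#' k-mer cosine distance between two protein sequences
#'
#' `1 - cosine similarity` of k-mer count vectors; a fast alignment-free
#' proxy for evolutionary distance.  Lies in `[0, 1]` and is 0 for
#' identical sequences.
#'
#' @param a,b amino-acid strings.
#' @param k k-mer size (default 3).
#' @return Numeric distance.
#' @export
kmer_distance <- function(a, b, k = 3L) {
  if (nchar(a) < k || nchar(b) < k)
    stop("sequences must be at least k = ", k, " residues long")
  count <- function(s) {
    n <- nchar(s) - k + 1L
    table(substring(s, seq_len(n), seq_len(n) + k - 1L))
  }
  ca <- count(a); cb <- count(b)
  keys <- union(names(ca), names(cb))
  va <- as.numeric(ca[keys]); va[is.na(va)] <- 0
  vb <- as.numeric(cb[keys]); vb[is.na(vb)] <- 0
  sim <- sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
  max(0, min(1, 1 - sim))
}

#' All-by-all k-mer distance matrix
#' @param seqs named character vector of protein sequences.
#' @param k k-mer size.
#' @return Symmetric matrix with zero diagonal.
#' @export
kmer_distance_matrix <- function(seqs, k = 3L) {
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- kmer_distance(seqs[[i]], seqs[[j]], k)
  }
  d
}

# Kimura-corrected PAM estimate from the fraction of differing residues
# of a pairwise alignment.
kimura_pam <- function(p) {
  p <- min(p, 0.85)
  d <- -log(1 - p - 0.2 * p^2)
  min(300, 100 * d)
}

#' Rescale alignment-free distances to PAM units
#'
#' Fits a cubic polynomial through the origin mapping the alignment-free
#' distance to PAM estimated from Kimura-corrected pairwise alignments of
#' a calibration subsample, applies it to the whole matrix, clamps to
#' `[0, 300]`, and enforces monotonicity by an isotonic post-step.
#'
#' @param dm symmetric alignment-free distance matrix.
#' @param seqs named protein sequences matching `rownames(dm)`.
#' @param n_calib number of calibration pairs to align (at least 20 are
#'   required).
#' @param seed seed for the calibration subsample.
#' @return Distance matrix in PAM units.
#' @export
pam_rescale <- function(dm, seqs, n_calib = 100L, seed = 1L) {
  ids <- rownames(dm)
  n <- length(ids)
  pairs <- which(upper.tri(dm), arr.ind = TRUE)
  if (nrow(pairs) < 20L)
    stop("need at least 20 calibration pairs (", nrow(pairs), " available)")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  take <- sample(nrow(pairs), min(n_calib, nrow(pairs)))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  x <- numeric(0); y <- numeric(0)
  m62 <- sub_matrix()[1:20, 1:20]
  for (r in take) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    al <- Biostrings::pairwiseAlignment(
      gsub("X", "A", seqs[[ids[i]]]), gsub("X", "A", seqs[[ids[j]]]),
      substitutionMatrix = m62, gapOpening = 11, gapExtension = 1)
    p <- 1 - Biostrings::pid(al, type = "PID2") / 100
    x <- c(x, dm[i, j]); y <- c(y, kimura_pam(p))
  }
  if (max(x) - min(x) < 1e-12) {
    if (max(y) < 1e-9) stop("degenerate calibration: all sequences identical")
    stop("degenerate calibration: alignment-free distances are constant")
  }
  fit <- stats::lm(y ~ 0 + x + I(x^2) + I(x^3))
  vals <- dm[upper.tri(dm)]
  pred <- pmin(300, pmax(0, stats::predict(fit, data.frame(x = vals))))
  # isotonic correction in the order of the input distances
  o <- order(vals)
  iso <- stats::isoreg(seq_along(o), pred[o])$yf
  pred[o] <- iso
  out <- dm
  out[upper.tri(out)] <- pred
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  diag(out) <- 0
  out
}

# ---------------------------------------------------------------------------
# UPGMA guide tree.  Nodes are nested lists: leaves carry `id`, internal
# nodes carry `children` (two subtrees); every node has `height` (PAM/2
# scale: a merge at distance d sits at height d/2) and `ids`.

tree_leaf <- function(id) {
  structure(list(leaf = TRUE, id = id, ids = id, height = 0),
            class = "gsa_tree")
}

tree_node <- function(a, b, height) {
  structure(list(leaf = FALSE, children = list(a, b),
                 ids = c(a$ids, b$ids), height = height),
            class = "gsa_tree")
}

#' UPGMA guide tree from a distance matrix
#'
#' Average-linkage agglomeration; a merge at distance d creates a node at
#' height d/2, so leaf-to-root heights are ultrametric.  Ties are broken
#' by the smallest index pair in the current cluster ordering.
#'
#' @param dm symmetric distance matrix with ids as dimnames.
#' @return An object of class `gsa_tree`.
#' @export
upgma <- function(dm) {
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  n <- nrow(dm)
  stopifnot(n >= 2)
  ids <- rownames(dm)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  act <- lapply(ids, tree_leaf)
  sizes <- rep(1L, n)
  d <- dm
  while (length(act) > 1) {
    m <- length(act)
    bi <- 1L; bj <- 2L; best <- Inf
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      if (d[i, j] < best - 1e-12) { best <- d[i, j]; bi <- i; bj <- j }
    }
    node <- tree_node(act[[bi]], act[[bj]], best / 2)
    newd <- (sizes[bi] * d[bi, ] + sizes[bj] * d[bj, ]) /
      (sizes[bi] + sizes[bj])
    d[bi, ] <- newd; d[, bi] <- newd; d[bi, bi] <- 0
    act[[bi]] <- node
    sizes[bi] <- sizes[bi] + sizes[bj]
    act <- act[-bj]; sizes <- sizes[-bj]
    d <- d[-bj, -bj, drop = FALSE]
  }
  act[[1]]
}

#' @export
print.gsa_tree <- function(x, ...) {
  cat("gsa_tree:", length(x$ids), "leaves, height", format(x$height), "\n")
  invisible(x)
}

tree_leaves <- function(tree) tree$ids

#' Newick export of a guide tree (with branch lengths from node heights)
#' @param tree a `gsa_tree`.
#' @return Newick string.
#' @export
as_newick <- function(tree) {
  rec <- function(node, parent_h) {
    bl <- format(parent_h - node$height, digits = 10)
    if (node$leaf) return(paste0(node$id, ":", bl))
    paste0("(", rec(node$children[[1]], node$height), ",",
           rec(node$children[[2]], node$height), "):", bl)
  }
  if (tree$leaf) return(paste0(tree$id, ";"))
  paste0("(", rec(tree$children[[1]], tree$height), ",",
         rec(tree$children[[2]], tree$height), ");")
}

#' Cut a guide tree into clusters
#'
#' All edges crossing `max_height` are cut; any resulting subtree larger
#' than `max_cluster` is recursively split at its root; subtrees smaller
#' than `min_cluster` go to the unclustered pool.
#'
#' @param tree a `gsa_tree` from [upgma()].
#' @param cfg a [gsa_config()] (uses `max_height`, `max_cluster`,
#'   `min_cluster`).
#' @return `list(clusters=, unclustered=)`; each cluster is a list with
#'   `members`, `tree`, and `cut_height`.
#' @export
cut_tree <- function(tree, cfg = gsa_config()) {
  by_height <- list()
  rec_h <- function(node) {
    if (node$height <= cfg$max_height || node$leaf) {
      by_height[[length(by_height) + 1L]] <<- node
    } else {
      rec_h(node$children[[1]])
      rec_h(node$children[[2]])
    }
  }
  rec_h(tree)
  final <- list()
  rec_s <- function(node) {
    if (length(node$ids) <= cfg$max_cluster || node$leaf) {
      final[[length(final) + 1L]] <<- node
    } else {
      rec_s(node$children[[1]])
      rec_s(node$children[[2]])
    }
  }
  for (sub in by_height) rec_s(sub)
  clusters <- list()
  unclustered <- character(0)
  for (sub in final) {
    if (length(sub$ids) >= cfg$min_cluster) {
      clusters[[length(clusters) + 1L]] <-
        list(members = sub$ids, tree = sub, cut_height = sub$height)
    } else {
      unclustered <- c(unclustered, sub$ids)
    }
  }
  list(clusters = clusters, unclustered = unclustered)
}

#' Remove minor isoforms from a cluster
#'
#' Members mapping to the same genomic locus are isoforms of one gene;
#' only the major isoform -- the one with the highest average percent
#' identity (on the cluster alignment) to the members outside its locus --
#' is kept.  Ties prefer the longest sequence, then the lexicographically
#' smallest id.
#'
#' @param cluster cluster as returned by [cut_tree()].
#' @param msa the cluster [gsa_msa] alignment.
#' @param locus_map named character vector mapping member id -> locus id.
#' @return The cluster with minor isoforms removed from `members`.
#' @export
remove_minor_isoforms <- function(cluster, msa, locus_map) {
  members <- cluster$members
  loci <- locus_map[members]
  keep <- character(0)
  for (loc in unique(loci)) {
    iso <- members[loci == loc]
    if (length(iso) == 1L) { keep <- c(keep, iso); next }
    others <- setdiff(members, iso)
    sim <- vapply(iso, function(id) {
      if (length(others) == 0) return(0)
      mean(vapply(others, function(o) msa_pid(msa, id, o), numeric(1)))
    }, numeric(1))
    len <- vapply(iso, function(id) {
      sum(msa$aln[id, ] != "-")
    }, numeric(1))
    o <- order(-sim, -len, iso)
    keep <- c(keep, iso[o[1]])
  }
  cluster$members <- members[members %in% keep]
  cluster
}
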