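# Gene-structure-aware multiple protein sequence alignment: rows carry
# intron marks (alignment column, phase); the objective is a weighted
# sum-of-pairs score with a bonus for intron positions aligned at the
# same column with the same phase.

new_msa <- function(ids, aln, introns, proteins = NULL, tree = NULL,
                    seq_w = NULL, pair_w = NULL) {
  rownames(aln) <- ids
  if (is.null(seq_w)) seq_w <- stats::setNames(rep(1, length(ids)), ids)
  structure(list(ids = ids, aln = aln, introns = introns,
                 proteins = proteins, tree = tree,
                 seq_w = seq_w, pair_w = pair_w),
            class = "gsa_msa")
}

#' @export
print.gsa_msa <- function(x, ...) {
  cat("gsa_msa:", length(x$ids), "rows x", ncol(x$aln), "columns,",
      sum(vapply(x$introns, nrow, integer(1))), "intron marks\n")
  invisible(x)
}

# single-row alignment from an annotated protein; intron mark columns are
# the 1-based columns of their host residues
msa_from_protein <- function(p) {
  chars <- strsplit(p$residues, "")[[1]]
  aln <- matrix(chars, nrow = 1)
  ir <- p$introns
  col <- pmin(pmax(ir$aa_index + 1L, 1L), length(chars))
  introns <- list(data.frame(column = col, phase = ir$phase))
  names(introns) <- p$protein_id
  pl <- list(p); names(pl) <- p$protein_id
  new_msa(p$protein_id, aln, introns, proteins = pl)
}

#' Build a generalized profile from (a subset of) an alignment
#'
#' Column-wise weighted residue counts, deletion weight, and intron
#' weight per phase; the raw material both for profile-profile alignment
#' and for spliced-alignment templates.
#'
#' @param msa a `gsa_msa`.
#' @param members subset of row ids (default all).
#' @param seq_w named per-sequence weights (default the alignment's).
#' @return A `gsa_profile`: list with `freq` (21 x L weighted residue
#'   counts), `del` (weighted gap counts), `intron` (3 x L weighted
#'   intron counts by phase), `occ` (weighted residue occupancy), and
#'   `weight` (total weight).
#' @export
build_profile <- function(msa, members = msa$ids, seq_w = NULL) {
  if (length(members) == 0) stop("empty member subset")
  if (is.null(seq_w)) seq_w <- msa$seq_w
  w <- seq_w[members]
  if (all(w <= 0)) w[] <- 1
  aa <- aa_alphabet()
  L <- ncol(msa$aln)
  freq <- matrix(0, 21, L, dimnames = list(aa, NULL))
  del <- numeric(L)
  intron <- matrix(0, 3, L)
  for (id in members) {
    row <- msa$aln[id, ]
    wi <- w[[id]]
    gap <- row == "-"
    del[gap] <- del[gap] + wi
    for (u in which(!gap)) {
      freq[match(row[u], aa), u] <- freq[match(row[u], aa), u] + wi
    }
    ir <- msa$introns[[id]]
    if (nrow(ir) > 0) {
      for (r in seq_len(nrow(ir))) {
        intron[ir$phase[r] + 1L, ir$column[r]] <-
          intron[ir$phase[r] + 1L, ir$column[r]] + wi
      }
    }
  }
  structure(list(freq = freq, del = del, intron = intron,
                 occ = colSums(freq), weight = sum(w), members = members),
            class = "gsa_profile")
}

#' Align two generalized profiles
#'
#' Affine-gap (optionally double-affine) profile-profile dynamic
#' programming.  The column-pair score is the weighted cross-group
#' substitution sum plus `intron_bonus` for every cross-group pair of
#' introns at the same column with the same phase; gap costs against a
#' profile column scale with its weighted residue occupancy.  Ties prefer
#' the diagonal, then deletions, then insertions.
#'
#' @param profA,profB `gsa_profile`s from [build_profile()].
#' @param params scoring parameters from [score_params()].
#' @return `list(ops=, score=)`; `ops` codes 1 = aligned columns, 2 =
#'   column of A against gap, 3 = column of B against gap.
#' @export
align_groups <- function(profA, profB, params = score_params()) {
  M <- params$matrix
  S <- t(profA$freq) %*% M %*% profB$freq +
    params$intron_bonus * (t(profA$intron) %*% profB$intron)
  openA <- params$gap_open * profA$occ * profB$weight
  extA <- params$gap_ext * profA$occ * profB$weight
  openB <- params$gap_open * profB$occ * profA$weight
  extB <- params$gap_ext * profB$occ * profA$weight
  da <- !is.null(params$gap_open2)
  if (da) {
    openA2 <- params$gap_open2 * profA$occ * profB$weight
    extA2 <- params$gap_ext2 * profA$occ * profB$weight
    openB2 <- params$gap_open2 * profB$occ * profA$weight
    extB2 <- params$gap_ext2 * profB$occ * profA$weight
  } else {
    openA2 <- extA2 <- numeric(length(openA))
    openB2 <- extB2 <- numeric(length(openB))
  }
  r <- .align_core(S, openA, extA, openB, extB, da,
                   openA2, extA2, openB2, extB2)
  list(ops = r$ops, score = r$score)
}

# combine two sub-alignments along an op path
merge_alignments <- function(msaA, msaB, ops) {
  L <- length(ops)
  ia <- 0L; ib <- 0L
  mapA <- integer(ncol(msaA$aln)); mapB <- integer(ncol(msaB$aln))
  colA <- integer(L); colB <- integer(L)
  for (k in seq_len(L)) {
    if (ops[k] != 3L) { ia <- ia + 1L; mapA[ia] <- k; colA[k] <- ia }
    if (ops[k] != 2L) { ib <- ib + 1L; mapB[ib] <- k; colB[k] <- ib }
  }
  nA <- length(msaA$ids); nB <- length(msaB$ids)
  aln <- matrix("-", nA + nB, L)
  aln[seq_len(nA), colA != 0L] <- msaA$aln[, , drop = FALSE]
  aln[nA + seq_len(nB), colB != 0L] <- msaB$aln[, , drop = FALSE]
  remap <- function(introns, map) {
    lapply(introns, function(df) {
      df$column <- map[df$column]
      df
    })
  }
  introns <- c(remap(msaA$introns, mapA), remap(msaB$introns, mapB))
  new_msa(c(msaA$ids, msaB$ids), aln, introns,
          proteins = c(msaA$proteins, msaB$proteins))
}

# Gerstein-Sonnhammer-Chothia-style sequence weights: each edge's length
# is shared equally among the leaves below it.
gsc_weights <- function(tree) {
  w <- stats::setNames(numeric(length(tree$ids)), tree$ids)
  rec <- function(node, inherited) {
    if (node$leaf) { w[node$id] <<- inherited; return(invisible()) }
    for (ch in node$children) {
      rec(ch, inherited + (node$height - ch$height) / length(ch$ids))
    }
  }
  rec(tree, 0)
  if (sum(w) <= 0) w[] <- 1
  w
}

#' Branch-proportional pair weights from a guide tree
#'
#' The weight of a sequence pair is the product of the two per-sequence
#' weights derived from the tree's branch lengths, normalized so the mean
#' over all pairs is 1; with equal branch lengths all pairs get weight 1,
#' and duplicated sequences (zero branches) are down-weighted.
#'
#' @param tree a `gsa_tree` covering all members.
#' @return Symmetric matrix of pair weights (diagonal 0).
#' @export
pair_weights <- function(tree) {
  w <- gsc_weights(tree)
  ids <- names(w)
  pw <- outer(w, w)
  diag(pw) <- 0
  n <- length(ids)
  if (n > 1) {
    mu <- sum(pw[upper.tri(pw)]) / (n * (n - 1) / 2)
    if (mu > 0) pw <- pw / mu else pw[] <- 1
    diag(pw) <- 0
  }
  dimnames(pw) <- list(ids, ids)
  pw
}

#' Progressive gene-structure-aware alignment along a guide tree
#'
#' Post-order merge of cluster members using [align_groups()]; intron
#' marks are remapped through inserted gaps, so the multiset of
#' (member, CDS position, phase) marks is conserved.
#'
#' @param proteins named list of [annotated_protein()]s.
#' @param tree guide `gsa_tree` whose leaves are the protein ids.
#' @param params scoring parameters.
#' @return A `gsa_msa` with tree, sequence and pair weights attached.
#' @export
progressive_align <- function(proteins, tree, params = score_params()) {
  seq_w <- gsc_weights(tree)
  rec <- function(node) {
    if (node$leaf) return(msa_from_protein(proteins[[node$id]]))
    a <- rec(node$children[[1]])
    b <- rec(node$children[[2]])
    pa <- build_profile(a, seq_w = seq_w)
    pb <- build_profile(b, seq_w = seq_w)
    al <- align_groups(pa, pb, params)
    merge_alignments(a, b, al$ops)
  }
  out <- rec(tree)
  out$tree <- tree
  out$seq_w <- seq_w
  out$pair_w <- pair_weights(tree)
  out$proteins <- out$proteins[out$ids]
  out
}

# affine gap cost of one run; with the double-affine option each run
# takes the cheaper regime
gap_run_cost <- function(len, params) {
  c1 <- params$gap_open + params$gap_ext * len
  if (!is.null(params$gap_open2))
    c1 <- pmin(c1, params$gap_open2 + params$gap_ext2 * len)
  c1
}

# substitution + gap + intron-bonus score of one row pair
pair_score <- function(rowA, rowB, intrA, intrB, params) {
  ga <- rowA == "-"; gb <- rowB == "-"
  keep <- !(ga & gb)
  a <- rowA[keep]; b <- rowB[keep]
  st <- ifelse(a == "-", 2L, ifelse(b == "-", 3L, 1L))
  s <- 0
  both <- st == 1L
  if (any(both)) s <- sum(params$matrix[cbind(a[both], b[both])])
  r <- rle(st)
  glen <- r$lengths[r$values != 1L]
  if (length(glen) > 0) s <- s - sum(gap_run_cost(glen, params))
  if (nrow(intrA) > 0 && nrow(intrB) > 0) {
    shared <- merge(intrA, intrB, by = c("column", "phase"))
    s <- s + params$intron_bonus * nrow(shared)
  }
  s
}

#' (Weighted) sum-of-pairs score of an alignment
#'
#' `SP` sums substitution, affine gap, and intron-bonus terms over all
#' row pairs; `WSP` weights each pair by the tree-derived pair weights.
#' The normalized versions `nSP`/`nWSP` divide by (number of pairs x
#' number of columns).
#'
#' @param msa a `gsa_msa`.
#' @param params scoring parameters.
#' @param weighted use pair weights (WSP) or not (SP).
#' @return Numeric score.
#' @export
wsp_score <- function(msa, params = score_params(), weighted = TRUE) {
  n <- length(msa$ids)
  if (n < 2) return(0)
  st <- msa_sp_stats(msa, params)
  if (weighted) st$wsp else st$sp
}

# integer-coded alignment (0..20 residues, -1 gap) plus flattened marks
msa_codes <- function(msa) {
  cd <- match(msa$aln, aa_alphabet())
  cd[is.na(cd)] <- 0L
  codes <- matrix(as.integer(cd - 1L), nrow = nrow(msa$aln))
  mk_row <- integer(0); mk_col <- integer(0); mk_ph <- integer(0)
  for (i in seq_along(msa$ids)) {
    df <- msa$introns[[msa$ids[i]]]
    if (!is.null(df) && nrow(df) > 0) {
      mk_row <- c(mk_row, rep(i - 1L, nrow(df)))
      mk_col <- c(mk_col, df$column)
      mk_ph <- c(mk_ph, df$phase)
    }
  }
  list(codes = codes, mk_row = mk_row, mk_col = mk_col, mk_ph = mk_ph)
}

# one C pass over all pairs: SP and WSP totals plus per-column weighted
# substitution scores (for conserved-block detection)
msa_sp_stats <- function(msa, params = score_params()) {
  n <- length(msa$ids)
  pw <- msa$pair_w
  if (is.null(pw)) {
    pw <- matrix(1, n, n); diag(pw) <- 0
  } else {
    pw <- pw[msa$ids, msa$ids, drop = FALSE]
  }
  mc <- msa_codes(msa)
  da <- !is.null(params$gap_open2)
  r <- .wsp_stats(mc$codes, pw, params$matrix,
                  params$gap_open, params$gap_ext, da,
                  if (da) params$gap_open2 else 0,
                  if (da) params$gap_ext2 else 0,
                  mc$mk_row, mc$mk_col, mc$mk_ph, params$intron_bonus)
  list(sp = r$sp, wsp = r$wsp, colscore = r$colscore,
       wtot = sum(pw[upper.tri(pw)]))
}

#' @rdname wsp_score
#' @export
nsp_score <- function(msa, params = score_params()) {
  n <- length(msa$ids)
  if (n < 2 || ncol(msa$aln) == 0) return(0)
  wsp_score(msa, params, weighted = FALSE) / (n * (n - 1) / 2 * ncol(msa$aln))
}

#' @rdname wsp_score
#' @export
nwsp_score <- function(msa, params = score_params()) {
  n <- length(msa$ids)
  if (n < 2 || ncol(msa$aln) == 0) return(0)
  wsp_score(msa, params, weighted = TRUE) / (n * (n - 1) / 2 * ncol(msa$aln))
}

# drop columns that are gaps in every row
drop_allgap_columns <- function(msa) {
  keep <- colSums(msa$aln != "-") > 0
  if (all(keep)) return(msa)
  map <- cumsum(keep)
  msa$aln <- msa$aln[, keep, drop = FALSE]
  msa$introns <- lapply(msa$introns, function(df) {
    df$column <- map[df$column]
    df
  })
  msa
}

# realign the two groups of a bipartition; returns the candidate msa
realign_partition <- function(msa, groupA, params) {
  groupB <- setdiff(msa$ids, groupA)
  subset_msa <- function(g) {
    m <- new_msa(g, msa$aln[g, , drop = FALSE], msa$introns[g],
                 proteins = msa$proteins[g], seq_w = msa$seq_w)
    drop_allgap_columns(m)
  }
  a <- subset_msa(groupA)
  b <- subset_msa(groupB)
  al <- align_groups(build_profile(a, seq_w = msa$seq_w),
                     build_profile(b, seq_w = msa$seq_w), params)
  out <- merge_alignments(a, b, al$ops)
  out <- new_msa(msa$ids, out$aln[msa$ids, , drop = FALSE],
                 out$introns[msa$ids], proteins = msa$proteins,
                 tree = msa$tree, seq_w = msa$seq_w, pair_w = msa$pair_w)
  out
}

# bipartitions to try: every single member plus every internal clade
refinement_partitions <- function(msa) {
  parts <- as.list(msa$ids)
  if (!is.null(msa$tree)) {
    rec <- function(node) {
      if (node$leaf) return(invisible())
      if (length(node$ids) < length(msa$ids)) {
        parts[[length(parts) + 1L]] <<- node$ids
      }
      for (ch in node$children) rec(ch)
    }
    rec(msa$tree)
  }
  parts[!duplicated(lapply(parts, function(p) paste(sort(p), collapse = "|")))]
}

#' Iterative restricted-partitioning refinement
#'
#' One outer pass of restricted partitioning: every member (and every
#' guide-tree bipartition) is split off and realigned against the rest;
#' a realignment is kept only if the weighted sum-of-pairs score does not
#' decrease.  Sweeps repeat until no strict improvement or `max_rounds`.
#'
#' @param msa a `gsa_msa`.
#' @param params scoring parameters.
#' @param max_rounds cap on inner sweeps.
#' @return The refined `gsa_msa` (WSP never lower than the input's).
#' @export
iterate_refine <- function(msa, params = score_params(), max_rounds = 3L,
                           partitions = NULL) {
  if (length(msa$ids) < 2) return(msa)
  cur <- drop_allgap_columns(msa)
  cur_wsp <- wsp_score(cur, params)
  parts <- if (is.null(partitions)) refinement_partitions(cur)
           else partitions
  for (round in seq_len(max_rounds)) {
    improved <- FALSE
    for (p in parts) {
      cand <- realign_partition(cur, p, params)
      cand_wsp <- wsp_score(cand, params)
      if (cand_wsp >= cur_wsp - 1e-9 &&
          !identical(cand$aln, cur$aln)) {
        if (cand_wsp > cur_wsp + 1e-9) improved <- TRUE
        else next  # equal score: keep current to guarantee termination
        cur <- cand
        cur_wsp <- cand_wsp
      }
    }
    if (!improved) break
  }
  cur
}

#' Update an alignment with revised members
#'
#' Rows with matching ids are removed, the revised members are aligned in
#' one by one against the profile of the remaining alignment, pair
#' weights are recomputed, and [iterate_refine()] is applied.
#'
#' @param msa a `gsa_msa`.
#' @param revised list of [annotated_protein()]s (ids may or may not be
#'   present in the alignment).
#' @param params scoring parameters.
#' @param refine_rounds sweeps of [iterate_refine()] after insertion.
#' @param refine_scope `"full"` sweeps every partition; `"revised"`
#'   realigns only the re-inserted members against the rest (the cheap
#'   choice for the inner loop of a refinement pass, where the rest of
#'   the alignment was already refined).
#' @return The updated `gsa_msa`.
#' @export
update_msa <- function(msa, revised, params = score_params(),
                       refine_rounds = 1L,
                       refine_scope = c("full", "revised")) {
  refine_scope <- match.arg(refine_scope)
  ids_rm <- vapply(revised, function(p) p$protein_id, character(1))
  remain <- setdiff(msa$ids, ids_rm)
  if (length(remain) == 0) stop("update would remove every member")
  cur <- new_msa(remain, msa$aln[remain, , drop = FALSE],
                 msa$introns[remain], proteins = msa$proteins[remain],
                 tree = msa$tree, seq_w = msa$seq_w, pair_w = msa$pair_w)
  cur <- drop_allgap_columns(cur)
  for (p in revised) {
    single <- msa_from_protein(p)
    al <- align_groups(build_profile(cur, seq_w = cur$seq_w),
                       build_profile(single), params)
    cur <- merge_alignments(cur, single, al$ops)
    cur$tree <- msa$tree
    cur$seq_w <- msa$seq_w
    cur$proteins[[p$protein_id]] <- p
  }
  ord <- intersect(c(msa$ids, setdiff(cur$ids, msa$ids)), cur$ids)
  cur <- new_msa(ord, cur$aln[ord, , drop = FALSE], cur$introns[ord],
                 proteins = cur$proteins[ord], tree = msa$tree,
                 seq_w = msa$seq_w, pair_w = msa$pair_w)
  if (!is.null(msa$tree) && setequal(ord, tree_leaves(msa$tree))) {
    cur$pair_w <- pair_weights(msa$tree)
    cur$seq_w <- gsc_weights(msa$tree)
  }
  parts <- if (refine_scope == "revised") as.list(ids_rm) else NULL
  iterate_refine(cur, params, max_rounds = refine_rounds,
                 partitions = parts)
}

# percent identity between two rows of an alignment
msa_pid <- function(msa, id1, id2) {
  a <- msa$aln[id1, ]; b <- msa$aln[id2, ]
  both <- a != "-" & b != "-"
  if (!any(both)) return(0)
  100 * sum(a[both] == b[both]) / sum(both)
}

#' Write / read an alignment with its intron marks
#'
#' The alignment is stored as gapped FASTA plus a sidecar TSV of intron
#' marks (`member`, `column` 1-based, `phase`).
#'
#' @param msa a `gsa_msa`.
#' @param fasta_path,tsv_path output paths.
#' @export
write_msa <- function(msa, fasta_path, tsv_path) {
  seqs <- Biostrings::AAStringSet(apply(msa$aln, 1, paste, collapse = ""))
  names(seqs) <- msa$ids
  Biostrings::writeXStringSet(seqs, fasta_path)
  marks <- do.call(rbind, lapply(msa$ids, function(id) {
    df <- msa$introns[[id]]
    if (nrow(df) == 0) return(NULL)
    data.frame(member = id, column = df$column, phase = df$phase)
  }))
  if (is.null(marks)) {
    marks <- data.frame(member = character(), column = integer(),
                        phase = integer())
  }
  utils::write.table(marks, tsv_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(fasta_path)
}

#' @rdname write_msa
#' @export
read_msa <- function(fasta_path, tsv_path) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  ids <- names(seqs)
  aln <- do.call(rbind, strsplit(as.character(seqs), ""))
  marks <- utils::read.table(tsv_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  introns <- lapply(ids, function(id) {
    df <- marks[marks$member == id, c("column", "phase"), drop = FALSE]
    rownames(df) <- NULL
    df
  })
  names(introns) <- ids
  new_msa(ids, aln, introns)
}
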