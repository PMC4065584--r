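# Profiles, profile-profile alignment, progressive alignment, weights,
# sum-of-pairs scores, iterative refinement, updates.

test_that("profiles summarize columns with weights and intron marks", {
  p <- annotated_protein("a", "MKV",
                         introns = data.frame(aa_index = 1L, phase = 2L))
  m <- msa_from_protein(p)
  pr <- build_profile(m)
  expect_equal(dim(pr$freq), c(21L, 3L))
  expect_equal(unname(pr$freq["M", 1]), 1)
  expect_equal(pr$del, c(0, 0, 0))
  expect_equal(pr$intron[3, 2], 1)          # phase 2 at column 2
  expect_error(build_profile(m, members = character(0)), "empty")

  # two identical rows behave like one after weight normalization
  msa2 <- new_msa(c("a", "b"), rbind(strsplit("MKV", "")[[1]],
                                     strsplit("MKV", "")[[1]]),
                  list(a = data.frame(column = 2L, phase = 2L),
                       b = data.frame(column = 2L, phase = 2L)))
  pr2 <- build_profile(msa2)
  expect_equal(unname(pr2$freq["M", 1]) / pr2$weight, 1)

  # one gap of two equally weighted rows -> deletion fraction 0.5
  msa3 <- new_msa(c("a", "b"), rbind(c("M", "K"), c("M", "-")),
                  list(a = data.frame(column = integer(), phase = integer()),
                       b = data.frame(column = integer(), phase = integer())))
  pr3 <- build_profile(msa3)
  expect_equal(pr3$del[2] / pr3$weight, 0.5)
})

test_that("align_groups on single sequences matches the enumeration oracle", {
  params <- fx_params()
  set.seed(31)
  for (rep in 1:40) {
    la <- sample(2:8, 1); lb <- sample(2:8, 1)
    A <- fx_protein(la); B <- fx_protein(lb)
    ia <- if (stats::runif(1) < 0.5)
      data.frame(aa_index = sample(0:(la - 1), 1), phase = sample(0:2, 1))
    ib <- if (stats::runif(1) < 0.5)
      data.frame(aa_index = sample(0:(lb - 1), 1), phase = sample(0:2, 1))
    expect_equal(single_pair_align(A, B, params, ia, ib)$score,
                 enum_align_score(A, B, params, ia, ib))
  }
})

test_that("identical sequences align without gaps; intron bonus is exact", {
  params <- fx_params()
  s <- "MKVLADEWGH"
  r <- single_pair_align(s, s, params)
  expect_true(all(r$ops == 1))
  expect_equal(r$score, sum(params$matrix[cbind(strsplit(s, "")[[1]],
                                                strsplit(s, "")[[1]])]))
  ir <- data.frame(aa_index = 5L, phase = 1L)
  expect_equal(single_pair_align(s, s, params, ir, ir)$score - r$score,
               params$intron_bonus)
  ir2 <- data.frame(aa_index = 5L, phase = 2L)
  expect_equal(single_pair_align(s, s, params, ir, ir2)$score, r$score)
})

test_that("raising the intron bonus never unmatches intron marks", {
  cfg <- fx_cfg()
  set.seed(8)
  for (rep in 1:25) {
    la <- sample(5:9, 1); lb <- sample(5:9, 1)
    A <- fx_protein(la); B <- fx_protein(lb)
    ia <- data.frame(aa_index = sample(0:(la - 1), 1), phase = sample(0:2, 1))
    ib <- data.frame(aa_index = sample(0:(lb - 1), 1), phase = ia$phase)
    p_lo <- score_params(fx_cfg(intron_bonus = 0.01))
    p_hi <- score_params(fx_cfg(intron_bonus = 40))
    expect_gte(fx_matched_marks(A, B, ia, ib, p_hi),
               fx_matched_marks(A, B, ia, ib, p_lo))
  }
})

test_that("progressive alignment conserves intron marks and isolates indels", {
  params <- fx_params()
  p1 <- annotated_protein("a", "MKVLDEWGHR",
                          introns = data.frame(aa_index = 4L, phase = 0L))
  p2 <- annotated_protein("b", "MKVLDEWGHR",
                          introns = data.frame(aa_index = 4L, phase = 0L))
  p3 <- annotated_protein("c", "MKVLAAAAADEWGHR",
                          introns = data.frame(aa_index = 9L, phase = 0L))
  dm <- kmer_distance_matrix(c(a = p1$residues, b = p2$residues,
                               c = p3$residues))
  msa <- progressive_align(list(a = p1, b = p2, c = p3), upgma(dm), params)
  # the 5-residue insertion sits in a single gap block of the short rows
  rowa <- paste(msa$aln["a", ], collapse = "")
  expect_match(rowa, "^MKVL-{5}DEWGHR$")
  # intron-mark multiset conserved
  expect_equal(sum(vapply(msa$introns, nrow, integer(1))), 3L)
  # marks of a and b still on residue columns, same (column, phase)
  expect_equal(msa$introns[["a"]], msa$introns[["b"]])
  for (id in msa$ids) {
    ir <- msa$introns[[id]]
    if (nrow(ir)) expect_true(all(msa$aln[id, ir$column] != "-"))
  }
  # degapping reproduces the inputs
  expect_equal(paste(msa$aln["c", msa$aln["c", ] != "-"], collapse = ""),
               p3$residues)
})

test_that("pair weights are branch-proportional and normalized to mean 1", {
  # star tree with equal branches -> all pair weights 1
  star <- tree_node(tree_node(tree_leaf("a"), tree_leaf("b"), 1),
                    tree_node(tree_leaf("c"), tree_leaf("d"), 1), 1)
  pw <- pair_weights(star)
  expect_equal(mean(pw[upper.tri(pw)]), 1)
  expect_equal(max(abs(pw[upper.tri(pw)] - 1)), 0)

  # 4-leaf unbalanced tree: hand-computed GSC weights
  tr <- tree_node(tree_node(tree_leaf("a"), tree_leaf("b"), 1),
                  tree_node(tree_leaf("c"), tree_leaf("d"), 3), 5)
  # leaf weights: a,b = 1 + 4/2 = 3; c,d = 3 + 2/2 = 4
  w <- gsc_weights(tr)
  expect_equal(unname(w[c("a", "b", "c", "d")]), c(3, 3, 4, 4))
  pw2 <- pair_weights(tr)
  raw <- c(9, 12, 12, 12, 12, 16)   # ab, ac, ad, bc, bd, cd
  expect_equal(sort(pw2[upper.tri(pw2)]), sort(raw / mean(raw)))

  # duplicated sequence (zero branch) is down-weighted
  dup <- tree_node(tree_node(tree_leaf("a"), tree_leaf("a2"), 0),
                   tree_leaf("c"), 2)
  pwd <- pair_weights(dup)
  expect_lt(pwd["a", "a2"], pwd["a", "c"])
})

test_that("sum-of-pairs scores match the R reference and normalize correctly", {
  params <- fx_params()
  # 2 identical rows of one repeated residue -> nSP equals the match score
  p <- annotated_protein("a", "AAAAAA")
  q <- annotated_protein("b", "AAAAAA")
  dm <- matrix(c(0, .1, .1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  msa <- progressive_align(list(a = p, b = q), upgma(dm), params)
  expect_equal(nsp_score(msa, params), params$matrix["A", "A"])

  # an all-gap column dilutes nSP (score unchanged, length + 1)
  msa2 <- msa
  msa2$aln <- cbind(msa$aln, c("-", "-"))
  expect_equal(wsp_score(msa2, params, weighted = FALSE),
               wsp_score(msa, params, weighted = FALSE))
  expect_lt(nsp_score(msa2, params), nsp_score(msa, params))

  # 3-row toy equals the summed R reference pair scores
  sim <- fx_family(n_genomes = 10, protein_length = 120, seed = 42)
  m3 <- fx_aligned(sim)
  ref <- 0
  n <- length(m3$ids)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ref <- ref + pair_score(m3$aln[i, ], m3$aln[j, ],
                            m3$introns[[m3$ids[i]]], m3$introns[[m3$ids[j]]],
                            fx_params())
  }
  expect_equal(wsp_score(m3, fx_params(), weighted = FALSE), ref)
})

test_that("double-affine gaps take the cheaper regime consistently", {
  cfg <- fx_cfg(gap_open2 = 25, gap_ext2 = 0.1)
  params <- score_params(cfg)
  A <- "MKVLDEWGHRMKVLDEWGHR"
  B <- "MKVLDEWGHRAAAAAAAAAAAAAAAAMKVLDEWGHR"  # 16-residue insertion
  r <- single_pair_align(A, B, params)
  a <- msa_from_protein(annotated_protein("a", A))
  b <- msa_from_protein(annotated_protein("b", B))
  m <- merge_alignments(a, b, r$ops)
  expect_equal(r$score,
               pair_score(m$aln[1, ], m$aln[2, ],
                          m$introns[[1]], m$introns[[2]], params))
  # the long regime must be in effect: cheaper than single-affine price
  single <- score_params(fx_cfg())
  expect_gt(r$score, single_pair_align(A, B, single)$score - 1e-9)
})

test_that("iterative refinement never lowers WSP and fixes a bad gap", {
  params <- fx_params()
  sim <- fx_family(n_genomes = 10, protein_length = 120, seed = 42)
  msa <- fx_aligned(sim)
  w0 <- wsp_score(msa, params)
  out <- iterate_refine(msa, params, max_rounds = 2)
  expect_gte(wsp_score(out, params), w0 - 1e-9)

  # construct a deliberately misplaced-gap alignment: progressive with a
  # scrambled (worst-case) guide tree, then refine
  ids <- msa$ids
  bad_tree <- local({
    t <- tree_leaf(ids[1])
    for (k in 2:length(ids)) t <- tree_node(t, tree_leaf(ids[k]), k)
    t
  })
  bad <- progressive_align(msa$proteins[ids], bad_tree, params)
  bad$tree <- msa$tree; bad$seq_w <- msa$seq_w; bad$pair_w <- msa$pair_w
  wb <- wsp_score(bad, params)
  ref <- iterate_refine(bad, params, max_rounds = 3)
  expect_gte(wsp_score(ref, params), wb - 1e-9)
})

test_that("update_msa replaces rows, realigns, and keeps the partition", {
  params <- fx_params()
  sim <- fx_family(n_genomes = 10, protein_length = 120, seed = 42)
  msa <- fx_aligned(sim)
  id <- msa$ids[3]
  # update with the identical sequence: alignment equivalent up to
  # all-gap-column removal
  upd <- update_msa(msa, list(msa$proteins[[id]]), params)
  expect_setequal(upd$ids, msa$ids)
  expect_equal(paste(upd$aln[id, upd$aln[id, ] != "-"], collapse = ""),
               msa$proteins[[id]]$residues)
  expect_gte(wsp_score(upd, params), wsp_score(msa, params) - 30)

  # a revised protein (one fewer residue) only changes that row's region
  rev <- msa$proteins[[id]]
  rev$residues <- sub("^(.{10}).", "\\1", rev$residues)
  rev$introns <- data.frame(aa_index = integer(), phase = integer())
  upd2 <- update_msa(msa, list(rev), params)
  expect_equal(paste(upd2$aln[id, upd2$aln[id, ] != "-"], collapse = ""),
               rev$residues)
  expect_setequal(upd2$ids, msa$ids)
})
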