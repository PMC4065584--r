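# Alignment-free distances, PAM rescaling, UPGMA, tree cutting, isoforms.

test_that("k-mer cosine distance matches hand enumeration", {
  expect_equal(kmer_distance("MKVLM", "MKVLM"), 0)
  expect_equal(kmer_distance("AAAAA", "WWWWW"), 1)
  # MKVLM: {MKV, KVL, VLM}; MKVLA: {MKV, KVL, VLA}; cosine = 2/3
  expect_equal(kmer_distance("MKVLM", "MKVLA"), 1 - 2 / 3)
  expect_error(kmer_distance("MK", "MKVLM"), "at least")
  dm <- kmer_distance_matrix(c(a = "MKVLM", b = "MKVLA", c = "MKVLM"))
  expect_equal(dm, t(dm))
  expect_equal(diag(dm), c(a = 0, b = 0, c = 0))
  expect_equal(dm["a", "c"], 0)
})

test_that("UPGMA follows average linkage with deterministic ties", {
  dm <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(dm)
  expect_equal(tr$height, 3)
  inner <- tr$children[[1]]
  expect_setequal(inner$ids, c("A", "B"))
  expect_equal(inner$height, 1)
  # n = 2
  d2 <- matrix(c(0, 5, 5, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  t2 <- upgma(d2)
  expect_equal(t2$height, 2.5)
  # non-symmetric input rejected
  bad <- dm; bad[1, 2] <- 3
  expect_error(upgma(bad), "symmetric")
})

test_that("UPGMA agrees with the direct-definition oracle and with hclust", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    m <- matrix(stats::runif(n * n, 1, 10), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    dimnames(m) <- list(letters[1:n], letters[1:n])
    t1 <- upgma(m)
    t2 <- upgma_oracle(m)
    expect_equal(tree_canonical(t1), tree_canonical(t2))
    # independent cross-check: hclust average heights (merge distances)
    hc <- stats::hclust(stats::as.dist(m), method = "average")
    expect_equal(sort(collect_heights(t1)), sort(hc$height / 2),
                 tolerance = 1e-9)
  }
})

test_that("PAM rescaling goes through the origin and is monotone", {
  sim <- fx_family(n_genomes = 10, protein_length = 120, seed = 42)
  seqs <- vapply(sim$proteins, function(p) p$residues, character(1))
  dm <- kmer_distance_matrix(seqs)
  pm <- pam_rescale(dm, seqs, n_calib = 45, seed = 2)
  expect_equal(diag(pm), stats::setNames(rep(0, 10), names(seqs)))
  expect_true(all(pm >= 0 & pm <= 300))
  # monotone in the input distances
  o <- order(dm[upper.tri(dm)])
  expect_true(all(diff(pm[upper.tri(pm)][o]) >= -1e-9))
  expect_error(pam_rescale(dm[1:4, 1:4], seqs[1:4]), "calibration pairs")
})

test_that("PAM estimates recover the simulated divergence", {
  sim <- fx_family(n_genomes = 12, protein_length = 150, seed = 7,
                   divergence_pam = 80)
  seqs <- vapply(sim$proteins, function(p) p$residues, character(1))
  dm <- kmer_distance_matrix(seqs)
  pm <- pam_rescale(dm, seqs, n_calib = 66, seed = 2)
  vals <- pm[upper.tri(pm)]
  # simulated pairs diverge by up to ~2x the tree height (~80 PAM);
  # the calibrated estimates should mostly fall in a wide band around it
  expect_gt(mean(vals > 10 & vals < 180), 0.9)
})

test_that("tree cutting respects height, size, and the unclustered pool", {
  cfg <- gsa_config(max_height = 120, max_cluster = 50, min_cluster = 3)
  # all pairwise PAM below the cut height -> a single cluster
  near <- matrix(40, 5, 5); diag(near) <- 0
  dimnames(near) <- list(letters[1:5], letters[1:5])
  cut <- cut_tree(upgma(near), cfg)
  expect_length(cut$clusters, 1)
  expect_setequal(cut$clusters[[1]]$members, letters[1:5])
  expect_length(cut$unclustered, 0)

  # a 2-leaf subtree below MinCluster goes unclustered
  m <- matrix(300, 7, 7); diag(m) <- 0
  m[1:5, 1:5] <- 40; m[6, 7] <- m[7, 6] <- 40; diag(m) <- 0
  dimnames(m) <- list(letters[1:7], letters[1:7])
  cut2 <- cut_tree(upgma(m), cfg)
  expect_length(cut2$clusters, 1)
  expect_setequal(cut2$unclustered, c("f", "g"))
  # partition property
  got <- c(unlist(lapply(cut2$clusters, `[[`, "members")), cut2$unclustered)
  expect_setequal(got, letters[1:7])
  expect_equal(anyDuplicated(got), 0L)

  # oversized cluster split at the root: 5 leaves, MaxCluster 3, (3,2) split
  cfg2 <- gsa_config(max_height = 120, max_cluster = 3, min_cluster = 3)
  m3 <- matrix(100, 5, 5)
  m3[1:3, 1:3] <- 20; m3[4:5, 4:5] <- 20; diag(m3) <- 0
  dimnames(m3) <- list(letters[1:5], letters[1:5])
  cut3 <- cut_tree(upgma(m3), cfg2)
  expect_length(cut3$clusters, 1)
  expect_setequal(cut3$clusters[[1]]$members, c("a", "b", "c"))
  expect_setequal(cut3$unclustered, c("d", "e"))
})

test_that("minor isoforms are removed by average similarity with tie-breaks", {
  params <- fx_params()
  consensus <- "MKVLDEWGHRMKVLDEWGHR"
  minor <- "MKVLDEWGHR"             # skipped-exon-like short isoform
  prots <- list(
    a = annotated_protein("a", consensus),
    b = annotated_protein("b", consensus),
    iso1 = annotated_protein("iso1", consensus),
    iso2 = annotated_protein("iso2", minor))
  dm <- kmer_distance_matrix(vapply(prots, `[[`, "", "residues"))
  tr <- upgma(dm)
  msa <- progressive_align(prots, tr, params)
  cl <- list(members = names(prots), tree = tr)
  out <- remove_minor_isoforms(cl, msa,
                               c(a = "l1", b = "l2", iso1 = "l3", iso2 = "l3"))
  expect_setequal(out$members, c("a", "b", "iso1"))
  # single-isoform loci unchanged
  out2 <- remove_minor_isoforms(cl, msa,
                                c(a = "l1", b = "l2", iso1 = "l3", iso2 = "l4"))
  expect_setequal(out2$members, names(prots))
  # identical isoforms: exactly one kept (lexicographic tie-break)
  out3 <- remove_minor_isoforms(cl, msa,
                                c(a = "l1", b = "l1", iso1 = "l2", iso2 = "l3"))
  expect_true(sum(c("a", "b") %in% out3$members) == 1)
})
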