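# Conserved blocks, Dixon outliers, indel/divergence scans, intron
# concordance, defect points, cluster metrics.

make_msa <- function(rows, introns = NULL) {
  ids <- names(rows)
  aln <- do.call(rbind, strsplit(unlist(rows), ""))
  if (is.null(introns)) {
    introns <- lapply(ids, function(i)
      data.frame(column = integer(), phase = integer()))
    names(introns) <- ids
  }
  proteins <- lapply(ids, function(i)
    annotated_protein(i, gsub("-", "", rows[[i]])))
  names(proteins) <- ids
  new_msa(ids, aln, introns, proteins = proteins)
}

test_that("conserved blocks cover identical cores and skip scrambled ends", {
  cfg <- fx_cfg(block_window = 4)
  params <- fx_params()
  core <- "MKVLDEWGHRMK"
  same <- make_msa(list(a = core, b = core, c = core))
  b1 <- find_conserved_blocks(same, cfg, params)
  expect_equal(nrow(b1), 1L)
  expect_equal(c(b1$start, b1$end), c(0L, nchar(core)))
  expect_equal(nrow(variable_regions(b1, nchar(core))), 0L)

  set.seed(3)
  rnd <- make_msa(list(a = fx_protein(24), b = fx_protein(24),
                       c = fx_protein(24)))
  expect_equal(nrow(find_conserved_blocks(rnd, cfg, params)), 0L)

  mix <- make_msa(list(a = paste0(fx_protein(8), core, fx_protein(8)),
                       b = paste0(fx_protein(8), core, fx_protein(8)),
                       c = paste0(fx_protein(8), core, fx_protein(8))))
  b3 <- find_conserved_blocks(mix, cfg, params)
  expect_equal(nrow(b3), 1L)
  expect_lte(b3$start, 8L)
  expect_gte(b3$end, 8L + nchar(core))
  # tiling property: blocks + variable regions partition all columns
  vr <- variable_regions(b3, ncol(mix$aln))
  segs <- rbind(b3, vr)
  segs <- segs[order(segs$start), ]
  expect_equal(segs$start[1], 0L)
  expect_equal(segs$end[nrow(segs)], ncol(mix$aln))
  if (nrow(segs) > 1)
    expect_equal(segs$start[-1], segs$end[-nrow(segs)])
})

test_that("Dixon's test flags the textbook outlier and recurses", {
  # Q = (35-11)/(35-10) = 0.96 > 0.642 (n=5, two-sided alpha=0.1)
  expect_true(5L %in% dixon_outliers(c(10, 10, 11, 10, 35)))
  expect_equal(dixon_outliers(c(7, 7, 7, 7)), integer(0))
  expect_equal(dixon_outliers(c(1, 100)), integer(0))
  # recursion removes the extreme and tests again
  expect_setequal(dixon_outliers(c(10, 11, 12, 10, 35, 120)), c(5L, 6L))
  # low-side detection
  expect_true(1L %in% dixon_outliers(c(-40, 10, 10, 11, 10)))
  # n > 30 falls back to the robust z rule
  set.seed(1)
  x <- c(rnorm(40), 50)
  expect_true(length(dixon_outliers(x)) >= 1)
  expect_true(which.max(x) %in% dixon_outliers(x))
})

test_that("indel outliers and terminal-deletion flags are detected", {
  cfg <- fx_cfg(block_window = 4)
  params <- fx_params()
  core <- strrep("MKVLDEWGHR", 3)
  tail6 <- "MKVLDE"
  rows <- c(lapply(stats::setNames(nm = paste0("m", 1:3)),
                   function(i) paste0(core, tail6)),
            list(short = paste0(core, "------")))
  msa <- make_msa(rows)
  blocks <- find_conserved_blocks(msa, cfg, params)
  regions <- variable_regions(blocks, ncol(msa$aln))
  sc <- indel_outlier_scan(msa, regions, alpha = 0.1)
  expect_equal(unname(sc$counts["short"]), 1L)
  expect_true(sc$flag3[["short"]])
  expect_false(sc$flag5[["short"]])
  expect_true(all(sc$counts[paste0("m", 1:3)] == 0))

  # homogeneous cluster: nothing flagged
  homo <- make_msa(lapply(stats::setNames(nm = paste0("m", 1:5)),
                          function(i) core))
  b0 <- find_conserved_blocks(homo, cfg, params)
  r0 <- variable_regions(b0, ncol(homo$aln))
  expect_true(all(indel_outlier_scan(homo, r0)$counts == 0))
})

test_that("divergence outliers catch garbled same-length stretches", {
  cfg <- fx_cfg(block_window = 4)
  params <- fx_params()
  core <- strrep("MKVLDEWGHR", 2)
  var_good <- "AAAWWAAA"
  var_bad <- "DDDDDDDD"   # same length, garbled (compensating frameshift)
  rows <- c(lapply(stats::setNames(nm = paste0("m", 1:3)),
                   function(i) paste0(core, var_good, core)),
            list(bad = paste0(core, var_bad, core)))
  msa <- make_msa(rows)
  blocks <- find_conserved_blocks(msa, cfg, params)
  regions <- variable_regions(blocks, ncol(msa$aln))
  dv <- divergence_outlier_scan(msa, regions, alpha = 0.1)
  expect_equal(unname(dv[["bad"]]), 1L)
  expect_true(all(dv[paste0("m", 1:3)] == 0))
  # identical members: no outliers
  same <- make_msa(lapply(stats::setNames(nm = paste0("m", 1:5)),
                          function(i) paste0(core, var_good)))
  b0 <- find_conserved_blocks(same, cfg, params)
  expect_true(all(divergence_outlier_scan(
    same, variable_regions(b0, ncol(same$aln))) == 0))
})

test_that("intron concordance distinguishes mates from lonesome introns", {
  rows <- list(a = "MKVLDE", b = "MKVLDE", c = "MKVLDE")
  shared <- data.frame(column = 3L, phase = 0L)
  msa <- make_msa(rows, introns = list(a = shared, b = shared, c = shared))
  cc <- intron_concordance(msa)
  expect_equal(cc$n_concordant, 3L)
  expect_equal(cc$n_lonesome, 0L)
  expect_equal(cc$delta_cdi, 3L)

  # lonesome intron: no other member has any intron at that column
  msa2 <- make_msa(rows, introns = list(
    a = shared, b = shared, c = data.frame(column = 5L, phase = 0L)))
  cc2 <- intron_concordance(msa2)
  expect_equal(cc2$n_lonesome, 1L)
  expect_equal(cc2$lonesome_by_member[["c"]], 1L)

  # same column, different phases: both lonesome
  msa3 <- make_msa(rows, introns = list(
    a = data.frame(column = 3L, phase = 1L),
    b = data.frame(column = 3L, phase = 2L),
    c = data.frame(column = integer(), phase = integer())))
  cc3 <- intron_concordance(msa3)
  expect_equal(cc3$n_concordant, 0L)
  expect_equal(cc3$n_lonesome, 2L)
  expect_equal(cc3$delta_cdi, -2L)
})

test_that("defect points and labels follow the scoring rules", {
  cfg <- gsa_config(max_defect = 2)
  base <- list(indel_outliers = 0L, divergence_outliers = 0L,
               n_lonesome = 0L, n_frameshifts = 0L,
               n_premature_stops = 0L, n_ambiguous = 0L)
  expect_equal(defect_points_and_label(base, cfg),
               list(points = 0L, label = "R"))
  one <- modifyList(base, list(indel_outliers = 1L))
  expect_equal(defect_points_and_label(one, cfg),
               list(points = 1L, label = "Q"))
  fs <- modifyList(base, list(n_frameshifts = 1L))
  expect_equal(defect_points_and_label(fs, cfg),
               list(points = 2L, label = "P"))
  # lonesome introns add one point per gene, not per intron
  lone <- modifyList(base, list(n_lonesome = 3L))
  expect_equal(defect_points_and_label(lone, cfg)$points, 1L)
  # ambiguity counts one event per gene by default
  amb <- modifyList(base, list(n_ambiguous = 5L))
  expect_equal(defect_points_and_label(amb, cfg)$points, 2L)
  expect_equal(defect_points_and_label(
    amb, gsa_config(ambiguous_per_residue = TRUE))$points, 10L)
  # monotonicity: adding a frameshift never lowers the points
  for (br in list(base, one, lone)) {
    more <- modifyList(br, list(n_frameshifts = br$n_frameshifts + 1L))
    expect_gte(defect_points_and_label(more, cfg)$points,
               defect_points_and_label(br, cfg)$points)
  }
  # label boundaries move with max_defect
  cfg4 <- gsa_config(max_defect = 4)
  three <- modifyList(base, list(indel_outliers = 3L))
  expect_equal(defect_points_and_label(three, cfg4)$label, "Q")
  expect_equal(defect_points_and_label(three, cfg)$label, "P")
})

test_that("cluster metrics aggregate the member breakdowns", {
  cfg <- fx_cfg(block_window = 4)
  params <- fx_params()
  sim <- fx_family(n_genomes = 10, protein_length = 120, seed = 42)
  msa <- fx_aligned(sim)
  rep <- assess_msa(msa, cfg, params)
  expect_equal(rep$cluster$n_outlier_indels, sum(rep$members$indel_outliers))
  expect_equal(rep$cluster$delta_cdi,
               rep$cluster$n_concordant_introns -
                 rep$cluster$n_lonesome_introns)
  expect_equal(rep$cluster$nWSP, nwsp_score(msa, params))
  # identical members -> zero length spread
  same <- make_msa(lapply(stats::setNames(nm = paste0("m", 1:4)),
                          function(i) strrep("MKVLDEWGHR", 2)))
  rep2 <- assess_msa(same, cfg, params)
  expect_equal(rep2$cluster$sum_sd_lengths, 0)
  expect_true(all(rep2$members$label == "R"))
})
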