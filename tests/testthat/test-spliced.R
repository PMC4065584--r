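# Spliced alignment of genomic windows against protein and profile
# templates.

toy_template <- function() {
  annotated_protein("t", "MDE",
                    introns = data.frame(aa_index = 1L, phase = 2L))
}
toy_window <- "ATGGAGTAAGTTTTCAGTGAATAA"

test_that("window selection extends flanks and clips to contig bounds", {
  cfg <- gsa_config(flank_margin = 3000)
  genome <- c(c1 = strrep("A", 20000))
  gs <- gene_structure("g", "x", "c1", "+", cbind(8000L, 9000L))
  r <- select_target_region(gs, genome, cfg)
  expect_equal(c(r$start, r$end), c(5000L, 12000L))
  r5 <- select_target_region(gs, genome, cfg, flag5 = TRUE)
  expect_equal(c(r5$start, r5$end), c(2000L, 12000L))
  # the 5' side of a minus-strand gene is the high-coordinate side
  gsm <- gene_structure("g", "x", "c1", "-", cbind(8000L, 9000L))
  rm5 <- select_target_region(gsm, genome, cfg, flag5 = TRUE)
  expect_equal(c(rm5$start, rm5$end), c(5000L, 15000L))
  # clipping at the contig start
  gs0 <- gene_structure("g", "x", "c1", "+", cbind(100L, 400L))
  expect_equal(select_target_region(gs0, genome, cfg)$start, 0L)
})

test_that("the two-exon toy is solved exactly and matches the oracle", {
  params <- fx_params(); cfg <- fx_cfg()
  model <- splice_model(min_intron_len = 8)
  res <- spliced_align(toy_template(),
                       list(contig = "w", start = 0L,
                            end = nchar(toy_window), strand = "+"),
                       c(w = toy_window), model, params, cfg)
  expect_true(res$ok)
  expect_equal(unname(res$gene$exons), cbind(c(0L, 17L), c(5L, 24L)),
               ignore_attr = TRUE)
  expect_equal(res$protein$residues, "MDE")
  expect_equal(res$protein$introns,
               data.frame(aa_index = 1L, phase = 2L))
  expect_equal(res$template_intron_matches, 1L)
  expect_equal(res$score,
               enum_spliced_score(toy_window, toy_template(), model,
                                  params, cfg))

  # no GT..AG in the window: a single exon (terminal stop absorbed)
  res2 <- spliced_align(annotated_protein("t", "MG"),
                        list(contig = "w", start = 0L, end = 9L,
                             strand = "+"),
                        c(w = "ATGGGTTAA"), model, params, cfg)
  expect_equal(unname(res2$gene$exons), cbind(0L, 9L), ignore_attr = TRUE)
  expect_equal(res2$protein$residues, "MG")
})

test_that("the toy works identically on the minus strand", {
  params <- fx_params(); cfg <- fx_cfg()
  model <- splice_model(min_intron_len = 8)
  rc <- fx_revcomp(toy_window)
  res <- spliced_align(toy_template(),
                       list(contig = "w", start = 0L, end = nchar(rc),
                            strand = "-"),
                       c(w = rc), model, params, cfg)
  expect_true(res$ok)
  expect_equal(res$protein$residues, "MDE")
  L <- nchar(rc)
  expect_equal(sort(as.vector(res$gene$exons)),
               sort(as.vector(L - cbind(c(5L, 24L), c(0L, 17L)))))
})

test_that("spliced DP equals the structure-enumeration oracle", {
  params <- fx_params(); cfg <- fx_cfg()
  model <- splice_model(min_intron_len = 8, intron_open = 4)
  set.seed(19)
  for (rep in 1:40) {
    N <- sample(24:54, 1); P <- sample(3:12, 1)
    win <- fx_dna(N)
    ir <- if (stats::runif(1) < 0.5)
      data.frame(aa_index = sample(0:(P - 1), 1), phase = sample(0:2, 1))
    tmpl <- annotated_protein("t", fx_protein(P), introns = ir)
    res <- spliced_align(tmpl, list(contig = "w", start = 0L, end = N,
                                    strand = "+"),
                         c(w = win), model, params, cfg,
                         allow_frameshifts = FALSE)
    expect_equal(res$score, enum_spliced_score(win, tmpl, model, params, cfg),
                 tolerance = 1e-8)
  }
})

test_that("a deleted nucleotide is absorbed as a recorded frameshift", {
  params <- fx_params(); cfg <- fx_cfg()
  model <- splice_model()
  set.seed(23)
  prot <- fx_protein(30)
  codons <- vapply(strsplit(prot, "")[[1]], function(a) {
    gc <- Biostrings::GENETIC_CODE
    names(gc)[gc == a][1]
  }, character(1))
  cds <- paste(c(codons, "TAA"), collapse = "")
  broken <- paste0(substr(cds, 1, 44), substr(cds, 46, nchar(cds)))
  res <- spliced_align(annotated_protein("t", prot),
                       list(contig = "w", start = 0L,
                            end = nchar(broken), strand = "+"),
                       c(w = broken), model, params, cfg,
                       allow_frameshifts = TRUE)
  expect_true(res$ok)
  expect_equal(nrow(res$gene$frameshift_events), 1L)
  expect_equal(res$gene$frameshift_events$offset, -1L)
  expect_equal(res$protein$defects$n_frameshifts, 1L)
  # downstream residues are read in the restored frame
  expect_equal(substr(res$protein$residues, 17, 30), substr(prot, 17, 30))
})

test_that("translation round-trips for spliced alignments of random loci", {
  params <- fx_params(); cfg <- fx_cfg()
  model <- splice_model()
  sim <- fx_family(n_genomes = 10, protein_length = 120, seed = 42)
  for (id in names(sim$genes)[1:6]) {
    gs <- sim$genes[[id]]
    region <- select_target_region(gs, sim$genome, cfg)
    res <- spliced_align(sim$proteins[[id]], region, sim$genome, model,
                         params, cfg, gene_id = id)
    expect_true(res$ok)
    p2 <- translate_cds(res$gene, sim$genome)
    expect_equal(p2$residues, res$protein$residues)
    expect_equal(p2$introns, res$protein$introns)
    # a gene re-predicted from its own protein recovers its structure
    expect_equal(res$gene$exons, gs$exons)
  }
})

test_that("template choice modes pick CR / PR / M1 correctly", {
  cfg <- fx_cfg(); params <- fx_params()
  sim <- fx_family(n_genomes = 10, protein_length = 120, seed = 42)
  msa <- fx_aligned(sim)
  rep <- assess_msa(msa, cfg, params)
  q <- msa$ids[1]
  m1 <- choose_template(q, msa, rep, "M1")
  expect_s3_class(m1, "gsa_profile")
  expect_setequal(m1$members, setdiff(msa$ids, q))
  cr <- choose_template(q, msa, rep, "CR")
  expect_s3_class(cr, "annotated_protein")
  expect_true(cr$protein_id %in%
                setdiff(rep$members$id[rep$members$label == "R"], q))
  pr <- choose_template(q, msa, rep, "PR")
  expect_s3_class(pr, "gsa_profile")
  expect_setequal(pr$members,
                  setdiff(rep$members$id[rep$members$label == "R"], q))
  # zero R members -> explicit error
  rep0 <- rep
  rep0$members$label <- "P"
  expect_error(choose_template(q, msa, rep0, "CR"), "no reliable template")
})
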