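# Gene structures, translation, reconciliation, filters, GFF3 round trip.

test_that("translation handles single exons, splits, stops, Ns, frameshifts", {
  genome <- c(chr1 = "ATGGGTTAA")
  p <- translate_cds(gene_structure("g", "x", "chr1", "+", cbind(0L, 9L)),
                     genome)
  expect_equal(p$residues, "MG")
  expect_equal(nrow(p$introns), 0L)

  # split inside a codon after 1 nt -> one phase-1 mark on that residue
  g2 <- c(chr1 = paste0("ATGG", "GTAAGTTTTTTTTTAG", "GTTAA"))
  p2 <- translate_cds(gene_structure("g", "x", "chr1", "+",
                                     cbind(c(0L, 20L), c(4L, 25L))), g2)
  expect_equal(p2$residues, "MG")
  expect_equal(p2$introns$aa_index, 1L)
  expect_equal(p2$introns$phase, 1L)

  # internal stop -> X + premature-stop tally
  px <- translate_cds(gene_structure("g", "x", "chr1", "+", cbind(0L, 12L)),
                      c(chr1 = "ATGTAAGGGTGA"))
  expect_equal(px$residues, "MXG")
  expect_equal(px$defects$n_premature_stops, 1L)

  # ambiguous codon -> X + ambiguity tally
  pn <- translate_cds(gene_structure("g", "x", "chr1", "+", cbind(0L, 9L)),
                      c(chr1 = "ATGGNTTAA"))
  expect_equal(pn$residues, "MX")
  expect_equal(pn$defects$n_ambiguous, 1L)

  # frameshift: codon consumes 4 nt, residue from the last three
  pf <- translate_cds(gene_structure("g", "x", "chr1", "+", cbind(0L, 10L),
                        frameshift_events = data.frame(pos = 3L, offset = 1L)),
                      c(chr1 = "ATGAGGTTAA"))
  expect_equal(pf$residues, "MG")
  expect_equal(pf$defects$n_frameshifts, 1L)

  expect_error(translate_cds(gene_structure("g", "x", "chr1", "+",
                                            cbind(0L, 2L)),
                             genome), "shorter")
})

test_that("minus-strand genes translate like their reverse-complement twins", {
  set.seed(101)
  for (rep in 1:5) {
    sim <- simulate_family(family_spec(n_genomes = 1, protein_length = 60,
                                       n_introns = 2, flank_len = 50,
                                       seed = 300 + rep))
    gs <- sim$genes[[1]]
    p <- sim$proteins[[1]]
    # flip the contig and the gene
    ctg <- sim$genome[[gs$contig]]
    flipped <- fx_revcomp(ctg)
    L <- nchar(ctg)
    ex <- cbind(L - gs$exons[, 2], L - gs$exons[, 1])
    gs2 <- gene_structure(gs$gene_id, gs$genome_id, gs$contig,
                          if (gs$strand == "+") "-" else "+", ex)
    p2 <- translate_cds(gs2, stats::setNames(flipped, gs$contig))
    expect_equal(p2$residues, p$residues)
    expect_equal(p2$introns, p$introns)
  }
})

test_that("intron phase equals cumulative exon length mod 3", {
  sim <- fx_family()
  for (id in names(sim$genes)[1:5]) {
    gs <- sim$genes[[id]]
    p <- sim$proteins[[id]]
    cum <- cumsum(gs$exons[, 2] - gs$exons[, 1])
    junc <- cum[-length(cum)]
    expect_equal(p$introns$phase, as.integer(junc %% 3L))
    expect_equal(3L * p$introns$aa_index + p$introns$phase, as.integer(junc))
  }
})

test_that("GFF3 round trip reproduces structures and proteins", {
  sim <- fx_family(n_genomes = 4, protein_length = 80, seed = 9)
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(sim$genes, gff)
  back <- read_annotated_genes(gff, sim$genome, genome_id = "x")
  expect_setequal(names(back), names(sim$genes))
  for (id in names(sim$genes)) {
    expect_equal(back[[id]]$gene$exons, sim$genes[[id]]$exons)
    expect_equal(back[[id]]$gene$strand, sim$genes[[id]]$strand)
    expect_equal(back[[id]]$protein$residues, sim$proteins[[id]]$residues)
    expect_equal(back[[id]]$protein$introns, sim$proteins[[id]]$introns)
  }
  expect_error(read_annotated_genes(gff, c(other = "ACGT")), "missing")
})

test_that("reconcile fixes terminal residues and flags larger discrepancies", {
  p <- annotated_protein("p", "MKVLDEWG")
  expect_equal(reconcile("MKVLDEWG", p)$reconcile$status, "ok")
  expect_equal(reconcile("XKVLDEWG", p)$reconcile$status, "terminal_fixed")
  expect_equal(reconcile("XKVLDEWX", p)$reconcile$status, "terminal_fixed")
  garbled <- paste0("MKV", strrep("A", 30), "G")
  expect_equal(reconcile(garbled, p)$reconcile$status, "remap")
  r <- reconcile("MKVLDEWG", p)
  expect_equal(r$residues, p$residues)  # translated version always kept
})

test_that("first filter removes short proteins and ambiguous gene regions", {
  genome <- c(c1 = paste0(strrep("A", 10), "ATG", strrep("GGT", 420), "TAA"),
              c2 = paste0("ATGG", strrep("N", 10), "GTTAA"))
  long <- gene_structure("long", "x", "c1", "+",
                         cbind(10L, 10L + 3L + 3L * 420L + 3L))
  amb <- gene_structure("amb", "x", "c2", "+", cbind(0L, 19L))
  items <- list(long = list(gene = long,
                            protein = annotated_protein("long",
                                                        strrep("G", 421))),
                amb = list(gene = amb,
                           protein = annotated_protein("amb",
                                                       strrep("G", 500))),
                short = list(gene = long,
                             protein = annotated_protein("short",
                                                         strrep("G", 399))))
  cfg <- gsa_config(min_protein_len = 400, max_ambiguous_nt = 10)
  out <- first_filter(items, cfg, genome)
  expect_setequal(names(out$kept), "long")
  expect_setequal(out$removed$id, c("amb", "short"))
  expect_equal(out$removed$reason[out$removed$id == "short"], "length")
  expect_equal(out$removed$reason[out$removed$id == "amb"], "ambiguous")
  # min_protein_len = 0 disables the length filter
  out0 <- first_filter(items, gsa_config(min_protein_len = 0), genome)
  expect_true("short" %in% names(out0$kept))
})

test_that("gene structure invariants are enforced", {
  expect_silent(validate_gene_structure(
    gene_structure("g", "x", "c", "+", cbind(c(0L, 20L), c(6L, 26L)))))
  expect_error(validate_gene_structure(
    gene_structure("g", "x", "c", "+", cbind(c(0L, 8L), c(6L, 14L))),
    min_intron_len = 4), "intron")
  expect_error(validate_gene_structure(
    gene_structure("g", "x", "c", "+", cbind(0L, 7L))), "codons")
})
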