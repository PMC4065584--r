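# Shared fixture builders for the test suite.  Everything is generated
# in code; no data files.

fx_cfg <- function(...) {
  args <- utils::modifyList(list(min_protein_len = 0, flank_margin = 300),
                            list(...))
  do.call(gsa_config, args)
}
fx_params <- function(cfg = fx_cfg()) score_params(cfg)

# revcomp of a character string
fx_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# deterministic random protein / dna strings
fx_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, TRUE),
        collapse = "")
}

fx_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}

# a small clean simulated family (cached per session to keep tests fast)
fx_family <- local({
  cache <- list()
  function(n_genomes = 10, protein_length = 120, seed = 42, ...) {
    key <- paste(n_genomes, protein_length, seed, ...)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- simulate_family(family_spec(
        n_genomes = n_genomes, protein_length = protein_length,
        seed = seed, ...))
    }
    cache[[key]]
  }
})

# cluster + alignment for a simulated family (largest cluster)
fx_aligned <- function(sim, cfg = fx_cfg(), params = fx_params(cfg)) {
  cl <- build_clusters(sim$proteins, cfg)
  big <- which.max(vapply(cl$clusters, function(x) length(x$members),
                          integer(1)))
  align_cluster(cl$clusters[[big]], sim$proteins, cfg, params)
}

# internal node heights of a gsa_tree
collect_heights <- function(tree) {
  if (tree$leaf) return(numeric(0))
  c(tree$height, collect_heights(tree$children[[1]]),
    collect_heights(tree$children[[2]]))
}

# count intron marks aligned at the same column & phase in a pairwise
# alignment produced by align_groups on two single sequences
fx_matched_marks <- function(seqA, seqB, irA, irB, params) {
  mk <- function(s, ir, id) {
    if (is.null(ir)) ir <- data.frame(aa_index = integer(), phase = integer())
    msa_from_protein(annotated_protein(id, s, introns = ir))
  }
  a <- mk(seqA, irA, "qa"); b <- mk(seqB, irB, "qb")
  al <- align_groups(build_profile(a), build_profile(b), params)
  m <- merge_alignments(a, b, al$ops)
  ia <- m$introns[[1]]; ib <- m$introns[[2]]
  if (nrow(ia) == 0 || nrow(ib) == 0) return(0L)
  nrow(merge(ia, ib, by = c("column", "phase")))
}
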