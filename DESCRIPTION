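Package: gsalign
Title: Gene-Structure-Aware Multiple Protein Sequence Alignment and Gene
    Model Refinement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds multiple protein sequence alignments that carry the
    positions and phases of the introns of the parental genes, and uses
    them to assess and refine predicted eukaryotic gene structures.
    Homologous annotated genes are clustered by alignment-free distances
    rescaled to PAM units and a UPGMA guide tree; cluster members are
    aligned under a weighted sum-of-pairs objective with a bonus for
    conserved intron positions; each member is scored for defects
    (outlier indels, divergent segments, lonesome introns, frame shifts,
    premature stops) and labelled reliable, questionable, or pseudo;
    suspicious gene models are re-predicted by spliced alignment of
    genomic DNA against single-sequence or generalized-profile templates
    and the alignment is updated iteratively.  Includes an EST-evidence
    evaluation layer and a synthetic gene-family simulator with
    controlled annotation-error injection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    Rcpp,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
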