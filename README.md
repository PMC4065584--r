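# gsalign

Gene-structure-aware multiple protein sequence alignment for assessing
and refining predicted eukaryotic gene models.

## What problem this solves

High-throughput genome annotation produces gene models whose exon–intron
structures are rarely verified.  gsalign exploits two comparative
regularities of closely related protein-coding genes — long indels are
rare, and intron positions and phases projected onto the coding sequence
are well conserved — to (i) score the reliability of every predicted
gene in a family and (ii) repair the suspicious ones automatically.  It
is aimed at annotation and comparative-genomics work on gene families
sampled across many genomes.

## The method in brief

Each translated gene enters a multiple protein sequence alignment whose
rows carry *intron marks* `(alignment column, phase)`.  Alignments
maximise a weighted sum-of-pairs objective

```
WSP = Σ_{i<j} w_ij [ S(a_i, a_j) − gaps_affine(i, j) + b · |shared intron marks| ]
```

with BLOSUM62 substitution scores, affine gaps (11/1), tree-derived pair
weights `w_ij`, and an intron-position bonus `b` granted per sequence
pair when two introns occupy the same column with the same phase
(default `b` = twice the mean positive substitution score).  Families
are clustered by alignment-free k-mer distances rescaled to PAM units
and a UPGMA tree cut at 120 PAM (cluster sizes 3–50).

Each member is then assessed: recursive two-sided Dixon outlier tests
(α = 0.1) on per-region residue counts and divergences, plus intron
concordance (an intron with no mate at the same column and phase is
*lonesome*).  Defect points — +1 per outlier, +1 for lonesome introns,
+2 per frameshift/premature stop/ambiguity — classify members as **R**
(reliable, 0 points), **Q** (questionable, < `max_defect` = 2), or **P**
(pseudogene candidate).  Q members are re-predicted by spliced alignment
of their genomic window against a template chosen per mode — the closest
reliable member (CR), the profile of all reliable members (PR), or the
profile of all other members (M1) — where GT..AG introns that land on a
template intron position earn the bonus `b`, steering boundaries toward
the family consensus.  Modes chain into schedules such as CR-M1-PR and
iterate until the structures stop changing.

An EST-evidence layer computes intron-level sensitivity/specificity and
false rates from BED-like supported-intron and exon-coverage intervals,
including the homology-supported correction for retained-intron ESTs.
A seeded simulator (`simulate_family()`, `inject_errors()`) generates
gene families with conserved intron positions and predictor-style
annotation errors, with a machine-readable truth log.

## Worked example

Simulate a 12-member family, corrupt some annotations, assess, refine:

```r
library(gsalign)
cfg    <- gsa_config(min_protein_len = 0, flank_margin = 300)
params <- score_params(cfg)

sim <- simulate_family(family_spec(n_genomes = 12, protein_length = 150, seed = 3))
bad <- inject_errors(sim, rates = c(shifted_donor = 0.08, shifted_acceptor = 0.08,
                                    skipped_exon = 0.04, extra_exon = 0.04),
                     seed = 30)
subset(bad$truth$errors, !startsWith(detail, "skipped"))
#>   gene_id             kind intron_index                         detail
#> 1     g01 shifted_acceptor            3             intron 3 by -21 nt
#> 2     g04       extra_exon            4 inserted [575,593) in intron 4
#> 4     g10 shifted_acceptor            3             intron 3 by -27 nt
#> 5     g11    shifted_donor            4             intron 4 by +12 nt

cl     <- build_clusters(bad$proteins, cfg)
msa    <- align_cluster(cl$clusters[[1]], bad$proteins, cfg, params)
report <- assess_msa(msa, cfg, params)
report
#> gsa_assessment: 12 members; 8 R / 3 Q / 1 P; delta_cdi = 49
report$members[report$members$defect_points > 0,
               c("indel_outliers", "n_lonesome", "defect_points", "label")]
#>     indel_outliers n_lonesome defect_points label
#> g01              1          0             1     Q
#> g10              1          0             1     Q
#> g11              1          0             1     Q
#> g04              1          1             2     P
```

All four corrupted members are flagged (the splice shifts as indel
outliers, the recruited exon additionally as a lonesome intron).  Now
run the CR-M1-PR refinement schedule and compare against the truth log:

```r
out <- run_schedule(msa, bad$genome, gsa_schedule(c("CR", "M1", "PR")), cfg, params)
out$report
#> gsa_assessment: 12 members; 12 R / 0 Q / 0 P; delta_cdi = 49

refined <- lapply(out$msa$proteins, function(p) p$gene)
unlist(intron_boundary_recovery(sim$truth$genes, bad$truth$errors, refined))
#> n_corrupted n_recovered        rate
#>           4           4           1
```

All four corrupted structures are restored to the exact true intron
boundaries and every member is reliable afterwards.

A thin command-line front end is installed at `inst/exec/gsalign`
(`gsalign simulate ...`, `gsalign refine --genome fa --gff gff3 --out dir`).

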