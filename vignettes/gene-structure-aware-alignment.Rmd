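---
title: "Assessing and refining gene structures with intron-aware protein alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing and refining gene structures with intron-aware protein alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsalign)
```

## The problem

Automated genome annotation pipelines produce large sets of predicted
protein-coding genes whose exon–intron structures are, individually,
rarely checked.  Two empirical regularities make a *comparative* check
possible: among closely related homologous proteins, long insertions and
deletions are rare, and intron positions (projected onto the coding
sequence and annotated with their phase, the 0/1/2 offset within the
interrupted codon) are strongly conserved.  gsalign builds multiple
protein sequence alignments that carry these intron marks on every row —
a gene-structure-aware alignment — and reads annotation defects off the
alignment: a member with an outlying insertion, a divergent segment, or
an intron that no other member shares is suspicious, and its gene model
can be re-predicted by spliced alignment against its more reliable
relatives.

## The pipeline

1. **Ingest and reconcile** (`read_annotated_genes()`, `reconcile()`).
   CDS features are read from GFF3, translated from the genome, and
   compared with the annotation's protein sequences.  Discrepancies
   confined to the first or last residue (partial terminal codons, a
   missing stop) are silently resolved in favour of the translation;
   anything larger flags the gene for re-mapping (`remap_gene()`).
   Internally all coordinates are 0-based half-open; GFF3's 1-based
   inclusive convention is converted only at the I/O boundary, so no
   intermediate code ever reasons about inclusive ends.

2. **Filter** (`first_filter()`).  Proteins not longer than
   `min_protein_len` (default 400, the multi-domain-enzyme setting; 0
   disables the filter for short proteins such as ribosomal subunits)
   and genes whose genomic span contains `max_ambiguous_nt` (default 10)
   or more `N`s are set aside.

3. **Cluster** (`build_clusters()`).  All-by-all distances use a k-mer
   cosine measure (`k = 3`); any monotone proxy suffices here because
   the distances are then rescaled to PAM units by a cubic polynomial,
   constrained through the origin, fitted against Kimura-corrected
   pairwise alignments of a calibration subsample, with an isotonic
   post-step so that rescaling can never invert the distance order.  A
   UPGMA tree is cut at `max_height = 120` PAM — at that radius cluster
   members retain roughly 40 % or more mutual identity — then oversized
   subtrees are split recursively at their roots until no cluster
   exceeds `max_cluster` (default 50), and subtrees smaller than
   `min_cluster = 3` go to an unclustered pool (two sequences cannot
   outvote each other, so no meaningful consensus exists below three).
   Whether the size cap should apply before or after the height cut is
   genuinely open; we cut by height first because the height threshold
   carries the biological meaning and the size cap is a computational
   guard.  When several cluster members map to the same genomic locus
   they are isoforms of one gene; only the major isoform — the one most
   similar on average to the rest of the cluster — is kept.

4. **Align** (`progressive_align()`, `iterate_refine()`).  The
   objective is a weighted sum-of-pairs (WSP) score: BLOSUM62
   substitutions, affine gaps (open 11, extend 1; an optional second
   affine regime for long gaps is off by default), sequence-pair weights
   derived from the guide tree branch lengths (Gerstein–Sonnhammer–
   Chothia style, normalized to mean 1), **plus a bonus `b` for every
   pair of introns aligned at the same column with the same phase**.
   The bonus is the package's central scoring idea: it couples the
   protein alignment to the gene structures.  Its size is nowhere
   dictated by theory; we default to twice the average positive
   substitution score (≈ 5.8 for BLOSUM62) so that one conserved intron
   outweighs roughly two good residue matches but cannot overrule a
   well-supported gap placement.  The bonus is applied per sequence
   pair inside the dynamic programming (on column pairs), consistent
   with the pairwise WSP objective, rather than as a post-hoc column
   term.  Profile–profile alignment uses occupancy-scaled gap costs (a
   generalized-profile approximation: the exact gap-open bookkeeping is
   kept for single sequences, which is also where the test oracles bite);
   refinement is restricted partitioning — each member and each
   guide-tree bipartition is split off and realigned, and a candidate is
   kept only if WSP does not decrease.  Equal-score candidates are
   discarded to guarantee termination.  Following the observation that
   re-deriving pair weights between sweeps buys little, the outer loop
   runs once; inner sweeps stop at convergence or `max_rounds = 3`.

5. **Assess** (`assess_msa()`).  Conserved blocks are maximal runs of
   at least `block_window = 6` columns whose mean weighted column score
   reaches half the average positive substitution score with gap
   fraction at most 0.2.  The variable regions between and outside
   blocks tile the remaining columns.  Within each variable region, the
   per-member residue counts, and separately each member's mean
   divergence from the rest, are screened by a recursive two-sided
   Dixon ratio test (r10/r11/r21/r22 by sample size, published
   two-tailed critical values at α = 0.1; detected extremes are removed
   and the test repeated; beyond n = 30 a median/MAD z-rule takes
   over).  Both scans may add points to the same member in the same
   region — a garbled *and* shortened segment is doubly suspicious.
   Defect points: +1 per outlier detection, +1 if the gene has at least
   one lonesome intron (an intron with no mate at the same column and
   phase; the +1 is per gene, following the "at least one" reading,
   while ΔCDI still counts every intron), +2 per frameshift, premature
   stop, or ambiguity event (one ambiguity event per gene by default —
   a single sequencing gap often produces many `X`s that share one
   cause).  0 points ⇒ "R" (reliable), below `max_defect = 2` ⇒ "Q"
   (questionable), else "P" (pseudogene candidate).  A low-side length
   outlier in the first or last region sets a terminal-deletion flag:
   the gene may extend beyond its annotated span, so the re-prediction
   window is doubled on that side.

6. **Refine** (`run_schedule()`).  Template modes: **M1** re-predicts
   every member against the profile of all others; **CR** and **PR**
   re-predict only "Q" members, against the single closest "R" member
   or the profile of all "R" members respectively.  A re-predicted
   structure always replaces the previous one within a pass — the
   alignment is updated (`update_msa()`: same-id rows removed, revised
   member re-inserted against the remaining profile) and re-assessed
   after every visit — but a schedule-level guard reverts an entire
   mode pass if cluster nWSP drops by more than `nwsp_tolerance`; this
   mirrors the known failure mode in which a member carrying foreign
   sequence acts, under M1, as a template that seeds false exons in
   others.  Schedules chain up to three modes with no two consecutive
   modes equal; convergence is tested per full mode pass (the
   within-pass loop already iterates until structures stop changing, so
   a cross-mode test would terminate too eagerly).

7. **Spliced alignment** (`spliced_align()`).  Genomic DNA is aligned
   to a protein or a generalized-profile template by dynamic
   programming over codon-boundary, intron (one per phase), template-
   deletion, and DNA-insertion states.  Introns are canonical GT..AG
   only (species-specific splice signal training is out of scope and a
   flat model keeps the oracle tractable), with length ≥
   `min_intron_len = 30` nt and cost `intron_open + intron_logext ·
   log(length)` (defaults 8 and 1).  A predicted intron whose template
   residue and phase coincide with a template intron earns the bonus
   `b`, scaled by the template's intron frequency for profiles — this
   is what steers a re-prediction toward the cluster consensus
   boundary when two splice sites score similarly.  Frameshifted codons
   (3 ± 1 or 2 nt, penalty `2 · gap_open`) and in-frame stops (penalty
   twice the worst substitution score) are admitted and recorded as
   defect events — deliberately expensive, appearing only when the
   evidence demands, and mirroring their weight of 2 defect points.
   The alignment is global in the template, local in the window
   (windows deliberately over-extend the locus); a stop codon
   immediately following the last exon is absorbed into it, which
   resolves the "no terminal stop" ambiguity class deterministically.
   When a profile serves as the template, columns occupied by fewer
   than half the members are dropped: such columns stem from isolated
   insertions — often precisely the annotation errors under repair —
   and would otherwise offer nearly free deletions that attract
   intronic sequence of the gene being re-predicted.  Translation-
   initiation ambiguity (several nearby in-frame ATGs) is not modelled;
   the highest-scoring path decides.

8. **EST evaluation** (`est_report()`).  Transcript mapping itself is
   out of scope; evidence arrives as BED-like supported-intron and
   exon-coverage intervals.  Intron-level sensitivity and specificity,
   junction-level variants, and false-positive/negative rates follow
   the standard count definitions; "overlap" means one shared base.  A
   nominally false-positive intron that is concordant with another
   cluster member is reclassified as a homology-supported true
   positive (retained-intron ESTs otherwise inflate the false-positive
   count): IntTP gains IntHS_TP, JncTP gains 2·IntHS_TP, IntFP loses
   IntHS_TP.  Whether the supported-intron denominator should count
   distinct coordinates or alignment instances is ambiguous in the
   field's usage; we count distinct coordinates.

## The synthetic-data generator

`simulate_family()` evolves an ancestral protein along a random
ultrametric tree (substitutions drawn from a BLOSUM62-derived kernel,
rare 1–3-residue indels at about one event per unit branch length),
back-translates each tip with uniform codon usage, interrupts the CDS
with GT..AG introns at the inherited (position, phase) marks — with a
small per-branch gain/loss rate — and embeds each gene, on a random
strand, in its own contig with random flanks.  Defaults: 20 genomes,
one member each, 180-residue proteins, average pairwise divergence
about 60 PAM (a compact plant-like family inside one cluster radius),
4 ancestral introns, 5 % gain/loss, 500 nt flanks, intron lengths
uniform in [30, 90] nt.  `inject_errors()` corrupts selected genes with
exactly one predictor-style error each — a splice site moved to an
alternative GT/AG (frame-preserving, so the broken annotation still
encodes an ORF, as real predictors enforce), an in-frame exon skipped,
a spurious in-frame exon recruited from intronic sequence, or the start
moved to the next in-frame ATG — and logs the truth.

What the generator deliberately does **not** emulate: codon bias,
splice-site strength variation, non-canonical introns, repeats,
alternative splicing, paralog-specific rate variation, and assembly
gaps.  Tests passing on these fixtures therefore demonstrate the
machinery — coordinate bookkeeping, scoring, outlier logic, template
steering — not performance on real genomes, where splice-signal models
and messier homology would matter.

## Numerical and testing choices

Deterministic tie-breaks keep every run reproducible: the profile DP
prefers diagonal, then deletion, then insertion; UPGMA merges the
smallest index pair on ties; template choice breaks percent-identity
ties lexicographically; members are visited in input order.  The
spliced and profile DPs are compiled (Rcpp), as alignment kernels in
this field usually are.  Correctness is anchored by independent
oracles rather than by references to other tools: an exhaustive
path-enumeration oracle for pairwise affine alignment with the intron
bonus, a structure-enumeration oracle for spliced alignment (every
window start and every compatible GT..AG chain, scored by a plain
codon-level alignment with junction codons forced to match), and a
direct-definition UPGMA that recomputes cluster distances from the raw
matrix at every step; `hclust(method = "average")` serves as an extra
cross-check.  Dixon critical values are the published two-tailed
α = 0.1 table; the suite verifies the first-pass null flag rate on
2000 simulated samples.  Test problem sizes are chosen so the whole
suite exercises every path at small scale: oracle checks use sequences
of ≤ 8 residues and windows of ≤ 60 nt (the enumeration spaces are
exponential), refinement recovery uses 20 seeds of the default
20-genome family, and the profile-advantage comparison uses three
18-member families at 110 PAM — divergent enough that a single remote
template visibly underperforms the cluster profile.

## Known limitations

Frameshift penalties are constants rather than locus-specific error
models; the generalized-profile gap treatment is occupancy-scaled
rather than an exact gap-history profile, so gap-opening counts against
profiles are approximate (exact for single sequences); intron gain at
a site where another member independently gained a different-phase
intron is counted as discordant with no attempt at phase-shift
modelling; and the refinement guard operates at pass granularity — a
pass that improves most members but harms one is kept, matching the
always-replace update flow.
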