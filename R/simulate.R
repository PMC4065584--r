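# Synthetic gene families: an ancestral protein evolved along a random
# ultrametric tree with conserved intron positions, back-translated and
# wrapped with GT..AG introns and intergenic flanks; plus controlled
# injection of realistic annotation errors with a machine-readable truth
# log.  Every other module is testable against these fixtures without
# any download.

#' Family simulation specification
#'
#' Defaults describe a compact multi-exon plant-like gene family: 20
#' genomes with one member each, 180-residue proteins at an average
#' pairwise divergence of ~60 PAM, 4 ancestral introns with a small
#' per-lineage gain/loss rate, and 500 nt intergenic flanks.
#'
#' @param n_genomes number of genomes (tree tips per paralog).
#' @param paralogs_per_genome paralogous copies per genome.
#' @param protein_length ancestral protein length (residues).
#' @param divergence_pam target average pairwise divergence (PAM).
#' @param n_introns ancestral intron count.
#' @param gain_loss_rate per-branch probability of an intron gain or
#'   loss event.
#' @param indel_rate expected indel events per unit branch length.
#' @param flank_len intergenic flank on each side (nt).
#' @param min_intron_len minimal intron length; intron lengths are
#'   uniform in `[min, 3 min]`.
#' @param seed RNG seed; runs are reproducible byte-for-byte.
#' @return An object of class `family_spec`.
#' @export
family_spec <- function(n_genomes = 20L, paralogs_per_genome = 1L,
                        protein_length = 180L, divergence_pam = 60,
                        n_introns = 4L, gain_loss_rate = 0.05,
                        indel_rate = 1.0, flank_len = 500L,
                        min_intron_len = 30L, seed = 1L) {
  stopifnot(n_genomes >= 1, paralogs_per_genome >= 1, protein_length >= 10,
            n_introns >= 0, gain_loss_rate >= 0, gain_loss_rate <= 1,
            flank_len >= 0, min_intron_len >= 10)
  structure(list(n_genomes = as.integer(n_genomes),
                 paralogs_per_genome = as.integer(paralogs_per_genome),
                 protein_length = as.integer(protein_length),
                 divergence_pam = divergence_pam,
                 n_introns = as.integer(n_introns),
                 gain_loss_rate = gain_loss_rate,
                 indel_rate = indel_rate,
                 flank_len = as.integer(flank_len),
                 min_intron_len = as.integer(min_intron_len),
                 seed = as.integer(seed)),
            class = "family_spec")
}

# sample() treats a scalar first argument as 1:n; this keeps vectors of
# length one literal
resample <- function(x, ...) x[sample.int(length(x), ...)]

# random ultrametric tree over n tips: random pair joins at increasing
# heights up to H (substitutions/site per lineage)
random_ultrametric_tree <- function(ids, H) {
  n <- length(ids)
  act <- lapply(ids, tree_leaf)
  if (n == 1) return(act[[1]])
  hs <- sort(stats::runif(n - 1, 0.05 * H, H))
  hs[n - 1] <- H
  for (k in seq_len(n - 1)) {
    i <- sample.int(length(act), 1)
    j <- resample(setdiff(seq_along(act), i), 1)
    node <- tree_node(act[[i]], act[[j]], hs[k])
    act[[min(i, j)]] <- node
    act <- act[-max(i, j)]
  }
  act[[1]]
}

# substitute residues along a branch of length t (subst/site), mutation
# kernel proportional to exp(0.3 * blosum score), never to the same
# residue
mutate_residues <- function(chars, t, m = sub_matrix()) {
  aa20 <- aa_alphabet()[1:20]
  p_mut <- 1 - exp(-t)
  hit <- which(stats::runif(length(chars)) < p_mut)
  for (h in hit) {
    a <- chars[h]
    if (!a %in% aa20) next
    w <- exp(0.3 * m[a, aa20])
    w[aa20 == a] <- 0
    chars[h] <- sample(aa20, 1, prob = w)
  }
  chars
}

# apply an indel to (chars, marks); marks is data.frame(aa_index, phase)
apply_indel <- function(chars, marks, aa20) {
  L <- length(chars)
  if (L < 20) return(list(chars = chars, marks = marks))
  len <- sample(1:3, 1)
  if (stats::runif(1) < 0.5 && L > len + 10) {   # deletion
    s <- sample(2:(L - len), 1)                  # 1-based, keeps start M
    chars <- chars[-(s:(s + len - 1))]
    if (nrow(marks) > 0) {
      inside <- marks$aa_index >= (s - 1) & marks$aa_index < (s - 1 + len)
      marks$aa_index[inside] <- s - 1L
      after <- marks$aa_index >= (s - 1 + len)
      marks$aa_index[after] <- marks$aa_index[after] - len
    }
  } else {                                       # insertion
    s <- sample(2:L, 1)
    ins <- sample(aa20, len, replace = TRUE)
    chars <- append(chars, ins, after = s - 1)
    if (nrow(marks) > 0) {
      after <- marks$aa_index >= (s - 1)
      marks$aa_index[after] <- marks$aa_index[after] + len
    }
  }
  marks <- dedupe_marks(marks, length(chars))
  list(chars = chars, marks = marks)
}

dedupe_marks <- function(marks, L) {
  if (nrow(marks) == 0) return(marks)
  marks$aa_index <- pmin(pmax(marks$aa_index, 1L), L - 1L)
  key <- 3L * marks$aa_index + marks$phase
  marks <- marks[!duplicated(marks$aa_index), , drop = FALSE]
  marks <- marks[order(3L * marks$aa_index + marks$phase), , drop = FALSE]
  rownames(marks) <- NULL
  marks
}

random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# back-translate a residue vector with uniform codon usage
back_translate <- function(chars) {
  gc <- Biostrings::GENETIC_CODE
  vapply(chars, function(a) {
    cands <- names(gc)[gc == a]
    cands[sample(length(cands), 1)]
  }, character(1))
}

#' Simulate a gene family with conserved intron positions
#'
#' An ancestral protein is evolved along a random ultrametric tree to the
#' target divergence (substitution kernel from the substitution matrix,
#' rare short indels); each tip is back-translated with uniform codon
#' choice, interrupted by GT..AG introns at its inherited (CDS position,
#' phase) marks, and embedded in random intergenic flanks, one contig per
#' gene with random strand.  The terminal stop codon is part of the last
#' exon.
#'
#' @param spec a [family_spec()].
#' @return list with `genome` (named contig vector), `genes` (named list
#'   of [gene_structure()]), `proteins` (their translations), `truth`
#'   (list with `genes` and an empty `errors` log), and `spec`.
#' @export
simulate_family <- function(spec = family_spec()) {
  set.seed(spec$seed)
  aa20 <- aa_alphabet()[1:20]
  L <- spec$protein_length
  anc <- c("M", sample(aa20, L - 1, replace = TRUE))
  if (spec$n_introns > L - 4)
    stop("more introns than the protein can host")
  marks <- data.frame(aa_index = sort(sample(2:(L - 2), spec$n_introns)),
                      phase = sample(0:2, spec$n_introns, replace = TRUE))
  marks <- dedupe_marks(marks, L)

  n_tips <- spec$n_genomes * spec$paralogs_per_genome
  ids <- character(n_tips)
  k <- 0L
  for (g in seq_len(spec$n_genomes)) for (p in seq_len(spec$paralogs_per_genome)) {
    k <- k + 1L
    ids[k] <- if (spec$paralogs_per_genome > 1) sprintf("g%02d_p%d", g, p)
              else sprintf("g%02d", g)
  }
  H <- spec$divergence_pam / 200
  tree <- random_ultrametric_tree(ids, H)

  tips <- list()
  evolve <- function(node, chars, mk) {
    if (node$leaf) {
      tips[[node$id]] <<- list(chars = chars, marks = mk)
      return(invisible())
    }
    for (ch in node$children) {
      t <- node$height - ch$height
      c2 <- mutate_residues(chars, t)
      m2 <- mk
      n_ind <- stats::rpois(1, spec$indel_rate * t)
      for (q in seq_len(n_ind)) {
        r <- apply_indel(c2, m2, aa20)
        c2 <- r$chars; m2 <- r$marks
      }
      if (spec$gain_loss_rate > 0 && nrow(m2) > 0 &&
          stats::runif(1) < spec$gain_loss_rate / 2) {
        m2 <- m2[-sample(nrow(m2), 1), , drop = FALSE]
      }
      if (spec$gain_loss_rate > 0 &&
          stats::runif(1) < spec$gain_loss_rate / 2) {
        cand <- setdiff(2:(length(c2) - 2), m2$aa_index)
        if (length(cand) > 0) {
          m2 <- rbind(m2, data.frame(aa_index = resample(cand, 1),
                                     phase = sample(0:2, 1)))
          m2 <- dedupe_marks(m2, length(c2))
        }
      }
      evolve(ch, c2, m2)
    }
  }
  evolve(tree, anc, marks)

  genome <- character(0)
  genes <- list()
  for (id in ids) {
    tp <- tips[[id]]
    tp$chars[1] <- "M"
    codons <- back_translate(tp$chars)
    cds <- paste(c(codons, "TAA"), collapse = "")
    cuts <- 3L * tp$marks$aa_index + tp$marks$phase
    segs <- substring(cds, c(1L, cuts + 1L), c(cuts, nchar(cds)))
    ilen <- sample(spec$min_intron_len:(3L * spec$min_intron_len),
                   length(cuts), replace = TRUE)
    intr <- vapply(ilen, function(l) {
      paste0("GT", random_nt(l - 4L), "AG")
    }, character(1))
    body <- segs[1]
    for (q in seq_along(intr)) body <- paste0(body, intr[q], segs[q + 1])
    fl5 <- random_nt(spec$flank_len)
    fl3 <- random_nt(spec$flank_len)
    plus <- paste0(fl5, body, fl3)
    strand <- sample(c("+", "-"), 1)
    # plus-strand exon layout
    ex_s <- integer(0); ex_e <- integer(0)
    pos <- spec$flank_len
    for (q in seq_along(segs)) {
      ex_s <- c(ex_s, pos)
      pos <- pos + nchar(segs[q])
      ex_e <- c(ex_e, pos)
      if (q <= length(intr)) pos <- pos + nchar(intr[q])
    }
    ctg <- paste0("ctg_", id)
    if (strand == "+") {
      seq <- plus
      exons <- cbind(ex_s, ex_e)
    } else {
      seq <- paste(revcomp_chars(strsplit(plus, "")[[1]]), collapse = "")
      Lc <- nchar(plus)
      exons <- cbind(Lc - ex_e, Lc - ex_s)  # transcription order preserved
    }
    genome[[ctg]] <- seq
    genes[[id]] <- gene_structure(gene_id = id,
                                  genome_id = sub("_p\\d+$", "", id),
                                  contig = ctg, strand = strand,
                                  exons = exons, source = "annotation")
  }
  proteins <- lapply(genes, translate_cds, genome = genome)
  for (id in names(proteins)) proteins[[id]]$protein_id <- id
  list(genome = genome, genes = genes, proteins = proteins,
       truth = list(genes = genes,
                    errors = data.frame(gene_id = character(),
                                        kind = character(),
                                        intron_index = integer(),
                                        detail = character())),
       spec = spec)
}

# --- transcript-space boundary helpers (strand-aware) ---------------------

# dinucleotide at the transcript-oriented start of intron k (donor) and
# just before exon k+1 (acceptor)
donor_dinuc <- function(gs, k, genome) {
  ctg <- genome[[gs$contig]]
  if (gs$strand == "+") {
    p <- gs$exons[k, 2]
    substr(ctg, p + 1L, p + 2L)
  } else {
    p <- gs$exons[k, 1]
    paste(revcomp_chars(strsplit(substr(ctg, p - 1L, p), "")[[1]]),
          collapse = "")
  }
}

acceptor_dinuc <- function(gs, k, genome) {
  ctg <- genome[[gs$contig]]
  if (gs$strand == "+") {
    p <- gs$exons[k + 1, 1]
    substr(ctg, p - 1L, p)
  } else {
    p <- gs$exons[k + 1, 2]
    paste(revcomp_chars(strsplit(substr(ctg, p + 1L, p + 2L), "")[[1]]),
          collapse = "")
  }
}

# move the donor (3' end of exon k) by delta transcript nt
shift_donor <- function(gs, k, delta) {
  if (gs$strand == "+") gs$exons[k, 2] <- gs$exons[k, 2] + delta
  else gs$exons[k, 1] <- gs$exons[k, 1] - delta
  gs
}

# move the acceptor (5' start of exon k+1) by delta transcript nt
# (positive delta shortens the exon)
shift_acceptor <- function(gs, k, delta) {
  if (gs$strand == "+") gs$exons[k + 1, 1] <- gs$exons[k + 1, 1] + delta
  else gs$exons[k + 1, 2] <- gs$exons[k + 1, 2] - delta
  gs
}

exon_len <- function(gs) gs$exons[, 2] - gs$exons[, 1]

intron_len <- function(gs) {
  ii <- intron_intervals(gs)
  ii$end - ii$start
}

# a corrupted candidate is plausible annotation only if it still encodes
# an open reading frame
clean_translation <- function(gs, genome) {
  p <- tryCatch(translate_cds(gs, genome), error = function(e) NULL)
  !is.null(p) && p$defects$n_premature_stops == 0 &&
    p$defects$n_ambiguous == 0
}

corrupt_one <- function(gs, kind, genome) {
  n_ex <- nrow(gs$exons)
  deltas <- sample(c(seq(3, 30, by = 3), -seq(3, 30, by = 3)))
  if (kind %in% c("shifted_donor", "shifted_acceptor")) {
    if (n_ex < 2) return(NULL)
    for (k in sample(n_ex - 1)) {
      for (d in deltas) {
        cand <- if (kind == "shifted_donor") shift_donor(gs, k, d)
                else shift_acceptor(gs, k, d)
        if (any(exon_len(cand) < 3) || any(intron_len(cand) < 8)) next
        kk <- if (kind == "shifted_donor") k else k
        if (donor_dinuc(cand, kk, genome) != "GT" ||
            acceptor_dinuc(cand, kk, genome) != "AG") next
        if (!clean_translation(cand, genome)) next
        return(list(gene = cand, detail = sprintf("intron %d by %+d nt", k, d),
                    intron_index = k))
      }
    }
    return(NULL)
  }
  if (kind == "skipped_exon") {
    if (n_ex < 3) return(NULL)
    for (k in resample(2:(n_ex - 1), n_ex - 2L)) {
      if (exon_len(gs)[k] %% 3L != 0L) next
      cand <- gs
      cand$exons <- cand$exons[-k, , drop = FALSE]
      if (!clean_translation(cand, genome)) next
      return(list(gene = cand, detail = sprintf("exon %d", k),
                  intron_index = k - 1L))
    }
    return(NULL)
  }
  if (kind == "extra_exon") {
    if (n_ex < 2) return(NULL)
    ctg <- genome[[gs$contig]]
    for (k in sample(n_ex - 1)) {
      ii <- intron_intervals(gs)[k, ]
      if (ii$end - ii$start < 40) next
      for (trial in 1:40) {
        x <- resample((ii$start + 10):(ii$end - 20), 1)
        len <- sample(seq(9, 30, by = 3), 1)
        y <- x + len
        if (y > ii$end - 10) next
        # need AG right before x and GT right at y in transcript space
        if (gs$strand == "+") {
          okA <- substr(ctg, x - 1L, x) == "AG"
          okD <- substr(ctg, y + 1L, y + 2L) == "GT"
          new_ex <- c(x, y)
        } else {
          okA <- paste(revcomp_chars(strsplit(substr(ctg, y + 1L, y + 2L),
                                              "")[[1]]), collapse = "") == "AG"
          okD <- paste(revcomp_chars(strsplit(substr(ctg, x - 1L, x),
                                              "")[[1]]), collapse = "") == "GT"
          new_ex <- c(x, y)
        }
        if (!okA || !okD) next
        cand <- gs
        cand$exons <- rbind(cand$exons[1:k, , drop = FALSE],
                            matrix(as.integer(new_ex), 1),
                            cand$exons[(k + 1):n_ex, , drop = FALSE])
        if (gs$strand == "-") {
          # keep transcription order (descending starts)
          o <- order(-cand$exons[, 1])
          cand$exons <- cand$exons[o, , drop = FALSE]
        }
        if (any(intron_len(cand) < 8)) next
        if (!clean_translation(cand, genome)) next
        return(list(gene = cand,
                    detail = sprintf("inserted [%d,%d) in intron %d", x, y, k),
                    intron_index = k))
      }
    }
    return(NULL)
  }
  if (kind == "wrong_TIS") {
    cds <- cds_sequence(gs, genome)
    s <- paste(cds$chars, collapse = "")
    # next in-frame ATG after the original start, inside the first exon
    first_len <- exon_len(gs)[1]
    cand_off <- seq(3, min(first_len - 3, 90), by = 3)
    for (d in cand_off) {
      if (substr(s, d + 1, d + 3) != "ATG") next
      cand <- gs
      if (gs$strand == "+") cand$exons[1, 1] <- cand$exons[1, 1] + d
      else cand$exons[1, 2] <- cand$exons[1, 2] - d
      if (!clean_translation(cand, genome)) next
      return(list(gene = cand, detail = sprintf("TIS moved %+d nt", d),
                  intron_index = NA_integer_))
    }
    return(NULL)
  }
  stop("unknown error kind: ", kind)
}

#' Inject annotation errors into a simulated family
#'
#' Each selected gene receives exactly one error: a donor or acceptor
#' moved to an alternative GT/AG (frame-preserving, so the corrupted
#' annotation still encodes an open reading frame, as real predictor
#' errors do), an internal in-frame exon skipped, a spurious in-frame
#' exon recruited from intronic sequence, or the start codon moved to the
#' next in-frame ATG.  Genes for which no alternative signal exists are
#' skipped and logged.
#'
#' @param sim result of [simulate_family()].
#' @param rates named numeric vector of per-gene corruption
#'   probabilities by kind (`shifted_donor`, `shifted_acceptor`,
#'   `skipped_exon`, `extra_exon`, `wrong_TIS`); their sum is the overall
#'   corruption rate.
#' @param seed RNG seed for the injection.
#' @return `sim` with corrupted `genes`/`proteins` and
#'   `truth$errors` filled (kind, detail, affected intron index); the
#'   true structures stay in `truth$genes`.
#' @export
inject_errors <- function(sim, rates = c(shifted_donor = 0.05,
                                         shifted_acceptor = 0.05,
                                         skipped_exon = 0.025,
                                         extra_exon = 0.025,
                                         wrong_TIS = 0.0),
                          seed = 1L) {
  stopifnot(all(rates >= 0), sum(rates) <= 1)
  set.seed(seed)
  errors <- sim$truth$errors
  for (id in names(sim$genes)) {
    u <- stats::runif(1)
    kind <- NA_character_
    acc <- 0
    for (kn in names(rates)) {
      acc <- acc + rates[[kn]]
      if (u < acc) { kind <- kn; break }
    }
    if (is.na(kind)) next
    res <- corrupt_one(sim$genes[[id]], kind, sim$genome)
    if (is.null(res)) {
      errors <- rbind(errors, data.frame(gene_id = id, kind = kind,
                                         intron_index = NA_integer_,
                                         detail = "skipped: no signal"))
      next
    }
    sim$genes[[id]] <- res$gene
    p <- translate_cds(res$gene, sim$genome)
    p$protein_id <- id
    sim$proteins[[id]] <- p
    errors <- rbind(errors, data.frame(gene_id = id, kind = kind,
                                       intron_index = res$intron_index,
                                       detail = res$detail))
  }
  sim$truth$errors <- errors
  sim
}

#' Fraction of corrupted intron boundaries restored by refinement
#'
#' For every logged splice-site error, checks whether the refined
#' structure contains the true intron with exactly the true genomic
#' coordinates.
#'
#' @param truth_genes named list of true [gene_structure()]s.
#' @param errors the `truth$errors` log of [inject_errors()].
#' @param refined_genes named list of refined structures.
#' @return list with `n_corrupted`, `n_recovered`, `rate`.
#' @export
intron_boundary_recovery <- function(truth_genes, errors, refined_genes) {
  splice_kinds <- c("shifted_donor", "shifted_acceptor", "skipped_exon",
                    "extra_exon")
  rows <- errors[errors$kind %in% splice_kinds &
                   !startsWith(errors$detail, "skipped"), , drop = FALSE]
  n <- 0L; rec <- 0L
  for (k in seq_len(nrow(rows))) {
    id <- rows$gene_id[k]
    tr <- truth_genes[[id]]
    rf <- refined_genes[[id]]
    n <- n + 1L
    if (is.null(rf)) next
    ti <- intron_intervals(tr)
    ri <- intron_intervals(rf)
    tkey <- paste(ti$start, ti$end)
    rkey <- paste(ri$start, ri$end)
    if (all(tkey %in% rkey) && length(rkey) == length(tkey)) rec <- rec + 1L
  }
  list(n_corrupted = n, n_recovered = rec,
       rate = if (n > 0) rec / n else NA_real_)
}

#' Write a simulated family to disk (FASTA + GFF3 + truth JSON)
#' @param sim result of [simulate_family()] or [inject_errors()].
#' @param dir output directory (created if needed).
#' @export
write_family <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- Biostrings::DNAStringSet(unlist(sim$genome))
  Biostrings::writeXStringSet(seqs, file.path(dir, "genome.fa"))
  write_gff3(sim$genes, file.path(dir, "annotation.gff3"))
  write_gff3(sim$truth$genes, file.path(dir, "truth.gff3"))
  truth <- list(errors = sim$truth$errors,
                genes = lapply(sim$truth$genes, function(g) {
                  list(gene_id = g$gene_id, contig = g$contig,
                       strand = g$strand,
                       exons = apply(g$exons, 1, function(r) as.list(r)))
                }))
  writeLines(jsonlite::toJSON(truth, dataframe = "rows", auto_unbox = TRUE),
             file.path(dir, "truth.json"))
  invisible(dir)
}
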