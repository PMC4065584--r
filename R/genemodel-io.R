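# Gene structures, translation, and annotation I/O.
#
# Coordinates are 0-based half-open internally; GFF3 (1-based inclusive)
# is converted at the boundary.  Exons are kept in transcription order,
# so a minus-strand gene lists its highest-coordinate exon first.

#' Gene structure on a genome
#'
#' @param gene_id,genome_id,contig identifiers.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix of (start, end) genomic intervals,
#'   0-based half-open, in transcription order.
#' @param frameshift_events data.frame with columns `pos` (0-based genomic
#'   coordinate of the first transcribed nucleotide of the affected codon)
#'   and `offset` (extra nucleotides consumed by that codon: +1/+2 skip,
#'   -1/-2 short codon).  Annotations read from GFF3 never contain these;
#'   only the spliced aligner creates them.
#' @param premature_stops integer vector of 0-based CDS codon indices.
#' @param source `"annotation"` or `"refined"`.
#' @return An object of class `gene_structure`.
#' @export
gene_structure <- function(gene_id, genome_id, contig, strand, exons,
                           frameshift_events = NULL,
                           premature_stops = integer(),
                           source = "annotation") {
  if (is.null(frameshift_events)) {
    frameshift_events <- data.frame(pos = integer(), offset = integer())
  }
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  structure(list(gene_id = gene_id, genome_id = genome_id, contig = contig,
                 strand = strand, exons = exons,
                 frameshift_events = frameshift_events,
                 premature_stops = as.integer(premature_stops),
                 source = source),
            class = "gene_structure")
}

#' Validate a gene structure
#'
#' Checks that exons are non-empty, non-overlapping, separated by introns
#' of at least `min_intron_len` (and never less than 4 nt, room for
#' GT..AG), and that the coding length closes to whole codons once
#' frameshift offsets are taken out.
#'
#' @param gs a [gene_structure()].
#' @param min_intron_len minimal allowed intron length in nt.
#' @return `TRUE` invisibly; otherwise an error.
#' @export
validate_gene_structure <- function(gs, min_intron_len = 4L) {
  ex <- gs$exons
  stopifnot(nrow(ex) >= 1, all(ex[, 2] > ex[, 1]))
  if (nrow(ex) > 1) {
    ord <- if (gs$strand == "+") ex else ex[nrow(ex):1, , drop = FALSE]
    if (any(diff(ord[, 1]) <= 0) || any(ord[-1, 1] < ord[-nrow(ord), 2]))
      stop("exons overlap or are out of order for gene ", gs$gene_id)
    gaps <- ord[-1, 1] - ord[-nrow(ord), 2]
    if (any(gaps < max(4L, min_intron_len)))
      stop("intron shorter than ", max(4L, min_intron_len),
           " nt in gene ", gs$gene_id)
  }
  clen <- sum(ex[, 2] - ex[, 1]) - sum(gs$frameshift_events$offset)
  if (clen %% 3L != 0L)
    stop("coding length of gene ", gs$gene_id,
         " does not close to whole codons")
  invisible(TRUE)
}

intron_intervals <- function(gs) {
  ex <- gs$exons
  if (nrow(ex) < 2) {
    return(data.frame(start = integer(), end = integer()))
  }
  if (gs$strand == "+") {
    data.frame(start = ex[-nrow(ex), 2], end = ex[-1, 1])
  } else {
    data.frame(start = ex[-1, 2], end = ex[-nrow(ex), 1])
  }
}

#' Annotated protein: residues plus ordered intron marks
#'
#' @param protein_id identifier.
#' @param residues amino-acid string over the 20 letters plus `X`.
#' @param introns data.frame with columns `aa_index` (0-based residue
#'   index; a phase-0 intron is attached to the residue immediately after
#'   the junction) and `phase` (0/1/2).
#' @param gene the parental [gene_structure()], or `NULL`.
#' @param defects list with counts `n_frameshifts`, `n_premature_stops`,
#'   `n_ambiguous`.
#' @return An object of class `annotated_protein`.
#' @export
annotated_protein <- function(protein_id, residues,
                              introns = NULL, gene = NULL,
                              defects = list(n_frameshifts = 0L,
                                             n_premature_stops = 0L,
                                             n_ambiguous = 0L)) {
  if (is.null(introns)) {
    introns <- data.frame(aa_index = integer(), phase = integer())
  }
  pos <- 3L * introns$aa_index + introns$phase
  if (length(pos) > 1 && any(diff(pos) <= 0))
    stop("intron CDS positions must be strictly increasing")
  if (any(introns$phase < 0 | introns$phase > 2))
    stop("intron phase must be 0, 1 or 2")
  if (any(introns$aa_index < 0 | introns$aa_index > nchar(residues)))
    stop("intron aa_index out of range")
  structure(list(protein_id = protein_id, residues = residues,
                 introns = introns, gene = gene, defects = defects),
            class = "annotated_protein")
}

# genome: accept a named character vector or a DNAStringSet
as_genome <- function(genome) {
  if (is.character(genome)) return(genome)
  stats::setNames(as.character(genome), names(genome))
}

#' Read a genome FASTA into a named character vector
#' @param path FASTA file.
#' @return Named character vector of contig sequences (names cut at the
#'   first whitespace).
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  as_genome(x)
}

# CDS nucleotide characters and their 0-based genomic coordinates, in
# transcription order (minus-strand exons complemented).
cds_sequence <- function(gs, genome) {
  genome <- as_genome(genome)
  if (!gs$contig %in% names(genome))
    stop("contig ", gs$contig, " not present in genome")
  ctg <- genome[[gs$contig]]
  if (max(gs$exons[, 2]) > nchar(ctg) || min(gs$exons[, 1]) < 0)
    stop("CDS of gene ", gs$gene_id, " outside contig bounds")
  chars <- character(0)
  pos <- integer(0)
  for (k in seq_len(nrow(gs$exons))) {
    s <- gs$exons[k, 1]; e <- gs$exons[k, 2]
    seg <- strsplit(substr(ctg, s + 1L, e), "")[[1]]
    if (gs$strand == "+") {
      chars <- c(chars, seg)
      pos <- c(pos, seq.int(s, e - 1L))
    } else {
      chars <- c(chars, revcomp_chars(seg))
      pos <- c(pos, seq.int(e - 1L, s))
    }
  }
  list(chars = toupper(chars), pos = pos)
}

#' Translate the CDS of a gene structure
#'
#' Standard-table translation of the spliced CDS.  Internal stop codons
#' are emitted as `X` and tallied as premature stops; codons containing
#' `N` are emitted as `X` and tallied as ambiguous; frameshift events make
#' the affected codon consume `3 + offset` nucleotides (the residue is
#' translated from the last three, or is `X` for short codons).  A
#' terminal stop codon is dropped silently.  Intron marks are derived from
#' the junctions between consecutive exons.
#'
#' @param gs a [gene_structure()].
#' @param genome named character vector (or `DNAStringSet`) of contigs.
#' @return An [annotated_protein()].
#' @export
translate_cds <- function(gs, genome) {
  cds <- cds_sequence(gs, genome)
  n <- length(cds$chars)
  if (n < 3L) stop("CDS of gene ", gs$gene_id, " shorter than 3 nt")

  fs <- gs$frameshift_events
  fs_at <- integer(0)
  if (nrow(fs) > 0) {
    fs_at <- match(fs$pos, cds$pos)   # cds index where each event fires
    if (anyNA(fs_at))
      stop("frameshift position not within the CDS of gene ", gs$gene_id)
  }

  # junction CDS indices (number of nt before each junction)
  exlen <- gs$exons[, 2] - gs$exons[, 1]
  junc <- if (length(exlen) > 1) cumsum(exlen)[-length(exlen)] else integer(0)

  aa <- aa_alphabet()
  res <- character(0)
  codon_start <- integer(0)   # 0-based cds index of each codon's first nt
  codon_len <- integer(0)
  n_stop <- 0L; n_amb <- 0L; n_fs <- 0L
  stops <- integer(0)
  i <- 0L                      # 0-based cds cursor
  while (i + 3L <= n) {
    take <- 3L
    hit <- which(fs_at == i + 1L)
    if (length(hit) == 1L) {
      take <- 3L + fs$offset[hit]
      n_fs <- n_fs + 1L
    }
    if (i + take > n) break
    if (take >= 3L) {
      cdn <- cds$chars[(i + take - 2L):(i + take)]
      code <- codons_to_aa(cdn)
    } else {
      code <- 20L
    }
    codon_start <- c(codon_start, i)
    codon_len <- c(codon_len, take)
    if (code == 21L) {
      if (i + take >= n) { # terminal stop codon: drop
        i <- i + take
        codon_start <- codon_start[-length(codon_start)]
        codon_len <- codon_len[-length(codon_len)]
        break
      }
      stops <- c(stops, length(res))
      n_stop <- n_stop + 1L
      res <- c(res, "X")
    } else if (code == 20L) {
      if (take >= 3L) n_amb <- n_amb + 1L
      res <- c(res, "X")
    } else {
      res <- c(res, aa[code + 1L])
    }
    i <- i + take
  }

  # map junctions to (aa_index, phase)
  marks <- data.frame(aa_index = integer(), phase = integer())
  if (length(junc) > 0 && length(codon_start) > 0) {
    ends <- codon_start + codon_len
    for (J in junc) {
      k <- which(codon_start < J & ends > J)
      if (length(k) == 1L) {
        ph <- J - codon_start[k]
        if (ph > 2L) ph <- 2L
        marks <- rbind(marks, data.frame(aa_index = k - 1L, phase = ph))
      } else {
        k <- which(codon_start == J)
        if (length(k) == 1L)
          marks <- rbind(marks, data.frame(aa_index = k - 1L, phase = 0L))
        else if (J >= max(ends))
          marks <- rbind(marks,
                         data.frame(aa_index = length(res), phase = 0L))
      }
    }
    marks <- marks[order(3L * marks$aa_index + marks$phase), , drop = FALSE]
    marks <- marks[!duplicated(3L * marks$aa_index + marks$phase), ,
                   drop = FALSE]
    rownames(marks) <- NULL
  }

  annotated_protein(
    protein_id = gs$gene_id,
    residues = paste(res, collapse = ""),
    introns = marks, gene = gs,
    defects = list(n_frameshifts = n_fs, n_premature_stops = n_stop,
                   n_ambiguous = n_amb))
}

#' Read annotated genes from GFF3 + genome FASTA
#'
#' Parses `CDS` features grouped by their `Parent` (mRNA) attribute and
#' translates each gene, yielding one [annotated_protein()] per mRNA with
#' intron marks derived from the gaps between CDS features.
#'
#' @param gff3_path GFF3 annotation.
#' @param genome genome as named character vector, `DNAStringSet`, or a
#'   FASTA path.
#' @param genome_id label stored on the gene structures; defaults to the
#'   GFF3 file name.
#' @return List of lists with elements `gene` and `protein`.
#' @export
read_annotated_genes <- function(gff3_path, genome,
                                 genome_id = sub("\\.gff3?$", "",
                                                 basename(gff3_path))) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- read_genome_fasta(genome)
  genome <- as_genome(genome)
  gr <- rtracklayer::import(gff3_path)
  cds <- gr[tolower(as.character(gr$type)) == "cds"]
  if (length(cds) == 0) return(list())
  parent <- vapply(cds$Parent, function(p) p[[1]][1], character(1))
  out <- list()
  for (id in unique(parent)) {
    sel <- cds[parent == id]
    contig <- as.character(GenomicRanges::seqnames(sel))[1]
    if (!contig %in% names(genome))
      stop("contig ", contig, " referenced by ", id,
           " is missing from the genome FASTA")
    strand <- as.character(GenomicRanges::strand(sel))[1]
    st <- GenomicRanges::start(sel) - 1L
    en <- GenomicRanges::end(sel)
    o <- order(st)
    if (strand == "-") o <- rev(o)
    gs <- gene_structure(gene_id = id, genome_id = genome_id,
                         contig = contig, strand = strand,
                         exons = cbind(st[o], en[o]))
    if (max(en) > nchar(genome[[contig]]))
      stop("CDS of ", id, " outside bounds of contig ", contig)
    out[[id]] <- list(gene = gs, protein = translate_cds(gs, genome))
  }
  out
}

#' Write gene structures to GFF3
#'
#' Emits gene/mRNA/CDS rows with `Parent` attributes and correct phase
#' fields; the inverse of [read_annotated_genes()].
#'
#' @param genes list of [gene_structure()].
#' @param path output file.
#' @export
write_gff3 <- function(genes, path) {
  rows <- list()
  for (gs in genes) {
    ex <- gs$exons
    span <- c(min(ex[, 1]), max(ex[, 2]))
    exlen <- ex[, 2] - ex[, 1]
    cum <- c(0L, cumsum(exlen))[seq_len(nrow(ex))]
    phase <- (3L - (cum %% 3L)) %% 3L
    rows[[length(rows) + 1L]] <- data.frame(
      seqnames = gs$contig, start = span[1] + 1L, end = span[2],
      strand = gs$strand, type = c("gene", "mRNA"),
      ID = c(paste0(gs$gene_id, ".g"), gs$gene_id),
      Parent = c(NA, paste0(gs$gene_id, ".g")), phase = NA_integer_,
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      seqnames = gs$contig, start = ex[, 1] + 1L, end = ex[, 2],
      strand = gs$strand, type = "CDS",
      ID = paste0(gs$gene_id, ".cds", seq_len(nrow(ex))),
      Parent = gs$gene_id, phase = phase, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand)
  gr$type <- df$type
  gr$ID <- df$ID
  gr$Parent <- IRanges::CharacterList(lapply(df$Parent, function(p) {
    if (is.na(p)) character(0) else p
  }))
  gr$phase <- df$phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Reconcile a provided protein with the translated one
#'
#' Minor discrepancies confined to the first and/or last residue (partial
#' terminal codons, missing terminal stop) are resolved by keeping the
#' translated residue; any larger discrepancy flags the gene for
#' re-mapping by spliced alignment.
#'
#' @param given_protein amino-acid string as provided by the annotation.
#' @param translated the [annotated_protein()] from [translate_cds()].
#' @return `translated` with a `$reconcile` record (`status` one of
#'   `"ok"`, `"terminal_fixed"`, `"remap"`, plus the mismatch count).
#' @export
reconcile <- function(given_protein, translated) {
  stopifnot(nchar(given_protein) > 0, nchar(translated$residues) > 0)
  g <- strsplit(given_protein, "")[[1]]
  t <- strsplit(translated$residues, "")[[1]]
  status <- "remap"; n_mm <- NA_integer_
  if (length(g) == length(t)) {
    mm <- which(g != t)
    n_mm <- length(mm)
    if (n_mm == 0L) status <- "ok"
    else if (all(mm %in% c(1L, length(t)))) status <- "terminal_fixed"
  } else if (abs(length(g) - length(t)) == 1L) {
    k <- min(length(g), length(t))
    core <- sum(g[seq_len(k)] != t[seq_len(k)])
    n_mm <- core + 1L
    if (core == 0L || (core == 1L && which(g[seq_len(k)] != t[seq_len(k)])[1] == 1L))
      status <- "terminal_fixed"
  }
  translated$reconcile <- list(status = status, n_mismatch = n_mm)
  translated
}

#' First-stage filters
#'
#' Removes proteins whose length is not greater than `min_protein_len`
#' and genes whose genomic span contains at least `max_ambiguous_nt`
#' ambiguous nucleotides.
#'
#' @param items list of `list(gene=, protein=)` as returned by
#'   [read_annotated_genes()].
#' @param cfg a [gsa_config()].
#' @param genome the genome (for counting `N`s in gene spans).
#' @return `list(kept=, removed=)`; `removed` is a data.frame of ids and
#'   reasons.
#' @export
first_filter <- function(items, cfg, genome) {
  genome <- as_genome(genome)
  kept <- list()
  removed <- data.frame(id = character(), reason = character())
  for (it in items) {
    id <- it$protein$protein_id
    if (cfg$min_protein_len > 0 &&
        nchar(it$protein$residues) <= cfg$min_protein_len) {
      removed <- rbind(removed, data.frame(id = id, reason = "length"))
      next
    }
    gs <- it$gene
    span <- substr(genome[[gs$contig]], min(gs$exons[, 1]) + 1L,
                   max(gs$exons[, 2]))
    n_amb <- sum(strsplit(span, "")[[1]] == "N")
    if (n_amb >= cfg$max_ambiguous_nt) {
      removed <- rbind(removed, data.frame(id = id, reason = "ambiguous"))
      next
    }
    kept[[id]] <- it
  }
  list(kept = kept, removed = removed)
}

#' Serialize an annotated protein (with intron marks) to JSON
#' @param p an [annotated_protein()].
#' @param path optional output file.
#' @return JSON string (invisibly if written to a file).
#' @export
protein_to_json <- function(p, path = NULL) {
  x <- list(protein_id = p$protein_id, residues = p$residues,
            introns = p$introns, defects = p$defects)
  js <- jsonlite::toJSON(x, dataframe = "rows", auto_unbox = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
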