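# Assessment of gene-structure-aware alignments: conserved blocks and
# variable regions, recursive Dixon outlier analysis of region lengths
# and divergences, intron concordance, defect points, and R/Q/P labels.

#' Locate conserved blocks in an alignment
#'
#' Maximal runs of at least `window` columns whose mean weighted
#' sum-of-pairs column score reaches `theta` and whose gap fraction stays
#' below `max_gap_frac`.
#'
#' @param msa a `gsa_msa`.
#' @param cfg a [gsa_config()] (uses `block_window`, `block_theta`,
#'   `block_max_gap`).
#' @param params scoring parameters.
#' @return data.frame of column intervals (`start`, `end`), 0-based
#'   half-open.
#' @export
find_conserved_blocks <- function(msa, cfg = gsa_config(),
                                  params = score_params()) {
  n <- length(msa$ids)
  L <- ncol(msa$aln)
  if (n < 2 || L == 0) {
    return(data.frame(start = integer(), end = integer()))
  }
  st <- msa_sp_stats(msa, params)
  score <- st$colscore / max(st$wtot, 1e-12)
  gapfrac <- colSums(msa$aln == "-") / n
  good <- score >= cfg$block_theta & gapfrac <= cfg$block_max_gap
  r <- rle(good)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= cfg$block_window
  data.frame(start = starts[keep] - 1L, end = ends[keep])
}

#' Variable regions complementary to the conserved blocks
#'
#' @param blocks data.frame from [find_conserved_blocks()].
#' @param n_columns alignment length.
#' @return data.frame of (start, end) 0-based half-open intervals that
#'   tile the columns together with the blocks; empty intervals are
#'   dropped.
#' @export
variable_regions <- function(blocks, n_columns) {
  bounds <- c(0L, as.vector(t(as.matrix(blocks))), n_columns)
  starts <- bounds[seq(1, length(bounds), by = 2)]
  ends <- bounds[seq(2, length(bounds), by = 2)]
  keep <- ends > starts
  data.frame(start = starts[keep], end = ends[keep])
}

# Dixon two-sided critical values, alpha = 0.10 (Rorabacher 1991,
# two-tailed 90% confidence): r10 for n = 3..7, r11 for 8..10, r21 for
# 11..13, r22 for 14..30.
dixon_crit_010 <- c(
  0.941, 0.765, 0.642, 0.560, 0.507,          # n = 3..7
  0.554, 0.512, 0.477,                        # n = 8..10
  0.576, 0.546, 0.521,                        # n = 11..13
  0.546, 0.525, 0.507, 0.490, 0.475, 0.462,   # n = 14..19
  0.450, 0.440, 0.430, 0.421, 0.413, 0.406,   # n = 20..25
  0.399, 0.393, 0.387, 0.381, 0.376)          # n = 26..30

#' Recursive Dixon outlier detection
#'
#' Two-sided Dixon ratio test with the n-appropriate statistic (r10 for
#' 3 <= n <= 7, r11 for 8..10, r21 for 11..13, r22 for 14..30) against
#' published alpha = 0.1 critical values; a detected extreme is removed
#' and the test repeated until nothing is flagged or fewer than 3 values
#' remain.  For n > 30 a robust `|z| > z(1-alpha/2)` rule on median/MAD
#' is used instead.
#'
#' @param values numeric vector.
#' @param alpha significance level; the table covers 0.1, any other
#'   value falls back to the robust z rule.
#' @return Integer indices (into `values`) of the flagged outliers.
#' @export
dixon_outliers <- function(values, alpha = 0.1) {
  idx <- seq_along(values)
  out <- integer(0)
  repeat {
    n <- length(values)
    if (n < 3) break
    if (n > 30 || abs(alpha - 0.1) > 1e-9) {
      m <- stats::median(values)
      s <- stats::mad(values)
      if (s <= 0) break
      z <- abs(values - m) / s
      bad <- which(z > stats::qnorm(1 - alpha / 2) & z == max(z))[1]
      if (is.na(bad) || z[bad] <= stats::qnorm(1 - alpha / 2)) break
      out <- c(out, idx[bad])
      values <- values[-bad]; idx <- idx[-bad]
      next
    }
    o <- order(values)
    x <- values[o]
    rng <- x[n] - x[1]
    if (rng <= 0) break
    if (n <= 7) {
      lo <- (x[2] - x[1]) / (x[n] - x[1])
      hi <- (x[n] - x[n - 1]) / (x[n] - x[1])
    } else if (n <= 10) {
      lo <- (x[2] - x[1]) / (x[n - 1] - x[1])
      hi <- (x[n] - x[n - 1]) / (x[n] - x[2])
    } else if (n <= 13) {
      lo <- (x[3] - x[1]) / (x[n - 1] - x[1])
      hi <- (x[n] - x[n - 2]) / (x[n] - x[2])
    } else {
      lo <- (x[3] - x[1]) / (x[n - 2] - x[1])
      hi <- (x[n] - x[n - 2]) / (x[n] - x[3])
    }
    lo[!is.finite(lo)] <- 0; hi[!is.finite(hi)] <- 0
    crit <- dixon_crit_010[n - 2L]
    if (max(lo, hi) <= crit) break
    bad <- if (hi >= lo) o[n] else o[1]
    out <- c(out, idx[bad])
    values <- values[-bad]; idx <- idx[-bad]
  }
  sort(out)
}

# residues of each member inside a column interval (0-based half-open)
region_lengths <- function(msa, region) {
  cols <- (region$start + 1L):region$end
  rowSums(msa$aln[, cols, drop = FALSE] != "-")
}

#' Indel outlier scan over variable regions
#'
#' Within each variable region, the per-member residue counts are tested
#' by recursive Dixon analysis; every detection adds one outlier to the
#' member.  A low-side outlier in the first/last region sets the 5'/3'
#' terminal-deletion flag (the genomic window should be extended on that
#' side in the next prediction cycle).
#'
#' @param msa a `gsa_msa`.
#' @param regions data.frame from [variable_regions()].
#' @param alpha Dixon significance level.
#' @return list with `counts` (named outlier counts), `flag5`, `flag3`
#'   (named logicals).
#' @export
indel_outlier_scan <- function(msa, regions, alpha = 0.1) {
  ids <- msa$ids
  counts <- stats::setNames(integer(length(ids)), ids)
  flag5 <- flag3 <- stats::setNames(logical(length(ids)), ids)
  L <- ncol(msa$aln)
  for (r in seq_len(nrow(regions))) {
    reg <- regions[r, ]
    lens <- region_lengths(msa, reg)
    hits <- dixon_outliers(lens, alpha)
    for (h in hits) {
      counts[h] <- counts[h] + 1L
      low <- lens[h] < stats::median(lens)
      if (low && reg$start == 0L) flag5[h] <- TRUE
      if (low && reg$end == L) flag3[h] <- TRUE
    }
  }
  list(counts = counts, flag5 = flag5, flag3 = flag3)
}

#' Divergence outlier scan over variable regions
#'
#' Within each region the average fraction of mismatched aligned residue
#' pairs between one member and the rest is computed; the set of values
#' is tested by recursive Dixon analysis.  Catches compensating frame
#' shifts (garbled stretches of unchanged length) that the indel scan
#' cannot see.
#'
#' @inheritParams indel_outlier_scan
#' @return Named outlier counts.
#' @export
divergence_outlier_scan <- function(msa, regions, alpha = 0.1) {
  ids <- msa$ids
  n <- length(ids)
  counts <- stats::setNames(integer(n), ids)
  if (nrow(regions) == 0) return(counts)
  mc <- msa_codes(msa)
  div <- .divergence_stats(mc$codes,
                           matrix(as.integer(c(regions$start, regions$end)),
                                  ncol = 2))
  for (r in seq_len(nrow(regions))) {
    ok <- which(!is.na(div[, r]))
    hits <- dixon_outliers(div[ok, r], alpha)
    for (h in ok[hits]) counts[h] <- counts[h] + 1L
  }
  counts
}

#' Intron concordance and the concordant/discordant difference
#'
#' An intron is concordant if at least one other member has an intron at
#' the same alignment column with the same phase; otherwise it is a
#' lonesome (discordant) intron.  `delta_cdi` is the number of
#' concordant minus the number of lonesome introns.
#'
#' @param msa a `gsa_msa`.
#' @return list with `marks` (data.frame member/column/phase/concordant),
#'   `n_concordant`, `n_lonesome`, `delta_cdi`, and per-member lonesome
#'   counts.
#' @export
intron_concordance <- function(msa) {
  rows <- do.call(rbind, lapply(msa$ids, function(id) {
    df <- msa$introns[[id]]
    if (nrow(df) == 0) return(NULL)
    data.frame(member = id, column = df$column, phase = df$phase)
  }))
  if (is.null(rows) || nrow(rows) == 0) {
    return(list(marks = data.frame(member = character(), column = integer(),
                                   phase = integer(), concordant = logical()),
                n_concordant = 0L, n_lonesome = 0L, delta_cdi = 0L,
                lonesome_by_member = stats::setNames(integer(length(msa$ids)),
                                                     msa$ids)))
  }
  key <- paste(rows$column, rows$phase)
  conc <- vapply(seq_len(nrow(rows)), function(k) {
    any(key == key[k] & rows$member != rows$member[k])
  }, logical(1))
  rows$concordant <- conc
  lonely <- stats::setNames(integer(length(msa$ids)), msa$ids)
  tb <- table(rows$member[!conc])
  lonely[names(tb)] <- as.integer(tb)
  list(marks = rows,
       n_concordant = sum(conc), n_lonesome = sum(!conc),
       delta_cdi = sum(conc) - sum(!conc),
       lonesome_by_member = lonely)
}

#' Defect points and R/Q/P label of one member
#'
#' Points = indel outliers + divergence outliers + 1 if the gene has at
#' least one lonesome intron + 2 for every frame shift, premature stop,
#' and ambiguity event.  Label: "R" at 0 points, "Q" below `max_defect`,
#' otherwise "P".
#'
#' @param breakdown list with `indel_outliers`, `divergence_outliers`,
#'   `n_lonesome`, `n_frameshifts`, `n_premature_stops`, `n_ambiguous`.
#' @param cfg a [gsa_config()].
#' @return `list(points=, label=)`.
#' @export
defect_points_and_label <- function(breakdown, cfg = gsa_config()) {
  amb_events <- if (cfg$ambiguous_per_residue) breakdown$n_ambiguous
                else as.integer(breakdown$n_ambiguous > 0)
  points <- breakdown$indel_outliers + breakdown$divergence_outliers +
    as.integer(breakdown$n_lonesome > 0) +
    2L * (breakdown$n_frameshifts + breakdown$n_premature_stops + amb_events)
  label <- if (points == 0L) "R"
           else if (points < cfg$max_defect) "Q"
           else "P"
  list(points = as.integer(points), label = label)
}

#' Assess every member of an alignment
#'
#' Runs the conserved-block search, the indel and divergence outlier
#' scans, and the intron-concordance analysis, combines them with the
#' per-gene translation defects into defect points and R/Q/P labels, and
#' aggregates cluster-level metrics (outlier totals, concordant/lonesome
#' intron counts and their difference, the summed per-region length
#' standard deviations, and nSP/nWSP).
#'
#' @param msa a `gsa_msa` whose `proteins` carry defect tallies.
#' @param cfg a [gsa_config()].
#' @param params scoring parameters.
#' @return An object of class `gsa_assessment`: list with `members`
#'   (one row per member) and `cluster` (metric list), plus the blocks
#'   and regions used.
#' @export
assess_msa <- function(msa, cfg = gsa_config(), params = score_params()) {
  blocks <- find_conserved_blocks(msa, cfg, params)
  regions <- variable_regions(blocks, ncol(msa$aln))
  indel <- indel_outlier_scan(msa, regions, cfg$alpha)
  diver <- divergence_outlier_scan(msa, regions, cfg$alpha)
  conc <- intron_concordance(msa)
  rows <- lapply(msa$ids, function(id) {
    p <- msa$proteins[[id]]
    defects <- if (!is.null(p)) p$defects
               else list(n_frameshifts = 0L, n_premature_stops = 0L,
                         n_ambiguous = 0L)
    br <- list(indel_outliers = indel$counts[[id]],
               divergence_outliers = diver[[id]],
               n_lonesome = conc$lonesome_by_member[[id]],
               n_frameshifts = defects$n_frameshifts,
               n_premature_stops = defects$n_premature_stops,
               n_ambiguous = defects$n_ambiguous)
    pl <- defect_points_and_label(br, cfg)
    data.frame(id = id, indel_outliers = br$indel_outliers,
               divergence_outliers = br$divergence_outliers,
               n_lonesome = br$n_lonesome,
               n_frameshifts = br$n_frameshifts,
               n_premature_stops = br$n_premature_stops,
               n_ambiguous = br$n_ambiguous,
               defect_points = pl$points, label = pl$label,
               flag5 = indel$flag5[[id]], flag3 = indel$flag3[[id]],
               stringsAsFactors = FALSE)
  })
  members <- do.call(rbind, rows)
  rownames(members) <- members$id
  sum_sd <- 0
  for (r in seq_len(nrow(regions))) {
    lens <- region_lengths(msa, regions[r, ])
    if (length(lens) > 1) sum_sd <- sum_sd + stats::sd(lens)
  }
  cluster <- list(
    n_outlier_indels = sum(members$indel_outliers),
    n_outlier_divergences = sum(members$divergence_outliers),
    n_concordant_introns = conc$n_concordant,
    n_lonesome_introns = conc$n_lonesome,
    delta_cdi = conc$delta_cdi,
    sum_sd_lengths = sum_sd,
    nSP = nsp_score(msa, params),
    nWSP = nwsp_score(msa, params))
  structure(list(members = members, cluster = cluster,
                 blocks = blocks, regions = regions),
            class = "gsa_assessment")
}

#' @export
print.gsa_assessment <- function(x, ...) {
  cat("gsa_assessment:", nrow(x$members), "members;",
      sum(x$members$label == "R"), "R /",
      sum(x$members$label == "Q"), "Q /",
      sum(x$members$label == "P"), "P; delta_cdi =",
      x$cluster$delta_cdi, "\n")
  invisible(x)
}

#' Write an assessment report as TSV (members) + JSON (cluster metrics)
#' @param report a `gsa_assessment`.
#' @param tsv_path,json_path output files.
#' @export
write_assessment <- function(report, tsv_path, json_path) {
  utils::write.table(report$members, tsv_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  writeLines(jsonlite::toJSON(report$cluster, auto_unbox = TRUE,
                              digits = NA), json_path)
  invisible(tsv_path)
}
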