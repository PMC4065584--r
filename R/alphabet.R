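# Residue alphabet, substitution matrix, and codon translation tables.
# The working alphabet is the 20 standard amino acids plus 'X', which is
# used for ambiguous codons and for premature stops kept in-frame so that
# the residue string stays alignable.

aa_alphabet <- function() {
  c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
}

#' Substitution matrix used for alignment and assessment
#'
#' BLOSUM62 restricted to the 20 standard amino acids, extended with an
#' 'X' row/column scoring 0 against everything (so that residues standing
#' in for ambiguities or masked stops neither reward nor penalize any
#' pairing).
#'
#' @return A 21 x 21 numeric matrix with dimnames over the alphabet
#'   `ACDEFGHIKLMNPQRSTVWYX`.
#' @export
sub_matrix <- function() {
  if (!is.null(.gsa_env$sub_matrix)) return(.gsa_env$sub_matrix)
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  aa <- aa_alphabet()
  aa20 <- setdiff(aa, "X")
  m <- matrix(0, 21L, 21L, dimnames = list(aa, aa))
  m[aa20, aa20] <- e$BLOSUM62[aa20, aa20]
  .gsa_env$sub_matrix <- m
  m
}

# Mean of the positive entries of the 20x20 core; basis for the default
# intron bonus (2x) and the conserved-block threshold (0.5x).
avg_positive_score <- function(m = sub_matrix()) {
  core <- m[1:20, 1:20]
  mean(core[core > 0])
}

# Codon -> residue code lookup used by both the R translator and the C++
# spliced-alignment kernel.  Nucleotides are coded A=0, C=1, G=2, T=3,
# other=4; index = n1*25 + n2*5 + n3 (0-based).  Values: 0..19 index into
# aa_alphabet(), 20 = X (any ambiguity), 21 = stop.
codon_aa_table <- function() {
  if (!is.null(.gsa_env$codon_table)) return(.gsa_env$codon_table)
  nts <- c("A", "C", "G", "T", "N")
  aa <- aa_alphabet()
  tab <- integer(125L)
  gc <- Biostrings::GENETIC_CODE
  k <- 1L
  for (n1 in 1:5) for (n2 in 1:5) for (n3 in 1:5) {
    if (n1 == 5L || n2 == 5L || n3 == 5L) {
      tab[k] <- 20L
    } else {
      cdn <- paste0(nts[n1], nts[n2], nts[n3])
      r <- gc[[cdn]]
      tab[k] <- if (r == "*") 21L else match(r, aa) - 1L
    }
    k <- k + 1L
  }
  .gsa_env$codon_table <- tab
  tab
}

# encode a nucleotide character vector as 0..4
encode_nt <- function(chars) {
  code <- match(chars, c("A", "C", "G", "T"))
  code[is.na(code)] <- 5L
  code - 1L
}

# translate a vector of nucleotide characters (length divisible by 3 not
# required; trailing partial codon ignored) into residue codes
codons_to_aa <- function(nt_chars) {
  n <- length(nt_chars) %/% 3L
  if (n == 0L) return(integer(0))
  code <- encode_nt(nt_chars[seq_len(3L * n)])
  idx <- code[seq(1L, by = 3L, length.out = n)] * 25L +
    code[seq(2L, by = 3L, length.out = n)] * 5L +
    code[seq(3L, by = 3L, length.out = n)] + 1L
  codon_aa_table()[idx]
}

revcomp_chars <- function(chars) {
  rev(chartr("ACGTN", "TGCAN", chars))
}
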