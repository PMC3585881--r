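# Internal sequence helpers. Sequences are handled as plain uppercase DNA
# strings internally; RNA (U) input is accepted everywhere and converted.

DNA_BASES <- c("A", "C", "G", "T")

as_dna <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

as_rna <- function(x) {
  x <- toupper(x)
  gsub("T", "U", x, fixed = TRUE)
}

#' Reverse complement of DNA/RNA sequences
#'
#' @param x Character vector of sequences (T/U insensitive).
#' @return Character vector of DNA reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(as_dna(x))))
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Hamming distance between two equal-length sequences
#'
#' Alphabet-insensitive to T/U and case. Returns `NA_integer_` when the
#' lengths differ (no alignment is attempted).
#'
#' @param a,b Sequences.
#' @return Integer count of mismatching positions, or `NA` on length mismatch.
#' @export
hamming <- function(a, b) {
  a <- as_dna(a); b <- as_dna(b)
  if (nchar(a) != nchar(b)) return(NA_integer_)
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards
with_rng <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# character vector of per-position bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# substring on a chromosome string, 1-based inclusive
chrom_sub <- function(genome, chrom, start1, end1) {
  s <- as.character(genome[[chrom]])
  substr(s, start1, end1)
}

#' Positions of a sequence motif
#'
#' Scans a mature miRNA (or any sequence) for a motif and reports the
#' 1-based position of the motif's last base (for the default `GGU` motif
#' this is the substitutable U). T/U and case insensitive; overlapping
#' occurrences are all reported.
#'
#' @param seq Sequence to scan.
#' @param motif Motif, default `"GGU"`.
#' @return Integer vector of end positions, empty when absent.
#' @export
motif_positions <- function(seq, motif = "GGU") {
  s <- as_dna(seq)
  m <- as_dna(motif)
  k <- nchar(m)
  n <- nchar(s)
  if (n < k) return(integer(0))
  starts <- which(vapply(seq_len(n - k + 1),
                         function(i) substr(s, i, i + k - 1) == m,
                         logical(1)))
  starts + k - 1L
}
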