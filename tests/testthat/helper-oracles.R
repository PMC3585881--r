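# Independent oracles: deliberately naive implementations used only to
# verify the package's optimised code paths.

# Brute-force maximum base-pairing: plain exponential recursion that
# implicitly enumerates every nested structure with loop >= min_loop.
bf_pairable <- function(a, b) {
  (a == "A" && b == "U") || (a == "U" && b == "A") ||
    (a == "G" && b == "C") || (a == "C" && b == "G") ||
    (a == "G" && b == "U") || (a == "U" && b == "G")
}

bf_max_pairs <- function(seq, min_loop = 3L) {
  ch <- strsplit(gsub("T", "U", toupper(seq)), "")[[1]]
  rec <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (bf_pairable(ch[i], ch[k])) {
        v <- 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j)
        if (v > best) best <- v
      }
    }
    best
  }
  if (length(ch) < min_loop + 2L) return(0L)
  rec(1L, length(ch))
}

# Exact one-sided (greater) hypergeometric tail by direct summation of
# binomial coefficients over the 2x2 table [[a, b], [c, d]].
bf_hyper_tail <- function(a, b, c, d) {
  N <- a + b + c + d
  K <- a + b          # targets
  m <- a + c          # genes on the chromosome
  xs <- a:min(K, m)
  sum(vapply(xs, function(x)
    exp(lchoose(m, x) + lchoose(N - m, K - x) - lchoose(N, K)),
    numeric(1)))
}

# Naive all-occurrence substring scan (both strands) for mapping checks.
bf_count_occurrences <- function(pattern, chrom_strings) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(pattern)))
  total <- 0L
  for (s in chrom_strings) {
    for (p in unique(c(pattern, rc))) {
      hits <- gregexpr(paste0("(?=", p, ")"), s, perl = TRUE)[[1]]
      total <- total + sum(hits > 0L)
    }
  }
  total
}

# Naive sliding Hamming scan: minimum mismatch count of `pattern` against
# any equal-length window of any subject sequence.
bf_min_hamming <- function(pattern, subjects) {
  n <- nchar(pattern)
  pc <- utf8ToInt(pattern)
  best <- Inf
  for (s in subjects) {
    if (nchar(s) < n) next
    sc <- utf8ToInt(s)
    for (i in seq_len(nchar(s) - n + 1L)) {
      best <- min(best, sum(pc != sc[i:(i + n - 1L)]))
    }
  }
  best
}

# Transitive closure of the pairwise distance relation for clustering
# checks: brute-force union-find over all pairs.
bf_cluster_membership <- function(chrom, start0, cutoff = 10000L) {
  n <- length(start0)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && chrom[i] == chrom[j] &&
        abs(start0[i] - start0[j]) <= cutoff) {
      parent[find(i)] <- find(j)
    }
  }
  vapply(seq_len(n), find, 1L)
}
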