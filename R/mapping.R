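# Exact-match genome mapping and small-RNA class partitioning.

#' Map collapsed reads to a genome by exact matching
#'
#' Reports every occurrence of each sequence on both strands (minus-strand
#' hits are found by matching the reverse complement and reported on forward
#' coordinates). Sequences with more than `max_loci` genomic loci are
#' flagged `excluded`; sequences with no locus are flagged `unmapped` and
#' retained for homology rescue.
#'
#' @param sequences Character vector of read sequences (or a collapsed-read
#'   table, in which case its `sequence` column is used).
#' @param genome A named [Biostrings::DNAStringSet].
#' @param max_loci Maximum genomic loci before exclusion.
#' @return A list with `hits` (data.frame: sequence, chrom, start0 (0-based),
#'   strand) and `status` (data.frame: sequence, n_loci, status in
#'   mapped/unmapped/excluded).
#' @export
map_exact <- function(sequences, genome, max_loci = 100L) {
  if (is.data.frame(sequences)) sequences <- sequences$sequence
  if (length(genome) == 0L || sum(Biostrings::width(genome)) == 0L)
    stop("empty genome")
  sequences <- unique(as_dna(sequences))
  hits <- vector("list", length(sequences))
  n_loci <- integer(length(sequences))
  for (k in seq_along(sequences)) {
    s <- sequences[k]
    rows <- list()
    for (str in c("+", "-")) {
      pat <- if (str == "+") s else revcomp(s)
      m <- Biostrings::vmatchPattern(pat, genome)
      for (ci in seq_along(genome)) {
        st <- BiocGenerics::start(m[[ci]])
        if (length(st) > 0L)
          rows[[length(rows) + 1L]] <-
            data.frame(sequence = s, chrom = names(genome)[ci],
                       start0 = st - 1L, strand = str,
                       stringsAsFactors = FALSE)
      }
    }
    h <- if (length(rows)) do.call(rbind, rows) else NULL
    n_loci[k] <- if (is.null(h)) 0L else nrow(h)
    hits[[k]] <- h
  }
  status <- data.frame(
    sequence = sequences, n_loci = n_loci,
    status = ifelse(n_loci == 0L, "unmapped",
                    ifelse(n_loci > max_loci, "excluded", "mapped")),
    stringsAsFactors = FALSE)
  keep <- status$status == "mapped"
  hits <- hits[keep]
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(sequence = character(0), chrom = character(0),
               start0 = integer(0), strand = character(0),
               stringsAsFactors = FALSE)
  rownames(hits) <- NULL
  list(hits = hits, status = status)
}

# any hit of `seq` within Hamming distance <= max_mm of a window of any
# sequence in `subject` (DNAStringSet), either strand
ncrna_homolog <- function(seq, subject, max_mm = 1L) {
  if (length(subject) == 0L) return(FALSE)
  for (pat in unique(c(seq, revcomp(seq)))) {
    m <- Biostrings::vcountPattern(pat, subject, max.mismatch = max_mm,
                                   fixed = TRUE)
    if (any(m > 0L)) return(TRUE)
  }
  FALSE
}

#' Partition mapped reads into small-RNA classes
#'
#' Assigns each sequence exactly one class with the precedence: homology to
#' known tRNA/rRNA/ncRNA sequences (Hamming distance at most one mismatch,
#' no indels, either strand) > overlap of any genomic locus with a repeat
#' interval (>= 1 nt) > mRNA degradation (only when a transcript set is
#' supplied) > miRNA candidate for remaining mapped reads. Unmapped and
#' multi-locus-excluded sequences keep classes `unmapped` and `undefined`.
#'
#' @param map Output of [map_exact()].
#' @param repeats A data.frame with `chrom`, `start0`, `end0` (0-based
#'   half-open) of repeat/transposable-element intervals, or a
#'   [GenomicRanges::GRanges].
#' @param known_ncrna [Biostrings::DNAStringSet] of known tRNA/rRNA/ncRNA
#'   sequences.
#' @param transcripts Optional `DNAStringSet` of mRNA transcripts; exact
#'   substring hits are classed `mRNA-degradation`.
#' @return Data.frame: sequence, n_loci, status, rna_class.
#' @export
classify_reads <- function(map, repeats = NULL, known_ncrna = NULL,
                           transcripts = NULL) {
  status <- map$status
  hits <- map$hits
  rep_gr <- NULL
  if (!is.null(repeats)) {
    rep_gr <- if (methods::is(repeats, "GRanges")) repeats else
      GenomicRanges::GRanges(repeats$chrom,
                             IRanges::IRanges(repeats$start0 + 1L,
                                              repeats$end0))
  }
  repeat_seqs <- character(0)
  if (!is.null(rep_gr) && length(rep_gr) > 0L && nrow(hits) > 0L) {
    hit_gr <- GenomicRanges::GRanges(
      hits$chrom, IRanges::IRanges(hits$start0 + 1L,
                                   hits$start0 + nchar(hits$sequence)))
    ov <- GenomicRanges::countOverlaps(hit_gr, rep_gr, minoverlap = 1L) > 0L
    repeat_seqs <- unique(hits$sequence[ov])
  }
  cls <- character(nrow(status))
  for (k in seq_len(nrow(status))) {
    s <- status$sequence[k]
    cls[k] <- if (!is.null(known_ncrna) && ncrna_homolog(s, known_ncrna))
      "tRNA/rRNA/ncRNA"
    else if (status$status[k] == "unmapped") "unmapped"
    else if (status$status[k] == "excluded") "undefined"
    else if (s %in% repeat_seqs) "repeat"
    else if (!is.null(transcripts) &&
             any(Biostrings::vcountPattern(s, transcripts) > 0L))
      "mRNA-degradation"
    else "miRNA-candidate"
  }
  out <- status
  out$rna_class <- cls
  out
}

#' Class composition of a library
#'
#' Read-count-weighted fractions per small-RNA class (the stacked-bar
#' summary of a sequencing run).
#'
#' @param classified Output of [classify_reads()].
#' @param collapsed Collapsed-read table with per-sample counts.
#' @return Data.frame: rna_class, reads, fraction (fractions sum to 1).
#' @export
class_summary <- function(classified, collapsed) {
  cc <- count_cols(collapsed)
  tot <- rowSums(collapsed[, cc, drop = FALSE])
  cl <- classified$rna_class[match(collapsed$sequence, classified$sequence)]
  agg <- tapply(tot, cl, sum)
  data.frame(rna_class = names(agg), reads = as.integer(agg),
             fraction = as.numeric(agg) / sum(agg),
             row.names = NULL, stringsAsFactors = FALSE)
}
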