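# Demultiplexing, adapter trimming, and read collapsing.
#
# Read layout: insert + 5-nt barcode + constant 3' adapter region, truncated
# to the sequenced read length, so the adapter is present as a (possibly
# partial) suffix. Trimming finds the longest suffix of the read equal to a
# prefix of the constant adapter (at least `min_adapter` nt, exact match);
# the five bases immediately 5' of it are the barcode and the remainder is
# the insert.

#' Demultiplex, trim, and collapse a multiplexed small-RNA library
#'
#' Reads failing any step are tallied and dropped: no adapter suffix found
#' (`no_adapter`), barcode not in the map (`unknown_barcode`), insert with an
#' ambiguous base N (`low_quality`), or insert length outside
#' `len_range` (`bad_length`). Identical inserts are collapsed to one row
#' with per-sample counts.
#'
#' @param reads A data.frame with columns `read_id` and `seq`, a character
#'   vector of reads, or a path to a FASTQ file.
#' @param barcode_map Named character vector: pentamer barcode -> sample
#'   label.
#' @param adapter Constant region of the 3' adapter.
#' @param min_adapter Minimum adapter prefix length accepted at the read
#'   end.
#' @param len_range Inclusive insert length window kept for analysis.
#' @return A list with `collapsed` (data.frame: `sequence` plus one count
#'   column per sample) and `qc` (named integer tallies; `assigned` plus the
#'   drop classes; tallies sum to the number of input reads).
#' @export
trim_and_demux <- function(reads, barcode_map,
                           adapter = library_adapters()$adapter3,
                           min_adapter = 6L, len_range = c(18L, 32L)) {
  if (length(barcode_map) == 0L) stop("empty barcode map")
  if (any(nchar(names(barcode_map)) != 5L))
    stop("barcodes must be pentamers")
  if (anyDuplicated(names(barcode_map)))
    stop("duplicated barcode in barcode map")
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    x <- Biostrings::readDNAStringSet(reads, format = "fastq")
    reads <- as.character(x)
  } else if (is.data.frame(reads)) {
    reads <- reads$seq
  }
  n <- length(reads)
  reads <- toupper(reads)

  # longest adapter prefix terminating the read; vectorised over prefix
  # lengths, longest first
  nr <- nchar(reads)
  plen <- rep(0L, n)
  for (p in seq(min(nchar(adapter), max(nr)), min_adapter)) {
    cand <- which(plen == 0L & nr >= p + 5L)
    if (length(cand) == 0L) next
    hit <- substr(reads[cand], nr[cand] - p + 1L, nr[cand]) ==
      substr(adapter, 1L, p)
    plen[cand[hit]] <- p
  }

  barcode <- ifelse(plen > 0L,
                    substr(reads, nr - plen - 4L, nr - plen), NA)
  insert <- ifelse(plen > 0L, substr(reads, 1L, nr - plen - 5L), NA)
  sample_lab <- barcode_map[barcode]

  drop <- rep(NA_character_, n)
  drop[plen == 0L] <- "no_adapter"
  drop[is.na(drop) & is.na(sample_lab)] <- "unknown_barcode"
  drop[is.na(drop) & grepl("N", insert, fixed = TRUE)] <- "low_quality"
  drop[is.na(drop) &
         (nchar(insert) < len_range[1L] | nchar(insert) > len_range[2L])] <-
    "bad_length"

  keep <- is.na(drop)
  qc <- c(assigned = sum(keep),
          no_adapter = sum(drop == "no_adapter", na.rm = TRUE),
          unknown_barcode = sum(drop == "unknown_barcode", na.rm = TRUE),
          low_quality = sum(drop == "low_quality", na.rm = TRUE),
          bad_length = sum(drop == "bad_length", na.rm = TRUE))

  samples <- unique(unname(barcode_map))
  if (sum(keep) == 0L) {
    collapsed <- data.frame(sequence = character(0))
    for (s in samples) collapsed[[s]] <- integer(0)
  } else {
    tab <- table(factor(insert[keep]),
                 factor(sample_lab[keep], levels = samples))
    collapsed <- data.frame(sequence = rownames(tab),
                            stringsAsFactors = FALSE)
    for (s in samples) collapsed[[s]] <- as.integer(tab[, s])
    collapsed <- collapsed[order(-rowSums(collapsed[, samples, drop = FALSE]),
                                 collapsed$sequence), , drop = FALSE]
    rownames(collapsed) <- NULL
  }
  list(collapsed = collapsed, qc = qc)
}

# count columns of a collapsed-read table
count_cols <- function(collapsed) {
  setdiff(colnames(collapsed), c("sequence"))
}

#' Remove orphan sequences
#'
#' Drops collapsed reads whose total count across all samples is one
#' (sequences seen exactly once in the whole experiment).
#'
#' @param collapsed A collapsed-read table from [trim_and_demux()].
#' @return The table with orphan rows removed.
#' @export
drop_orphans <- function(collapsed) {
  cc <- count_cols(collapsed)
  if (nrow(collapsed) == 0L) return(collapsed)
  tot <- rowSums(collapsed[, cc, drop = FALSE])
  out <- collapsed[tot > 1L, , drop = FALSE]
  rownames(out) <- NULL
  out
}
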