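# miRNA candidate calling: read stacks, flanking-window folding, the four
# acceptance criteria (hairpin precursor, read support, star strand, 5'
# precision), star detection, and arm balance.

# Extract a flanking window (1-based genomic coords) on the read's strand
# and fold it; returns NULL or a list describing the hairpin. Windows of
# each length are tried with the read placed on the 5' arm and on the 3'
# arm; among passing configurations the one pairing the largest fraction
# of mature bases wins (a genuine precursor stem out-pairs an incidental
# chain), with ties resolved to the longer window.
best_hairpin_window <- function(genome, chrom, mat_start1, mat_end1, strand,
                                window_lens = c(120L, 100L, 80L, 60L),
                                margin = 5L, min_stem_pairs = 18L,
                                max_bulge = 4L, min_paired_frac = 0.6) {
  clen <- Biostrings::width(genome)[match(chrom, names(genome))]
  best <- NULL
  for (W in sort(window_lens, decreasing = TRUE)) {
    for (placement in c("5parm", "3parm")) {
      if (placement == "5parm") {
        ws <- mat_start1 - margin
        we <- ws + W - 1L
      } else {
        we <- mat_end1 + margin
        ws <- we - W + 1L
      }
      ws <- max(1L, ws)
      we <- min(clen, we)
      if (mat_start1 < ws || mat_end1 > we) next
      wseq <- chrom_sub(genome, chrom, ws, we)
      if (strand == "-") {
        wseq <- revcomp(wseq)
        span <- c(we - mat_end1 + 1L, we - mat_start1 + 1L)
      } else {
        span <- c(mat_start1 - ws + 1L, mat_end1 - ws + 1L)
      }
      fold <- fold_max_pairs(wseq)
      hp <- detect_hairpin(fold, span, min_stem_pairs = min_stem_pairs,
                           max_bulge = max_bulge,
                           min_paired_frac = min_paired_frac)
      if (hp$is_hairpin &&
          (is.null(best) ||
             hp$mature_paired_frac > best$hairpin$mature_paired_frac))
        best <- list(fold = fold, hairpin = hp, window_start1 = ws,
                     window_end1 = we, window_len = W, strand = strand,
                     mature_span = span)
    }
  }
  best
}

#' Detect the star sequence of a mature miRNA in its read stack
#'
#' The duplex partner span of the mature is computed from the stem pairs of
#' the folded precursor; the most abundant stack read lying on the opposite
#' arm whose span matches the partner span within `slack` nt at each end is
#' the star.
#'
#' @param fold_info A window/fold description from candidate calling: a list
#'   with `fold`, `hairpin` (from [detect_hairpin()]), and `mature_span`
#'   (1-based span of the mature within the window).
#' @param stack Data.frame of stack reads in window coordinates: `sequence`,
#'   `start1`, `end1`, `count`.
#' @param slack Allowed deviation at each end, nt.
#' @return A list `star_sequence` (or `NA`), `star_count`, `partner_span`.
#' @export
detect_star <- function(fold_info, stack, slack = 3L) {
  stem <- fold_info$hairpin$stem_pairs
  m <- fold_info$mature_span[1L]:fold_info$mature_span[2L]
  partner <- c(stem[stem[, "i"] %in% m, "j"], stem[stem[, "j"] %in% m, "i"])
  if (length(partner) == 0L)
    return(list(star_sequence = NA_character_, star_count = 0L,
                partner_span = c(NA_integer_, NA_integer_)))
  ps <- range(partner)
  ok <- abs(stack$start1 - ps[1L]) <= slack & abs(stack$end1 - ps[2L]) <= slack
  # the candidate must not be the mature itself (opposite arm by construction
  # of the partner span, but guard against overlap)
  ok <- ok & !(stack$start1 == fold_info$mature_span[1L] &
                 stack$end1 == fold_info$mature_span[2L])
  if (!any(ok))
    return(list(star_sequence = NA_character_, star_count = 0L,
                partner_span = ps))
  cand <- stack[ok, , drop = FALSE]
  best <- which.max(cand$count)
  list(star_sequence = cand$sequence[best],
       star_count = as.integer(sum(cand$count)), partner_span = ps)
}

#' Are both arms of a precursor retained at comparable levels?
#'
#' TRUE when star reads exist and the more abundant strand exceeds the less
#' abundant one by less than `max_fold`.
#'
#' @param mature_count,star_count Read counts of the two strands.
#' @param max_fold Fold-difference bound (exclusive).
#' @return Logical.
#' @export
arm_balance <- function(mature_count, star_count, max_fold = 10) {
  if (is.na(star_count) || star_count <= 0L || mature_count <= 0L)
    return(FALSE)
  max(mature_count, star_count) / min(mature_count, star_count) < max_fold
}

# Hamming <= max_mm match of `seq` against a set of known matures at equal
# length; returns the name of the first match or NA
known_match <- function(seq, known, max_mm = 1L) {
  if (is.null(known) || length(known) == 0L) return(NA_character_)
  s <- as_dna(seq)
  kn <- as_dna(as.character(known))
  same_len <- nchar(kn) == nchar(s)
  for (i in which(same_len)) {
    if (hamming(s, kn[i]) <= max_mm)
      return(if (!is.null(names(known))) names(known)[i] else
        paste0("known-", i))
  }
  NA_character_
}

#' Call miRNA candidates from mapped read stacks
#'
#' Reads of class `miRNA-candidate` are grouped into genomic stacks
#' (overlapping hits on the same chromosome and strand). For each stack the
#' most abundant sequence is the mature candidate and flanking windows of
#' 60/80/100/120 nt are folded with the read placed on either arm. A novel
#' candidate must satisfy all four criteria: (1) a hairpin-shaped precursor,
#' (2) more than `min_reads` total stack reads, (3) a star sequence on the
#' opposite arm, and (4) a precise 5' end (the modal 5' position holds at
#' least `min_5p_frac` of mature-arm reads). A sequence within one mismatch
#' of a known mature (at equal length) is accepted as `known-homolog`
#' without the star/precision requirements; unmapped sequences matching a
#' known mature are accepted as `known-homolog-unmapped`.
#'
#' @param collapsed Collapsed-read table (post orphan removal) with
#'   per-sample counts.
#' @param classified Output of [classify_reads()] for the same sequences.
#' @param map Output of [map_exact()].
#' @param genome Named [Biostrings::DNAStringSet].
#' @param known_matures Optional named `DNAStringSet` of known mature
#'   miRNAs.
#' @param min_reads Criterion 2 threshold: total stack reads must exceed
#'   this.
#' @param min_5p_frac Criterion 4 threshold on the modal 5' position share.
#' @param star_slack Span slack for star detection, nt.
#' @param window_lens Flanking window lengths to try.
#' @param stack_gap Maximum gap (nt) between mapped reads merged into one
#'   stack; spans a precursor loop so both arms of a hairpin form a single
#'   stack.
#' @return A data.frame of miRNA records: name, sequence (RNA), arm, status,
#'   chrom, precursor window (0-based half-open), strand, star sequence and
#'   count, both_arms_retained, n_loci, per-sample `count.*` columns
#'   (mature-arm stack reads), and `star_count`.
#' @export
call_candidates <- function(collapsed, classified, map, genome,
                            known_matures = NULL, min_reads = 10L,
                            min_5p_frac = 0.9, star_slack = 3L,
                            window_lens = c(120L, 100L, 80L, 60L),
                            stack_gap = 30L) {
  cc <- count_cols(collapsed)
  totals <- stats::setNames(rowSums(collapsed[, cc, drop = FALSE]),
                            collapsed$sequence)
  cand_seqs <- classified$sequence[classified$rna_class == "miRNA-candidate"]
  hits <- map$hits[map$hits$sequence %in% cand_seqs, , drop = FALSE]
  records <- list()

  if (nrow(hits) > 0L) {
    hit_gr <- GenomicRanges::GRanges(
      hits$chrom,
      IRanges::IRanges(hits$start0 + 1L,
                       hits$start0 + nchar(hits$sequence)),
      strand = hits$strand)
    stacks_gr <- GenomicRanges::reduce(hit_gr, min.gapwidth = stack_gap)
    ov <- GenomicRanges::findOverlaps(hit_gr, stacks_gr)
    stack_of <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]

    for (sk in seq_along(stacks_gr)) {
      rows <- hits[stack_of == sk, , drop = FALSE]
      rows$count <- unname(totals[rows$sequence])
      rows$start1 <- rows$start0 + 1L
      rows$end1 <- rows$start0 + nchar(rows$sequence)
      total <- sum(rows$count[!duplicated(rows$sequence)])
      mature_row <- rows[which.max(rows$count), , drop = FALSE]
      mature <- mature_row$sequence
      strand <- mature_row$strand
      km <- known_match(mature, known_matures)

      fi <- best_hairpin_window(genome, mature_row$chrom,
                                mature_row$start1, mature_row$end1, strand,
                                window_lens = window_lens)
      star <- list(star_sequence = NA_character_, star_count = 0L)
      precise5 <- NA
      mature_arm_counts <- NULL
      if (!is.null(fi)) {
        # stack reads in window coordinates (window is on the read strand)
        if (strand == "-") {
          st <- fi$window_end1 - rows$end1 + 1L
          en <- fi$window_end1 - rows$start1 + 1L
        } else {
          st <- rows$start1 - fi$window_start1 + 1L
          en <- rows$end1 - fi$window_start1 + 1L
        }
        wstack <- data.frame(sequence = rows$sequence, start1 = st,
                             end1 = en, count = rows$count,
                             stringsAsFactors = FALSE)
        star <- detect_star(fi, wstack, slack = star_slack)
        # 5' precision among mature-arm reads: reads whose midpoint falls on
        # the same side of the loop as the mature
        arms <- fi$hairpin$arms
        mid <- (wstack$start1 + wstack$end1) / 2
        mature_on5 <- fi$hairpin$arm == "5p"
        loop_mid <- mean(arms$loop)
        on_mature_arm <- if (mature_on5) mid < loop_mid else mid > loop_mid
        marm <- wstack[on_mature_arm, , drop = FALSE]
        mature_arm_counts <- marm
        if (nrow(marm) > 0L) {
          by5 <- tapply(marm$count, marm$start1, sum)
          precise5 <- max(by5) / sum(by5) >= min_5p_frac
        } else precise5 <- FALSE
      }

      status <- if (!is.na(km)) "known-homolog"
        else if (!is.null(fi) && total > min_reads &&
                 star$star_count > 0L && isTRUE(precise5)) "novel"
        else NA_character_
      if (is.na(status)) next

      # per-sample counts over mature-arm reads (fall back to the whole
      # stack when no hairpin window exists)
      use <- if (!is.null(mature_arm_counts))
        unique(mature_arm_counts$sequence) else unique(rows$sequence)
      csel <- collapsed[collapsed$sequence %in% use, cc, drop = FALSE]
      cnt <- colSums(csel)
      mature_total <- sum(cnt)

      rec <- data.frame(
        name = NA_character_, sequence = as_rna(mature),
        arm = if (!is.null(fi)) fi$hairpin$arm else NA_character_,
        status = status, chrom = mature_row$chrom,
        prec_start0 = if (!is.null(fi)) fi$window_start1 - 1L else
          NA_integer_,
        prec_end0 = if (!is.null(fi)) fi$window_end1 else NA_integer_,
        strand = strand,
        mat_start0 = mature_row$start0,
        mat_end0 = mature_row$start0 + nchar(mature),
        star_sequence = if (is.na(star$star_sequence)) NA_character_ else
          as_rna(star$star_sequence),
        star_count = star$star_count,
        both_arms_retained = arm_balance(mature_total, star$star_count),
        n_loci = classified$n_loci[match(mature, classified$sequence)],
        total = mature_total, stringsAsFactors = FALSE)
      for (s in cc) rec[[paste0("count.", s)]] <- unname(cnt[s])
      rec$known_name <- km
      records[[length(records) + 1L]] <- rec
    }
  }

  # homology rescue of unmapped sequences
  unm <- classified$sequence[classified$status == "unmapped" &
                               classified$rna_class == "unmapped"]
  for (s in unm) {
    km <- known_match(s, known_matures)
    if (is.na(km)) next
    cnt <- colSums(collapsed[collapsed$sequence == s, cc, drop = FALSE])
    rec <- data.frame(
      name = NA_character_, sequence = as_rna(s), arm = NA_character_,
      status = "known-homolog-unmapped", chrom = NA_character_,
      prec_start0 = NA_integer_, prec_end0 = NA_integer_,
      strand = NA_character_, mat_start0 = NA_integer_,
      mat_end0 = NA_integer_, star_sequence = NA_character_,
      star_count = 0L, both_arms_retained = FALSE, n_loci = 0L,
      total = sum(cnt), stringsAsFactors = FALSE)
    for (sc in cc) rec[[paste0("count.", sc)]] <- unname(cnt[sc])
    rec$known_name <- km
    records[[length(records) + 1L]] <- rec
  }

  if (length(records) == 0L) {
    out <- data.frame(name = character(0), sequence = character(0),
                      arm = character(0), status = character(0),
                      chrom = character(0), prec_start0 = integer(0),
                      prec_end0 = integer(0), strand = character(0),
                      mat_start0 = integer(0), mat_end0 = integer(0),
                      star_sequence = character(0), star_count = integer(0),
                      both_arms_retained = logical(0), n_loci = integer(0),
                      total = integer(0), known_name = character(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, records)
  # drop duplicate records of multi-locus sequences (same mature called at
  # several stacks): keep the first, count loci via n_loci
  out <- out[!duplicated(out$sequence), , drop = FALSE]
  # one record per known mature: close sequence variants (<= 1 mismatch)
  # of an annotated miRNA are isomiRs of that miRNA, not further records;
  # prefer genomic records over unmapped rescues, then read depth
  ord <- order(out$known_name,
               out$status == "known-homolog-unmapped", -out$total)
  dup <- duplicated(out$known_name[ord], incomparables = NA)
  keep <- rep(TRUE, nrow(out))
  keep[ord[dup]] <- FALSE
  out <- out[keep, , drop = FALSE]
  out$name <- ifelse(is.na(out$known_name),
                     sprintf("mir-novel-%d", cumsum(is.na(out$known_name))),
                     out$known_name)
  rownames(out) <- NULL
  out
}
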