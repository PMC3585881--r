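# isomiR taxonomy: classify every read assigned to a miRNA as canonical, a
# templated 5'/3' length variant, an untemplated A/U/other tail, or an
# internal substitution; call substitution sites; analyse the 6-nt motif
# context of called sites.

# choice of 5' offsets, preferring the unshifted alignment
SHIFT_ORDER <- c(0L, -1L, 1L, -2L, 2L, -3L, 3L, -4L, 4L)

#' Classify one read against a canonical miRNA
#'
#' End-anchored alignment with no indels in the read body: the read's 5'
#' end is slid within `max_shift` nt of the canonical 5' end over the
#' templated genomic context. In priority order the read is called a perfect
#' templated match (canonical or 5'/3'/both-ends length variant), an
#' untemplated 3' tail of 1-2 nt (each tail base differing from the
#' templated base at its position; tails take precedence over length
#' variation of the read body), or a single internal substitution. Reads
#' fitting none of these are `unclassified`.
#'
#' @param read Read sequence.
#' @param canonical Canonical mature sequence.
#' @param upstream,downstream Templated genomic context 5' and 3' of the
#'   canonical (possibly empty for miRNAs without a genomic locus; tail
#'   bases beyond the known template then count as untemplated).
#' @param max_shift Maximum 5' end offset, nt.
#' @return A list: `class` (one of canonical, len5, len3, both-ends,
#'   tail-U, tail-A, tail-other, subst, unclassified), `shift5`, `shift3`,
#'   `tail`, `subst_pos` (1-based on the canonical), `alt`.
#' @export
classify_read <- function(read, canonical, upstream = "", downstream = "",
                          max_shift = 4L) {
  read <- as_dna(read)
  canonical <- as_dna(canonical)
  upstream <- as_dna(upstream)
  downstream <- as_dna(downstream)
  u <- nchar(upstream)
  L <- nchar(canonical)
  ref <- paste0(upstream, canonical, downstream)
  nref <- nchar(ref)
  n <- nchar(read)
  rcode <- utf8ToInt(read)
  refcode <- utf8ToInt(ref)
  none <- list(class = "unclassified", shift5 = NA_integer_,
               shift3 = NA_integer_, tail = NA_character_,
               subst_pos = NA_integer_, alt = NA_character_)

  res_of <- function(class, shift5, shift3, tail = NA_character_,
                     subst_pos = NA_integer_, alt = NA_character_) {
    if (class == "match") {
      class <- if (shift5 == 0L && shift3 == 0L) "canonical"
      else if (shift5 != 0L && shift3 == 0L) "len5"
      else if (shift5 == 0L && shift3 != 0L) "len3"
      else "both-ends"
    }
    list(class = class, shift5 = shift5, shift3 = shift3, tail = tail,
         subst_pos = subst_pos, alt = alt)
  }

  shifts <- SHIFT_ORDER[abs(SHIFT_ORDER) <= max_shift & SHIFT_ORDER >= -u]
  # pass 1: perfect templated match; pass 2: untemplated tail; pass 3:
  # single internal substitution
  for (pass in 1:3) {
    for (s5 in shifts) {
      p0 <- u + 1L + s5
      ks <- if (pass == 2L) 1:2 else 0L
      for (k in ks) {
        nb <- n - k
        if (nb < 1L) next
        pend <- p0 + nb - 1L
        if (p0 < 1L || pend > nref) next
        body_mm <- which(rcode[seq_len(nb)] != refcode[p0:pend])
        shift3 <- pend - (u + L)
        if (pass == 1L && length(body_mm) == 0L)
          return(res_of("match", s5, shift3))
        if (pass == 2L && length(body_mm) == 0L) {
          tpos <- pend + seq_len(k)
          tail_bases <- rcode[nb + seq_len(k)]
          templated <- tpos <= nref & tail_bases == refcode[pmin(tpos, nref)]
          if (!any(templated)) {
            tail <- intToUtf8(tail_bases)
            cls <- if (grepl("^T+$", tail)) "tail-U"
            else if (grepl("^A+$", tail)) "tail-A"
            else "tail-other"
            return(res_of(cls, s5, shift3, tail = as_rna(tail)))
          }
        }
        if (pass == 3L && length(body_mm) == 1L) {
          pos_read <- body_mm
          if (pos_read > 1L && pos_read < nb) {
            cpos <- p0 + pos_read - 1L - u
            if (cpos >= 1L && cpos <= L)
              return(res_of("subst", s5, shift3, subst_pos = cpos,
                            alt = as_rna(substr(read, pos_read, pos_read))))
          }
        }
      }
    }
  }
  none
}

# templated context of a miRNA record on its strand
record_context <- function(rec, genome, up_len = 4L, down_len = 6L) {
  if (is.na(rec$chrom) || is.na(rec$mat_start0))
    return(list(up = "", down = ""))
  clen <- Biostrings::width(genome)[match(rec$chrom, names(genome))]
  if (identical(rec$strand, "-")) {
    up <- revcomp(chrom_sub(genome, rec$chrom, rec$mat_end0 + 1L,
                            min(clen, rec$mat_end0 + up_len)))
    down <- revcomp(chrom_sub(genome, rec$chrom,
                              max(1L, rec$mat_start0 - down_len + 1L),
                              rec$mat_start0))
  } else {
    up <- chrom_sub(genome, rec$chrom,
                    max(1L, rec$mat_start0 - up_len + 1L), rec$mat_start0)
    down <- chrom_sub(genome, rec$chrom, rec$mat_end0 + 1L,
                      min(clen, rec$mat_end0 + down_len))
  }
  list(up = up, down = down)
}

#' Build per-miRNA isomiR profiles from collapsed reads
#'
#' Every collapsed read not already classed as tRNA/rRNA/ncRNA or repeat is
#' classified against each annotated miRNA with [classify_read()]; reads
#' classifiable to more than one miRNA are excluded as ambiguous. Counts
#' are accumulated per variant class, and internal substitutions fill a
#' 4 x L per-position count matrix.
#'
#' @param records miRNA records from [call_candidates()].
#' @param collapsed Collapsed-read table with per-sample counts.
#' @param genome Named [Biostrings::DNAStringSet] (templated context).
#' @param classified Optional [classify_reads()] output used to skip
#'   ncRNA/repeat sequences.
#' @return A list of profiles (class `isomir_profile`): each has `name`,
#'   `canonical` (RNA), `arm`, `class_counts` (named numeric), `subst`
#'   (4 x L count matrix, rows A/C/G/U), `per_sample` (class x sample count
#'   matrix), `total`. Attribute `ambiguous` counts excluded reads.
#' @export
isomir_profiles <- function(records, collapsed, genome, classified = NULL) {
  cc <- count_cols(collapsed)
  keep <- rep(TRUE, nrow(collapsed))
  if (!is.null(classified)) {
    cl <- classified$rna_class[match(collapsed$sequence,
                                     classified$sequence)]
    keep <- !cl %in% c("tRNA/rRNA/ncRNA", "repeat", "undefined")
  }
  seqs <- collapsed$sequence[keep]
  counts <- collapsed[keep, cc, drop = FALSE]
  recs <- records[!duplicated(records$sequence), , drop = FALSE]
  n_mir <- nrow(recs)
  classes <- c("canonical", "len5", "len3", "both-ends", "tail-U", "tail-A",
               "tail-other", "subst")

  profiles <- lapply(seq_len(n_mir), function(i) {
    can <- as_dna(recs$sequence[i])
    L <- nchar(can)
    list(name = recs$name[i], canonical = as_rna(can), arm = recs$arm[i],
         class_counts = stats::setNames(numeric(length(classes)), classes),
         subst = matrix(0, 4L, L, dimnames = list(c("A", "C", "G", "U"),
                                                  NULL)),
         per_sample = matrix(0, length(classes), length(cc),
                             dimnames = list(classes, cc)),
         total = 0)
  })
  names(profiles) <- recs$name
  ctx <- lapply(seq_len(n_mir), function(i)
    record_context(recs[i, , drop = FALSE], genome))
  cans <- as_dna(recs$sequence)
  # cheap prefilter: a read assignable to a miRNA must retain one of two
  # core 8-mers of its canonical (single substitutions and terminal edits
  # cannot disrupt both)
  key1 <- substr(cans, 5L, 12L)
  key2 <- substr(cans, 13L, 20L)

  ambiguous <- 0
  for (k in seq_along(seqs)) {
    s <- as_dna(seqs[k])
    cand <- which(nchar(cans) >= 20L &
                    (vapply(key1, grepl, TRUE, x = s, fixed = TRUE) |
                       vapply(key2, grepl, TRUE, x = s, fixed = TRUE)))
    if (length(cand) == 0L)
      cand <- which(abs(nchar(cans) - nchar(s)) <= 6L & nchar(cans) < 20L)
    if (length(cand) == 0L) next
    res <- lapply(cand, function(i)
      classify_read(s, cans[i], ctx[[i]]$up, ctx[[i]]$down))
    ok <- which(vapply(res, function(r) r$class != "unclassified", TRUE))
    if (length(ok) == 0L) next
    if (length(ok) > 1L) {
      ambiguous <- ambiguous + sum(counts[k, ])
      next
    }
    i <- cand[ok]
    r <- res[[ok]]
    cnt <- sum(counts[k, ])
    profiles[[i]]$class_counts[r$class] <-
      profiles[[i]]$class_counts[r$class] + cnt
    profiles[[i]]$per_sample[r$class, ] <-
      profiles[[i]]$per_sample[r$class, ] + as.numeric(counts[k, ])
    profiles[[i]]$total <- profiles[[i]]$total + cnt
    if (r$class == "subst")
      profiles[[i]]$subst[r$alt, r$subst_pos] <-
        profiles[[i]]$subst[r$alt, r$subst_pos] + cnt
  }
  profiles <- lapply(profiles, function(p) structure(p,
                                                     class = "isomir_profile"))
  attr(profiles, "ambiguous") <- ambiguous
  profiles
}

#' Call internal substitution sites from an isomiR profile
#'
#' A site is reported when the miRNA's total reads (variants included)
#' exceed `min_total`, reads substituted at the position (summed over
#' alternate bases) exceed `min_rate` of the total, and the position is at
#' least 2 nt away from both termini. A-to-G sites are flagged as putative
#' editing; each site carries a one-sided binomial p-value against the
#' sequencing error rate.
#'
#' @param profile An `isomir_profile`.
#' @param min_total Total-read threshold (exclusive).
#' @param min_rate Substitution-rate threshold (exclusive).
#' @param error_rate Per-base sequencing error rate for the annotation
#'   p-value.
#' @return Data.frame: mirna, position, ref, alt (major alternate), reads,
#'   rate, in_GGU, in_seed, putative_editing, p_error.
#' @export
call_sites <- function(profile, min_total = 100, min_rate = 0.05,
                       error_rate = 0.005) {
  stopifnot(inherits(profile, "isomir_profile"))
  can <- as_rna(profile$canonical)
  L <- nchar(can)
  empty <- data.frame(mirna = character(0), position = integer(0),
                      ref = character(0), alt = character(0),
                      reads = numeric(0), rate = numeric(0),
                      in_GGU = logical(0), in_seed = logical(0),
                      putative_editing = logical(0), p_error = numeric(0),
                      stringsAsFactors = FALSE)
  if (profile$total <= min_total) return(empty)
  out <- empty
  for (p in seq_len(L)) {
    reads_p <- sum(profile$subst[, p])
    rate <- reads_p / profile$total
    if (reads_p == 0 || rate <= min_rate) next
    if (p < 2L || p > L - 1L) next
    ref <- substr(can, p, p)
    alt <- rownames(profile$subst)[which.max(profile$subst[, p])]
    in_ggu <- p >= 3L && substr(can, p - 2L, p) == "GGU"
    out <- rbind(out, data.frame(
      mirna = profile$name, position = p, ref = ref, alt = alt,
      reads = reads_p, rate = rate, in_GGU = in_ggu,
      in_seed = p >= 2L && p <= 8L,
      putative_editing = ref == "A" && alt == "G",
      p_error = pbinom(reads_p - 1, profile$total, error_rate,
                       lower.tail = FALSE),
      stringsAsFactors = FALSE))
  }
  out
}

#' Extract aligned 6-nt windows around substitution sites
#'
#' Each called site contributes a 6-nt window of its canonical sequence
#' with the substituted base at position 3, so a GGU reference motif ending
#' at the site occupies window positions 1-3. Sites with fewer than 2 nt of
#' 5' context or 3 nt of 3' context are dropped and tallied.
#'
#' @param sites Data.frame of sites (from [call_sites()], possibly row-bound
#'   over miRNAs).
#' @param canonicals Named character vector: miRNA name -> canonical
#'   sequence.
#' @param k Window width (fixed layout assumes 6).
#' @return A list: `windows` (data.frame mirna, position, window (RNA),
#'   in_GGU), `dropped` (count).
#' @export
motif_windows <- function(sites, canonicals, k = 6L) {
  dropped <- 0L
  rows <- list()
  for (r in seq_len(nrow(sites))) {
    can <- as_rna(canonicals[[sites$mirna[r]]])
    p <- sites$position[r]
    if (p - 2L < 1L || p + 3L > nchar(can)) {
      dropped <- dropped + 1L
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      mirna = sites$mirna[r], position = p,
      window = substr(can, p - 2L, p + 3L),
      in_GGU = substr(can, p - 2L, p) == "GGU",
      stringsAsFactors = FALSE)
  }
  windows <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna = character(0), position = integer(0),
               window = character(0), in_GGU = logical(0),
               stringsAsFactors = FALSE)
  list(windows = windows, dropped = dropped)
}

#' Per-position information content of aligned windows
#'
#' Shannon information content in bits per position, `2 - H` with `H` the
#' entropy of the base frequencies (no small-sample correction), plus the
#' frequency matrix — the numbers behind a sequence logo.
#'
#' @param windows Character vector of equal-length windows (or the
#'   `windows` data.frame from [motif_windows()]).
#' @return A list: `freq` (4 x k matrix, rows A/C/G/U), `ic` (length-k
#'   numeric, bits in `[0, 2]`).
#' @export
information_content <- function(windows) {
  if (is.data.frame(windows)) windows <- windows$window
  if (length(windows) == 0L) stop("empty window set")
  windows <- as_rna(windows)
  k <- nchar(windows[1L])
  if (any(nchar(windows) != k)) stop("windows must have equal length")
  mat <- do.call(rbind, strsplit(windows, "", fixed = TRUE))
  freq <- apply(mat, 2L, function(col) {
    f <- table(factor(col, levels = c("A", "C", "G", "U")))
    as.numeric(f) / length(col)
  })
  rownames(freq) <- c("A", "C", "G", "U")
  ic <- apply(freq, 2L, function(f) {
    nz <- f[f > 0]
    2 + sum(nz * log2(nz))
  })
  list(freq = freq, ic = as.numeric(ic))
}

#' Summarise untemplated tailing across miRNAs
#'
#' Per-miRNA U/A tail read counts, the extended:non-extended read ratio
#' (tailed reads over canonical reads), and the arm cross-tabulation of
#' miRNAs with at least one tailed read.
#'
#' @param profiles List of `isomir_profile`s.
#' @return A list: `per_mirna` (data.frame), `arm_crosstab` (tail type x
#'   arm counts of miRNAs), `n_U_mirnas`, `n_A_mirnas`.
#' @export
tailing_summary <- function(profiles) {
  per <- do.call(rbind, lapply(profiles, function(p) {
    cc <- p$class_counts
    data.frame(mirna = p$name, arm = p$arm,
               tail_U = cc[["tail-U"]], tail_A = cc[["tail-A"]],
               tail_other = cc[["tail-other"]],
               canonical = cc[["canonical"]],
               extended_ratio = if (cc[["canonical"]] > 0)
                 (cc[["tail-U"]] + cc[["tail-A"]] + cc[["tail-other"]]) /
                 cc[["canonical"]] else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (is.null(per))
    per <- data.frame(mirna = character(0), arm = character(0),
                      tail_U = numeric(0), tail_A = numeric(0),
                      tail_other = numeric(0), canonical = numeric(0),
                      extended_ratio = numeric(0), stringsAsFactors = FALSE)
  rownames(per) <- NULL
  per_tailed <- per[per$tail_U + per$tail_A + per$tail_other > 0, ,
                    drop = FALSE]
  ct <- matrix(0L, 2L, 2L, dimnames = list(c("A", "U"), c("5p", "3p")))
  for (arm in c("5p", "3p")) {
    ct["A", arm] <- sum(per$arm == arm & per$tail_A > 0, na.rm = TRUE)
    ct["U", arm] <- sum(per$arm == arm & per$tail_U > 0, na.rm = TRUE)
  }
  list(per_mirna = per, arm_crosstab = ct,
       n_U_mirnas = sum(per$tail_U > 0), n_A_mirnas = sum(per$tail_A > 0),
       n_tailed = nrow(per_tailed))
}
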