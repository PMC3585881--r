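#' Fold a sequence by maximum base-pairing
#'
#' Predicts a nested secondary structure maximising the number of base pairs
#' (Watson-Crick plus G.U wobble) with a minimum hairpin loop of three
#' unpaired bases, by dynamic programming. This is a structural folder: it
#' optimises pair count, not free energy, which is sufficient for deciding
#' whether a window can form a miRNA-precursor-like stem-loop. The traceback
#' is deterministic (pairing a position is preferred over leaving it
#' unpaired; the smallest admissible partner is chosen), so identical input
#' always yields an identical structure.
#'
#' @param seq Sequence (RNA or DNA alphabet; T is read as U).
#' @param min_loop Minimum number of unpaired bases enclosed by a pair.
#' @return An object of class `fold_result`: a list with `seq` (RNA), `n`
#'   (sequence length), `n_pairs` (the maximum), and `pairs`, a two-column
#'   integer matrix of 1-based paired positions (i < j), ordered by i.
#' @export
fold_max_pairs <- function(seq, min_loop = 3L) {
  if (length(seq) != 1L || !is.character(seq) || is.na(seq))
    stop("'seq' must be a single sequence string")
  rna <- as_rna(seq)
  if (nchar(rna) < 1L) stop("'seq' is empty")
  if (grepl("[^ACGU]", rna))
    stop("invalid alphabet in 'seq': only A/C/G/U (or T) are allowed")
  res <- .nussinov(rna, as.integer(min_loop))
  pairs <- res$pairs
  if (nrow(pairs) > 1L) pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  colnames(pairs) <- c("i", "j")
  structure(list(seq = rna, n = nchar(rna),
                 n_pairs = as.integer(res$n_pairs), pairs = pairs),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("fold_result: %d nt, %d pairs\n", x$n, x$n_pairs))
  cat(dot_bracket(x), "\n")
  invisible(x)
}

#' Dot-bracket string for a folded structure
#'
#' @param fold A `fold_result`.
#' @return A character string with `(`/`)` at paired and `.` at unpaired
#'   positions.
#' @export
dot_bracket <- function(fold) {
  db <- rep(".", fold$n)
  db[fold$pairs[, "i"]] <- "("
  db[fold$pairs[, "j"]] <- ")"
  paste(db, collapse = "")
}

#' Longest single stem of a sequence
#'
#' The longest run of nested base pairs (i increasing, j decreasing, at
#' most `max_bulge` skipped bases between consecutive pairs on either side,
#' terminal loop of at least `min_loop` bases) over all pairable positions
#' — the longest bulged inverted repeat. Unlike the pair list of one
#' optimal maximum-pairing structure, this is stable under the degeneracy
#' of base-pair-count optima, so it is what hairpin detection scores.
#'
#' @param seq Sequence (RNA or DNA alphabet).
#' @param min_loop Minimum unpaired bases enclosed by the innermost pair.
#' @param max_bulge Maximum bulge between consecutive stem pairs, nt.
#' @param max_bulge_total Maximum skipped bases over the whole stem, nt;
#'   this budget is what keeps long chains from arising in random
#'   sequence.
#' @param anchor_i,anchor_j Optional 1-based `c(lo, hi)` windows: only
#'   chains whose outermost pair has `i` in `anchor_i` or `j` in
#'   `anchor_j` are considered (used to demand a stem starting at the
#'   outer end of a mature read).
#' @return Two-column integer matrix of 1-based paired positions, ordered
#'   outermost first; zero rows when nothing pairs.
#' @export
stem_chain <- function(seq, min_loop = 3L, max_bulge = 4L,
                       max_bulge_total = 8L, anchor_i = NULL,
                       anchor_j = NULL) {
  rna <- as_rna(seq)
  if (grepl("[^ACGU]", rna))
    stop("invalid alphabet in 'seq': only A/C/G/U (or T) are allowed")
  ai <- if (is.null(anchor_i)) c(0L, 0L) else as.integer(anchor_i)
  aj <- if (is.null(anchor_j)) c(0L, 0L) else as.integer(anchor_j)
  out <- .stem_chain(rna, as.integer(min_loop), as.integer(max_bulge),
                     as.integer(max_bulge_total), ai[1L], ai[2L],
                     aj[1L], aj[2L])
  colnames(out) <- c("i", "j")
  out
}

#' Decide whether a folded window is a miRNA-like hairpin
#'
#' A window qualifies when (a) it contains a single stem of at least
#' `min_stem_pairs` base pairs (the longest bulged inverted repeat, see
#' [stem_chain()]), (b) the mature span lies on one arm of that stem, and
#' (c) at least `min_paired_frac` of the mature bases are paired within
#' the stem.
#'
#' @param fold A `fold_result` for the window.
#' @param mature_span Integer length-2 vector, 1-based inclusive span of the
#'   mature read within the window.
#' @param min_stem_pairs Minimum pairs in the stem.
#' @param max_bulge Maximum bulge between consecutive stem pairs, in nt.
#' @param max_bulge_total Maximum skipped bases over the whole stem, nt.
#' @param min_paired_frac Minimum fraction of mature bases paired.
#' @param outer_slack Allowed overhang of the mature beyond the outer end
#'   of the stem, nt. On the loop side the mature may reach up to (but not
#'   into) the opposite arm's paired span: a maximum-pairing structure
#'   routinely pairs a few terminal mature bases into the loop, so strict
#'   containment in the paired arm span would be brittle; the paired-
#'   fraction criterion keeps specificity.
#' @return A list: `is_hairpin` (logical), `arm` (`"5p"`, `"3p"`, or `NA`),
#'   `stem_pairs` (matrix of the stem's pairs), `arms` (list with `arm5`,
#'   `arm3`, `loop` spans), `mature_paired_frac`.
#' @export
detect_hairpin <- function(fold, mature_span, min_stem_pairs = 18L,
                           max_bulge = 4L, max_bulge_total = 4L,
                           min_paired_frac = 0.6, outer_slack = 2L) {
  stopifnot(inherits(fold, "fold_result"), length(mature_span) == 2L)
  mature_span <- as.integer(mature_span)
  if (mature_span[1L] < 1L || mature_span[2L] > fold$n ||
      mature_span[1L] > mature_span[2L])
    stop("mature span outside the folded window")
  fail <- list(is_hairpin = FALSE, arm = NA_character_,
               stem_pairs = fold$pairs[0, , drop = FALSE],
               arms = NULL, mature_paired_frac = 0)
  # the stem must begin at the mature's outer end (either arm tried)
  stem <- stem_chain(fold$seq, max_bulge = max_bulge,
                     max_bulge_total = max_bulge_total,
                     anchor_i = c(max(1L, mature_span[1L] - outer_slack),
                                  mature_span[1L] + max_bulge),
                     anchor_j = c(mature_span[2L] - max_bulge,
                                  min(fold$n, mature_span[2L] + outer_slack)))
  if (nrow(stem) < min_stem_pairs) return(fail)
  arm5 <- range(stem[, "i"])
  arm3 <- range(stem[, "j"])
  loop <- c(arm5[2L] + 1L, arm3[1L] - 1L)
  m <- mature_span[1L]:mature_span[2L]
  on5 <- mature_span[1L] >= arm5[1L] - outer_slack &&
    mature_span[2L] < arm3[1L]
  on3 <- mature_span[1L] > arm5[2L] &&
    mature_span[2L] <= arm3[2L] + outer_slack
  if (!on5 && !on3) return(fail)
  if (on5 && on3) {
    on5 <- sum(m %in% stem[, "i"]) >= sum(m %in% stem[, "j"])
    on3 <- !on5
  }
  paired_frac <- if (on5) mean(m %in% stem[, "i"]) else
    mean(m %in% stem[, "j"])
  if (paired_frac < min_paired_frac) return(fail)
  list(is_hairpin = TRUE, arm = if (on5) "5p" else "3p",
       stem_pairs = stem,
       arms = list(arm5 = arm5, arm3 = arm3, loop = loop),
       mature_paired_frac = paired_frac)
}
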