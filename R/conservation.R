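# Cross-species conservation calls and genomic clustering of miRNA genes.

#' Search one species' sequence set for a mature miRNA homolog
#'
#' Scans for occurrences of the mature sequence with at most `max_mm`
#' mismatches (no indels, both strands). Each hit's flanking windows are
#' folded; a hit supported by a hairpin-shaped precursor is a
#' `precursor-homolog`, a hit without one is `mature-only` (which does not
#' count as a homolog for tier assignment), and no hit at all is `absent`.
#'
#' @param mature Mature miRNA sequence.
#' @param species_seqs [Biostrings::DNAStringSet] of the species' genomic /
#'   EST sequences.
#' @param max_mm Maximum mismatches.
#' @param window_lens Flanking window lengths for hairpin detection.
#' @return One of `"precursor-homolog"`, `"mature-only"`, `"absent"`.
#' @export
find_homolog <- function(mature, species_seqs, max_mm = 1L,
                         window_lens = c(120L, 100L, 80L, 60L)) {
  if (length(species_seqs) == 0L) return("absent")
  if (is.null(names(species_seqs)))
    names(species_seqs) <- paste0("seq", seq_along(species_seqs))
  pat <- as_dna(mature)
  found <- FALSE
  for (strand in c("+", "-")) {
    p <- if (strand == "+") pat else revcomp(pat)
    m <- Biostrings::vmatchPattern(p, species_seqs, max.mismatch = max_mm,
                                   fixed = TRUE)
    for (ci in seq_along(species_seqs)) {
      starts <- BiocGenerics::start(m[[ci]])
      if (length(starts) == 0L) next
      found <- TRUE
      for (st in starts) {
        fi <- best_hairpin_window(species_seqs[ci],
                                  names(species_seqs)[ci],
                                  st, st + nchar(pat) - 1L, strand,
                                  window_lens = window_lens)
        if (!is.null(fi)) return("precursor-homolog")
      }
    }
  }
  if (found) "mature-only" else "absent"
}

#' Assign a conservation tier from per-species homolog calls
#'
#' Only `precursor-homolog` calls count. Tiers, from narrowest to widest:
#' `species-specific` (no homolog outside the focal species),
#' `avian-specific` (homologs only in avian species), `avian+mammal` (also
#' in mammals but in no other vertebrate), `vertebrate` (in a non-avian,
#' non-mammal vertebrate), `pan-animal` (in an invertebrate). Adding a
#' species with a homolog can only widen the tier.
#'
#' @param calls Named character vector of per-species statuses from
#'   [find_homolog()].
#' @param groups List with character vectors `avian`, `mammal`,
#'   `vertebrate_other`, `invertebrate` naming the species in each group.
#' @return The tier label.
#' @export
assign_tier <- function(calls, groups) {
  if (length(calls) == 0L) stop("empty species set")
  hom <- names(calls)[calls == "precursor-homolog"]
  has <- function(g) any(hom %in% groups[[g]])
  if (has("invertebrate")) "pan-animal"
  else if (has("vertebrate_other")) "vertebrate"
  else if (has("mammal")) "avian+mammal"
  else if (has("avian")) "avian-specific"
  else "species-specific"
}

#' Group miRNA genes into genomic clusters
#'
#' Single-linkage chaining: loci on the same chromosome whose distance to
#' the previous locus is at most `cutoff` join one cluster (strand is
#' ignored). Singletons are not clusters. Clusters are named after their
#' first (leftmost) member followed by the member count in parentheses.
#' Clusters containing two loci with identical mature sequences are flagged
#' as tandem duplications.
#'
#' @param loci Data.frame with `name`, `chrom`, `start0` (and optionally
#'   `end0` and `mature`).
#' @param cutoff Distance cutoff, nt.
#' @param anchor `"start"` measures start-to-start distances; `"gap"`
#'   measures end-to-start gaps (requires `end0`).
#' @return Data.frame: cluster, chrom, n, members (comma-separated),
#'   span_start0, span_end0, tandem.
#' @export
cluster_loci <- function(loci, cutoff = 10000L, anchor = c("start", "gap")) {
  anchor <- match.arg(anchor)
  if (nrow(loci) == 0L)
    return(data.frame(cluster = character(0), chrom = character(0),
                      n = integer(0), members = character(0),
                      span_start0 = integer(0), span_end0 = integer(0),
                      tandem = logical(0), stringsAsFactors = FALSE))
  loci <- loci[order(loci$chrom, loci$start0), , drop = FALSE]
  out <- list()
  for (ch in unique(loci$chrom)) {
    l <- loci[loci$chrom == ch, , drop = FALSE]
    if (nrow(l) == 0L) next
    gap <- if (anchor == "start") diff(l$start0) else
      l$start0[-1L] - l$end0[-nrow(l)]
    grp <- cumsum(c(1L, as.integer(gap > cutoff)))
    for (g in unique(grp)) {
      m <- l[grp == g, , drop = FALSE]
      if (nrow(m) < 2L) next
      tandem <- if ("mature" %in% colnames(m))
        anyDuplicated(m$mature) > 0L else FALSE
      out[[length(out) + 1L]] <- data.frame(
        cluster = sprintf("%s(%d)", m$name[1L], nrow(m)),
        chrom = ch, n = nrow(m),
        members = paste(m$name, collapse = ","),
        span_start0 = min(m$start0),
        span_end0 = if ("end0" %in% colnames(m)) max(m$end0) else
          max(m$start0),
        tandem = tandem, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(cluster_loci(loci[0L, , drop = FALSE], cutoff))
  do.call(rbind, out)
}
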