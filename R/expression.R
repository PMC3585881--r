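# Expression analysis: RPM normalisation, tissue-enriched miRNA calls, and
# male:female expression ratios with Z-linkage annotation.

#' Expression matrix from miRNA records
#'
#' One row per distinct mature sequence (a multi-locus miRNA contributes its
#' counts once), one column per sample.
#'
#' @param records miRNA records from [call_candidates()].
#' @return Integer matrix, rownames = miRNA names.
#' @export
build_expression_matrix <- function(records) {
  recs <- records[!duplicated(records$sequence), , drop = FALSE]
  cols <- grep("^count\\.", colnames(recs), value = TRUE)
  m <- as.matrix(recs[, cols, drop = FALSE])
  colnames(m) <- sub("^count\\.", "", cols)
  rownames(m) <- recs$name
  m
}

#' Reads-per-million normalisation
#'
#' Scales each sample (column) to one million miRNA reads.
#'
#' @param mat Raw count matrix (miRNAs x samples).
#' @return Numeric matrix; each column sums to 1e6.
#' @export
rpm <- function(mat) {
  totals <- colSums(mat)
  if (any(totals == 0)) stop("sample with zero miRNA reads")
  sweep(mat, 2L, totals, "/") * 1e6
}

#' Call tissue-enriched miRNAs
#'
#' Counts are summed across sexes per tissue. A miRNA is enriched in its
#' top tissue when its total reads over all tissues reach `min_total` and
#' the top tissue holds at least `min_share` of them; ties for the top
#' tissue are called not-enriched. Calls are invariant to uniform scaling
#' of all samples.
#'
#' @param mat Raw count matrix (miRNAs x samples).
#' @param sample_tissue Named vector sample -> tissue (defaults to the part
#'   of the sample name before the final underscore).
#' @param min_total Minimum total reads across tissues.
#' @param min_share Minimum top-tissue share.
#' @return Data.frame: mirna, enriched_tissue (NA when not enriched),
#'   share, total.
#' @export
call_tissue_enrichment <- function(mat, sample_tissue = NULL,
                                   min_total = 100, min_share = 0.9) {
  if (is.null(sample_tissue))
    sample_tissue <- stats::setNames(sub("_[^_]*$", "", colnames(mat)),
                                     colnames(mat))
  tissues <- unique(unname(sample_tissue[colnames(mat)]))
  bytis <- vapply(tissues, function(t)
    rowSums(mat[, sample_tissue[colnames(mat)] == t, drop = FALSE]),
    numeric(nrow(mat)))
  if (nrow(mat) == 1L) bytis <- matrix(bytis, nrow = 1L,
                                       dimnames = list(rownames(mat),
                                                       tissues))
  total <- rowSums(bytis)
  share <- bytis / pmax(total, 1)
  top <- apply(share, 1L, max)
  top_t <- tissues[apply(share, 1L, which.max)]
  tied <- apply(share, 1L, function(x) sum(x == max(x)) > 1L)
  enriched <- total >= min_total & top >= min_share & !tied
  data.frame(mirna = rownames(mat),
             enriched_tissue = ifelse(enriched, top_t, NA_character_),
             share = top, total = total, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Male:female expression ratios with Z-linkage annotation
#'
#' Ratios are computed on RPM with a pseudocount in both numerator and
#' denominator; miRNAs whose combined raw reads fall below `min_total` are
#' excluded. Ratios are reported per tissue and for all tissues pooled
#' (`tissue = "all"`, recomputed from pooled counts).
#'
#' @param mat Raw count matrix (miRNAs x samples), columns named
#'   `<tissue>_<sex>`.
#' @param chrom Named vector miRNA -> chromosome (optional; enables the
#'   `z_linked` flag against `z_chrom`).
#' @param pseudocount Added to both RPM values.
#' @param min_total Minimum combined raw reads.
#' @param z_chrom Chromosome name treated as Z.
#' @return Data.frame: mirna, tissue, rpm_M, rpm_F, ratio, log2_ratio,
#'   chrom, z_linked.
#' @export
mf_ratio <- function(mat, chrom = NULL, pseudocount = 0.5, min_total = 100,
                     z_chrom = "chrZ") {
  sex <- sub("^.*_", "", colnames(mat))
  tissue <- sub("_[^_]*$", "", colnames(mat))
  if (!all(sex %in% c("M", "F")))
    stop("sample columns must be named <tissue>_<M|F>")
  norm <- rpm(mat)
  keep <- rowSums(mat) >= min_total
  out <- list()
  add <- function(tis, rpm_m, rpm_f) {
    out[[length(out) + 1L]] <<- data.frame(
      mirna = rownames(mat)[keep], tissue = tis,
      rpm_M = rpm_m[keep], rpm_F = rpm_f[keep],
      ratio = (rpm_m[keep] + pseudocount) / (rpm_f[keep] + pseudocount),
      stringsAsFactors = FALSE)
  }
  for (t in unique(tissue)) {
    mcol <- which(tissue == t & sex == "M")
    fcol <- which(tissue == t & sex == "F")
    if (length(mcol) == 0L || length(fcol) == 0L) next
    add(t, rowSums(norm[, mcol, drop = FALSE]),
        rowSums(norm[, fcol, drop = FALSE]))
  }
  pooled <- function(sx) {
    cols <- which(sex == sx)
    cnt <- rowSums(mat[, cols, drop = FALSE])
    cnt / sum(cnt) * 1e6
  }
  add("all", pooled("M"), pooled("F"))
  res <- do.call(rbind, out)
  res$log2_ratio <- log2(res$ratio)
  res$chrom <- if (is.null(chrom)) NA_character_ else
    unname(chrom[res$mirna])
  res$z_linked <- !is.na(res$chrom) & res$chrom == z_chrom
  rownames(res) <- NULL
  res
}
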