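# Seed-match target prediction on 3' UTRs and chromosomal enrichment.

# apply the minimum-UTR-length exclusion once, consistently
utr_universe <- function(utrs, min_utr = 10L) {
  utrs[nchar(utrs$utr) >= min_utr, , drop = FALSE]
}

#' Predict seed-match targets of a miRNA in a 3' UTR set
#'
#' The seed is mature positions 2-8 (a 7-mer); a gene is a putative target
#' when its 3' UTR contains the exact reverse complement of the seed (sense
#' strand, perfect match, gene-level binary). Genes with a UTR shorter than
#' `min_utr` nt are excluded from the universe before matching. Matching is
#' insensitive to case and to the T/U alphabet.
#'
#' @param mature Mature miRNA sequence, at least 8 nt.
#' @param utrs Data.frame with columns `gene`, `chrom`, `utr`.
#' @param min_utr Minimum UTR length kept.
#' @return Character vector of target gene ids.
#' @export
seed_match <- function(mature, utrs, min_utr = 10L) {
  mature <- as_dna(mature)
  if (nchar(mature) < 8L) stop("mature sequence shorter than 8 nt")
  u <- utr_universe(utrs, min_utr)
  site <- revcomp(substr(mature, 2L, 8L))
  hit <- grepl(site, as_dna(u$utr), fixed = TRUE)
  u$gene[hit]
}

#' Chromosomal enrichment of predicted targets (Fisher's exact test)
#'
#' Builds the 2x2 table of target/non-target genes on/off the chromosome
#' over the UTR-bearing gene universe and computes the one-sided (greater)
#' exact hypergeometric tail probability — enrichment, not depletion.
#'
#' @param targets Character vector of target gene ids (from
#'   [seed_match()]).
#' @param utrs The UTR data.frame defining the gene universe.
#' @param chromosome Chromosome label tested for enrichment.
#' @param min_utr Minimum UTR length (must match the prediction step).
#' @return A list of class `enrichment_result`: `table` (2x2 integer
#'   matrix), `p_value`, `odds_ratio` (sample odds ratio), `frac_on_chrom`
#'   (fraction of targets on the chromosome), `chromosome`.
#' @export
fisher_enrichment <- function(targets, utrs, chromosome, min_utr = 10L) {
  u <- utr_universe(utrs, min_utr)
  if (nrow(u) == 0L) stop("empty gene universe")
  is_t <- u$gene %in% targets
  on_c <- u$chrom == chromosome
  tab <- matrix(c(sum(is_t & on_c), sum(is_t & !on_c),
                  sum(!is_t & on_c), sum(!is_t & !on_c)),
                2L, 2L, byrow = TRUE,
                dimnames = list(c("target", "non-target"),
                                c("on_chrom", "elsewhere")))
  p <- fisher.test(tab, alternative = "greater")$p.value
  or <- (tab[1, 1] * tab[2, 2]) / max(tab[1, 2] * tab[2, 1], .Machine$double.eps)
  structure(list(table = tab, p_value = p, odds_ratio = or,
                 frac_on_chrom = if (sum(is_t) > 0)
                   tab[1, 1] / sum(is_t) else NA_real_,
                 chromosome = chromosome),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("targets on %s: %d of %d (%.1f%%), one-sided p = %.3g\n",
              x$chromosome, x$table[1, 1], sum(x$table[1, ]),
              100 * x$table[1, 1] / max(sum(x$table[1, ]), 1), x$p_value))
  invisible(x)
}

#' Per-chromosome distribution of predicted targets
#'
#' Target counts and percentages per chromosome, side by side with the
#' background distribution of UTR-bearing genes.
#'
#' @param targets Character vector of target gene ids.
#' @param utrs The UTR data.frame.
#' @param min_utr Minimum UTR length.
#' @return Data.frame: chrom, targets, target_pct (one decimal), genes,
#'   gene_pct. Empty when there are no targets.
#' @export
target_report <- function(targets, utrs, min_utr = 10L) {
  u <- utr_universe(utrs, min_utr)
  if (length(targets) == 0L)
    return(data.frame(chrom = character(0), targets = integer(0),
                      target_pct = numeric(0), genes = integer(0),
                      gene_pct = numeric(0), stringsAsFactors = FALSE))
  chroms <- sort(unique(u$chrom))
  tc <- table(factor(u$chrom[u$gene %in% targets], levels = chroms))
  gc <- table(factor(u$chrom, levels = chroms))
  data.frame(chrom = chroms,
             targets = as.integer(tc),
             target_pct = round(100 * as.integer(tc) / sum(tc), 1L),
             genes = as.integer(gc),
             gene_pct = round(100 * as.integer(gc) / sum(gc), 1L),
             row.names = NULL, stringsAsFactors = FALSE)
}
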