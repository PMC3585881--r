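# End-to-end orchestration over the synthetic study: simulate, preprocess,
# map, classify, discover, cluster, profile isomiRs, call expression biases,
# and predict/enrich targets, with per-stage count logging.

log_stage <- function(verbose, stage, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full pipeline on a synthetic study
#'
#' Generates a genome and reads from `cfg`, then runs every stage in order:
#' demultiplex/trim -> orphan removal -> exact mapping -> class partition ->
#' candidate calling -> clustering (and, optionally, conservation tiers) ->
#' isomiR profiles and substitution sites -> tissue enrichment and M:F
#' ratios -> seed-match targets and chrZ enrichment. Returns all stage
#' outputs together with the generator truth so recovery can be scored.
#'
#' @param cfg A [sim_config()].
#' @param known_matures Optional known-mature set for homolog annotation
#'   (`NULL` runs pure novel discovery).
#' @param with_species Also generate species sets and assign conservation
#'   tiers (slower).
#' @param with_utrs Also generate UTRs and run target prediction.
#' @param verbose Emit one log line per stage.
#' @return A list with elements `sim`, `reads`, `qc`, `collapsed`, `map`,
#'   `classified`, `class_summary`, `records`, `clusters`, `tiers`,
#'   `profiles`, `sites`, `expression` (list: matrix, rpm, enrichment,
#'   mf), `targets` (list per tested miRNA), and `truth`.
#' @export
run_pipeline <- function(cfg, known_matures = NULL, with_species = FALSE,
                         with_utrs = TRUE, verbose = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  t0 <- Sys.time()
  sim <- make_genome(cfg)
  rd <- make_reads(cfg, sim)
  log_stage(verbose, "simulate", "%d loci, %d reads in %d libraries",
            nrow(sim$loci), nrow(rd$reads),
            length(unique(rd$reads$sample)))

  td <- trim_and_demux(rd$reads, rd$barcodes)
  log_stage(verbose, "preprocess", "%d assigned, %d dropped (%s)",
            td$qc[["assigned"]], sum(td$qc) - td$qc[["assigned"]],
            paste(names(td$qc[-1L]), td$qc[-1L], collapse = ", "))
  collapsed <- drop_orphans(td$collapsed)
  log_stage(verbose, "preprocess", "%d distinct sequences after orphan removal",
            nrow(collapsed))

  map <- map_exact(collapsed, sim$genome)
  log_stage(verbose, "mapping", "%d mapped / %d unmapped / %d excluded",
            sum(map$status$status == "mapped"),
            sum(map$status$status == "unmapped"),
            sum(map$status$status == "excluded"))
  classified <- classify_reads(map, repeats = sim$decoys[
    sim$decoys$class == "repeat", , drop = FALSE],
    known_ncrna = sim$known_ncrna)
  csum <- class_summary(classified, collapsed)
  log_stage(verbose, "classes", "%s",
            paste(sprintf("%s %.1f%%", csum$rna_class, 100 * csum$fraction),
                  collapse = ", "))

  records <- call_candidates(collapsed, classified, map, sim$genome,
                             known_matures = known_matures)
  log_stage(verbose, "discovery", "%d miRNA records (%d novel)",
            nrow(records), sum(records$status == "novel"))

  loci_tab <- records[!is.na(records$chrom), , drop = FALSE]
  clusters <- cluster_loci(data.frame(name = loci_tab$name,
                                      chrom = loci_tab$chrom,
                                      start0 = loci_tab$mat_start0,
                                      end0 = loci_tab$mat_end0,
                                      mature = loci_tab$sequence,
                                      stringsAsFactors = FALSE))
  log_stage(verbose, "clusters", "%d clusters", nrow(clusters))

  tiers <- NULL
  if (with_species) {
    sp <- sim_species_sets(cfg, sim)
    tiers <- data.frame(
      mirna = records$name,
      tier = vapply(records$sequence, function(m) {
        calls <- vapply(names(sp$species), function(s)
          find_homolog(m, sp$species[[s]]), character(1))
        assign_tier(calls, sp$groups)
      }, character(1)),
      stringsAsFactors = FALSE)
    log_stage(verbose, "conservation", "%s",
              paste(names(table(tiers$tier)), table(tiers$tier),
                    collapse = ", "))
  }

  profiles <- isomir_profiles(records, collapsed, sim$genome, classified)
  sites <- do.call(rbind, lapply(profiles, call_sites))
  if (!is.null(sites)) rownames(sites) <- NULL
  log_stage(verbose, "isomir", "%d profiles, %d substitution sites",
            length(profiles), if (is.null(sites)) 0L else nrow(sites))

  expression <- NULL
  if (nrow(records) > 0L) {
    mat <- build_expression_matrix(records)
    chrom_map <- stats::setNames(records$chrom, records$name)
    expression <- list(
      matrix = mat, rpm = rpm(mat),
      enrichment = call_tissue_enrichment(mat),
      mf = mf_ratio(mat, chrom = chrom_map))
    log_stage(verbose, "expression", "%d enriched calls",
              sum(!is.na(expression$enrichment$enriched_tissue)))
  } else {
    log_stage(verbose, "expression", "no miRNA records; stage skipped")
  }

  targets <- NULL
  if (with_utrs) {
    ut <- sim_utrs(cfg, sim)
    ztest <- records[records$chrom %in% "chrZ", , drop = FALSE]
    targets <- list(utrs = ut, results = list())
    for (i in seq_len(nrow(ztest))) {
      tg <- seed_match(ztest$sequence[i], ut$utrs)
      enr <- fisher_enrichment(tg, ut$utrs, "chrZ")
      targets$results[[ztest$name[i]]] <-
        list(targets = tg, enrichment = enr,
             report = target_report(tg, ut$utrs))
    }
    log_stage(verbose, "targets", "%d Z-linked miRNAs tested",
              length(targets$results))
  }

  log_stage(verbose, "done", "elapsed %.1f s",
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
  list(sim = sim, reads = rd$reads, qc = td$qc, collapsed = collapsed,
       map = map, classified = classified, class_summary = csum,
       records = records, clusters = clusters, tiers = tiers,
       profiles = profiles, sites = sites, expression = expression,
       targets = targets, truth = rd$truth)
}

#' Score planted-locus recovery of a pipeline run
#'
#' A planted locus is recovered when a discovery record carries its mature
#' sequence; a false discovery is a novel record whose sequence is not a
#' planted mature.
#'
#' @param res Output of [run_pipeline()].
#' @return List: `recovered` (logical per planted locus, named),
#'   `recovery_rate`, `false_novel` (count).
#' @export
evaluate_discovery <- function(res) {
  planted <- as_rna(res$sim$loci$mature)
  names(planted) <- res$sim$loci$name
  found <- planted %in% res$records$sequence
  names(found) <- names(planted)
  false_novel <- sum(res$records$status == "novel" &
                       !res$records$sequence %in% planted)
  list(recovered = found,
       recovery_rate = if (length(found)) mean(found) else NA_real_,
       false_novel = false_novel)
}
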