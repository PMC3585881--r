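# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# A moderate synthetic study exercised by several test files: 8 loci
# (one 2-member cluster, 3 Z-linked of which one male-biased), 6000 reads
# per library.
small_cfg <- function() {
  sim_config(seed = 421L, n_mirna_loci = 8L, n_z_loci = 3L,
             cluster_spec = list(list(n = 2L, spacing = 4000L)),
             n_subst_loci = 2L, depth_per_sample = 6000L)
}

small_run <- function() {
  if (is.null(.fixtures$small_run))
    .fixtures$small_run <- run_pipeline(small_cfg(), verbose = FALSE,
                                        with_utrs = TRUE)
  .fixtures$small_run
}

# a tiny genome with one planted locus, for constructed discovery cases
one_locus_sim <- function() {
  if (is.null(.fixtures$one_locus))
    .fixtures$one_locus <- make_genome(
      sim_config(seed = 77L, n_mirna_loci = 1L, n_z_loci = 0L,
                 cluster_spec = list(), n_subst_loci = 0L,
                 chrom_lens = c(chr1 = 8000L, chrZ = 3000L),
                 n_decoys = 0L))
  .fixtures$one_locus
}

# collapsed-read table from named count vectors, one element per sample
make_collapsed <- function(seqs, ...) {
  counts <- list(...)
  df <- data.frame(sequence = seqs, stringsAsFactors = FALSE)
  for (s in names(counts)) df[[s]] <- counts[[s]]
  df
}
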