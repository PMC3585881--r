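#!/usr/bin/env Rscript
# Stage 5 — group the annotated miRNA genes into genomic clusters (10 kb
# single-linkage, named "<first member>(n)") and assign conservation tiers
# by scanning each species' sequence set for <= 1-mismatch homologs backed
# by a foldable precursor (mature-only hits do not count).
#
# The species sequence sets are regenerated from the stage-1 seed, so this
# stage is reproducible without extra artifacts on disk.
#
# Writes results/conservation/{clusters.tsv,tiers.tsv}.

library(finchmir)

records <- read.table("results/discovery/mirna_table.tsv", header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)
cfg <- sim_config(seed = 20121226L)
sim <- make_genome(cfg)
sp <- sim_species_sets(cfg, sim)

withp <- records[!is.na(records$chrom), , drop = FALSE]
clusters <- cluster_loci(data.frame(name = withp$name,
                                    chrom = withp$chrom,
                                    start0 = withp$mat_start0,
                                    end0 = withp$mat_end0,
                                    mature = withp$sequence,
                                    stringsAsFactors = FALSE))
message(sprintf("%d genomic clusters:", nrow(clusters)))
for (i in seq_len(nrow(clusters)))
  message(sprintf("  %s on %s [%s]", clusters$cluster[i],
                  clusters$chrom[i], clusters$members[i]))

tiers <- data.frame(
  mirna = records$name,
  tier = vapply(records$sequence, function(m) {
    calls <- vapply(names(sp$species), function(s)
      find_homolog(m, sp$species[[s]]), character(1))
    assign_tier(calls, sp$groups)
  }, character(1)), stringsAsFactors = FALSE)
message("conservation tiers:")
print(table(tiers$tier))

dir.create("results/conservation", recursive = TRUE, showWarnings = FALSE)
write.table(clusters, "results/conservation/clusters.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(tiers, "results/conservation/tiers.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
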