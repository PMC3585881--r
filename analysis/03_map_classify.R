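#!/usr/bin/env Rscript
# Stage 3 — map collapsed reads to the genome by exact matching (both
# strands, all occurrences; >100 loci excluded), then partition sequences
# into small-RNA classes: ncRNA homology (<= 1 mismatch) > repeat overlap >
# miRNA candidate; unmapped reads are kept for homology rescue.
#
# Reads results/sim + results/preprocess; writes
# results/mapping/{hits.tsv,status.tsv,class_summary.tsv}.

library(finchmir)

genome <- Biostrings::readDNAStringSet("results/sim/genome.fa")
collapsed <- read.table("results/preprocess/counts.tsv", header = TRUE,
                        stringsAsFactors = FALSE)
ann <- rtracklayer::import("results/sim/annotation.bed")
known_ncrna <- Biostrings::readDNAStringSet("results/sim/known_ncrna.fa")

map <- map_exact(collapsed, genome)
tab <- table(map$status$status)
message(paste(sprintf("%s: %d sequences", names(tab), tab), collapse = "; "))

repeats <- ann[grepl("^repeat", ann$name)]
classified <- classify_reads(map, repeats = repeats,
                             known_ncrna = known_ncrna)
cs <- class_summary(classified, collapsed)
message("read-weighted class fractions:")
for (i in seq_len(nrow(cs)))
  message(sprintf("  %-18s %6.2f%%", cs$rna_class[i], 100 * cs$fraction[i]))

dir.create("results/mapping", recursive = TRUE, showWarnings = FALSE)
write.table(map$hits, "results/mapping/hits.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(classified, "results/mapping/status.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cs, "results/mapping/class_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
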