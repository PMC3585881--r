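#!/usr/bin/env Rscript
# Stage 2 — demultiplex the multiplexed FASTQ by pentamer barcode, trim the
# constant 3' adapter, collapse identical inserts, and drop orphans
# (sequences seen once in the whole experiment).
#
# Reads results/sim/{reads.fastq,barcodes.tsv}; writes
# results/preprocess/{counts.tsv,qc.tsv}.

library(finchmir)

bm <- read.table("results/sim/barcodes.tsv", header = TRUE,
                 stringsAsFactors = FALSE)
barcodes <- setNames(bm$sample, bm$barcode)

td <- trim_and_demux("results/sim/reads.fastq", barcodes)
message(sprintf("assigned %d of %d reads (%.1f%%)", td$qc[["assigned"]],
                sum(td$qc), 100 * td$qc[["assigned"]] / sum(td$qc)))
for (k in setdiff(names(td$qc), "assigned"))
  message(sprintf("  dropped %-16s %d", k, td$qc[[k]]))

collapsed <- drop_orphans(td$collapsed)
message(sprintf("%d distinct sequences after orphan removal (of %d)",
                nrow(collapsed), nrow(td$collapsed)))

dir.create("results/preprocess", recursive = TRUE, showWarnings = FALSE)
write.table(collapsed, "results/preprocess/counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(metric = names(td$qc), reads = as.integer(td$qc)),
            "results/preprocess/qc.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
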