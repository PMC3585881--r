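#!/usr/bin/env Rscript
# Stage 7 — expression analysis: RPM normalisation, tissue-enriched miRNA
# calls (>= 100 reads, >= 90% of reads in one tissue, sexes combined), and
# male:female expression ratios with Z-linkage annotation (the dosage
# analysis).
#
# Writes results/expression/{matrix.tsv,rpm.tsv,enrichment.tsv,
# mf_ratios.tsv}.

library(finchmir)

records <- read.table("results/discovery/mirna_table.tsv", header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)
mat <- build_expression_matrix(records)
norm <- rpm(mat)

enr <- call_tissue_enrichment(mat)
called <- enr[!is.na(enr$enriched_tissue), , drop = FALSE]
message(sprintf("%d of %d miRNAs single-tissue enriched (%.0f%%)",
                nrow(called), nrow(enr), 100 * nrow(called) / nrow(enr)))
for (i in seq_len(nrow(called)))
  message(sprintf("  %s -> %s (%.1f%% of %d reads)", called$mirna[i],
                  called$enriched_tissue[i], 100 * called$share[i],
                  called$total[i]))

chrom_map <- setNames(records$chrom, records$name)
mf <- mf_ratio(mat, chrom = chrom_map)
zall <- mf[mf$tissue == "all" & mf$z_linked, , drop = FALSE]
message("M:F ratios of Z-linked miRNAs (all tissues pooled):")
for (i in seq_len(nrow(zall)))
  message(sprintf("  %-14s %5.2f", zall$mirna[i], zall$ratio[i]))

dir.create("results/expression", recursive = TRUE, showWarnings = FALSE)
write.table(data.frame(mirna = rownames(mat), mat, check.names = FALSE),
            "results/expression/matrix.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(mirna = rownames(norm), round(norm, 2L),
                       check.names = FALSE),
            "results/expression/rpm.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(enr, "results/expression/enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(mf, "results/expression/mf_ratios.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
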