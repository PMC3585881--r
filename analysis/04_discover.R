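#!/usr/bin/env Rscript
# Stage 4 — call miRNA candidates from mapped read stacks: fold 60-120 nt
# flanking windows, require a hairpin precursor, >10 reads, a star sequence
# on the opposite arm, and a precise 5' end. Novel discovery runs without
# any known-mature set here (the conservation stage compares against the
# planted reference separately).
#
# Writes results/discovery/{mirna_table.tsv,precursors.fa,structures.txt}.

library(finchmir)

genome <- Biostrings::readDNAStringSet("results/sim/genome.fa")
collapsed <- read.table("results/preprocess/counts.tsv", header = TRUE,
                        stringsAsFactors = FALSE)
classified <- read.table("results/mapping/status.tsv", header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE)
hits <- read.table("results/mapping/hits.tsv", header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
map <- list(hits = hits, status = classified[, c("sequence", "n_loci",
                                                 "status")])

records <- call_candidates(collapsed, classified, map, genome)
message(sprintf("%d miRNA records (%d novel, %d with a star sequence)",
                nrow(records), sum(records$status == "novel"),
                sum(records$star_count > 0)))
message(sprintf("%d records retain both arms at <10-fold difference",
                sum(records$both_arms_retained)))

dir.create("results/discovery", recursive = TRUE, showWarnings = FALSE)
write.table(records, "results/discovery/mirna_table.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# precursor windows and their dot-bracket structures
withp <- records[!is.na(records$chrom), , drop = FALSE]
prec <- vapply(seq_len(nrow(withp)), function(i) {
  s <- substr(as.character(genome[[withp$chrom[i]]]),
              withp$prec_start0[i] + 1L, withp$prec_end0[i])
  if (withp$strand[i] == "-") revcomp(s) else s
}, character(1))
ps <- Biostrings::DNAStringSet(prec)
names(ps) <- withp$name
Biostrings::writeXStringSet(ps, "results/discovery/precursors.fa")
writeLines(vapply(seq_along(prec), function(i)
  sprintf(">%s\n%s\n%s", withp$name[i], prec[i],
          dot_bracket(fold_max_pairs(prec[i]))), character(1)),
  "results/discovery/structures.txt")
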