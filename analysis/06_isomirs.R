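#!/usr/bin/env Rscript
# Stage 6 — classify every assigned read into the isomiR taxonomy
# (canonical, templated 5'/3' length variants, untemplated A/U tails,
# internal substitutions), call substitution sites (>100 total reads, >5%
# rate, >= 2 nt from the termini), and analyse the 6-nt motif context of
# called sites with per-position information content.
#
# Writes results/isomir/{class_fractions.tsv,profiles.tsv,sites.tsv,
# motif_ic.tsv,tailing.tsv}.

library(finchmir)

genome <- Biostrings::readDNAStringSet("results/sim/genome.fa")
collapsed <- read.table("results/preprocess/counts.tsv", header = TRUE,
                        stringsAsFactors = FALSE)
classified <- read.table("results/mapping/status.tsv", header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE)
records <- read.table("results/discovery/mirna_table.tsv", header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)

profiles <- isomir_profiles(records, collapsed, genome, classified)
cc <- Reduce(`+`, lapply(profiles, function(p) p$class_counts))
total <- sum(cc)
message(sprintf("assigned %d reads across %d miRNAs", total,
                length(profiles)))
lenv <- cc[["len5"]] + cc[["len3"]] + cc[["both-ends"]]
message(sprintf("length variants: %.1f%% of miRNA reads (%.1f%% of them 3')",
                100 * lenv / total, 100 * cc[["len3"]] / lenv))
message(sprintf("untemplated tails: %.1f%% (U:A = %.2f)",
                100 * (cc[["tail-U"]] + cc[["tail-A"]] +
                         cc[["tail-other"]]) / total,
                cc[["tail-U"]] / max(cc[["tail-A"]], 1)))

sites <- do.call(rbind, lapply(profiles, call_sites))
if (!is.null(sites)) rownames(sites) <- NULL
message(sprintf("%d substitution sites called (%d at a GGU motif)",
                if (is.null(sites)) 0L else nrow(sites),
                if (is.null(sites)) 0L else sum(sites$in_GGU)))

dir.create("results/isomir", recursive = TRUE, showWarnings = FALSE)
write.table(data.frame(class = names(cc), reads = as.numeric(cc),
                       fraction = as.numeric(cc) / total),
            "results/isomir/class_fractions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
prof_tab <- do.call(rbind, lapply(profiles, function(p)
  data.frame(mirna = p$name, canonical = p$canonical, arm = p$arm,
             total = p$total, t(p$class_counts), check.names = FALSE,
             stringsAsFactors = FALSE)))
write.table(prof_tab, "results/isomir/profiles.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
if (!is.null(sites) && nrow(sites) > 0L) {
  write.table(sites, "results/isomir/sites.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
  canonicals <- setNames(vapply(profiles, function(p) p$canonical,
                                character(1)),
                         vapply(profiles, function(p) p$name, character(1)))
  mw <- motif_windows(sites, canonicals)
  if (nrow(mw$windows) > 0L) {
    ic <- information_content(mw$windows)
    write.table(cbind(data.frame(position = seq_along(ic$ic),
                                 ic_bits = ic$ic), t(ic$freq)),
                "results/isomir/motif_ic.tsv", sep = "\t",
                quote = FALSE, row.names = FALSE)
    message(sprintf("motif windows: %d (GGU in %d); IC at position 3: %.2f",
                    nrow(mw$windows), sum(mw$windows$in_GGU), ic$ic[3L]))
  }
}
ts <- tailing_summary(profiles)
write.table(ts$per_mirna, "results/isomir/tailing.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
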