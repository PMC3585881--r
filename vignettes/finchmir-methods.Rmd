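---
title: "Methods: annotating a songbird miRNA repertoire from barcoded small-RNA libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating a songbird miRNA repertoire}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and study design

`finchmir` re-implements, as a tested pipeline, the analysis path from raw
multiplexed small-RNA sequencing reads to an annotated microRNA repertoire
with isomiR profiles, tissue- and sex-bias calls, and seed-match target
predictions with chromosomal enrichment statistics. The study design it is
built around is the zebra finch multi-tissue survey: eight libraries (brain,
heart, liver, muscle, in males and females) sequenced together, each read
carrying a 5-nt sample barcode followed by a constant 3' adapter. Because no
public raw data accompany that design at a size workable on one CPU, the
package ships a synthetic-study generator (`sim_config()`, `make_genome()`,
`make_reads()`) that emits a toy genome with planted precursor loci and
barcoded reads with a complete truth table, so every stage of the pipeline
is testable end to end with known answers.

# The synthetic study: what it emulates and what it does not

The generator's defaults are the study conditions the rest of the package
is validated against:

* **Loci.** Twelve miRNA loci: one genomic cluster of three members spaced
  5 kb apart (clusters are defined by a 10 kb cutoff, so the planted
  cluster is comfortably inside it), and three Z-chromosome loci of which
  one is a designated strongly male-biased locus. Precursors are designed
  stem-loops: a 22-nt mature arm, a 10-nt loop, and a complementary arm
  carrying two planted mismatches. The mismatches matter: a perfectly
  complementary arm makes the mature read an exact reverse-complement
  match of its own star arm (a phantom antisense locus for the mapper),
  and with a single mismatch one sequencing error can recreate such a
  match; two mismatches push that below double-error probability while
  still leaving a 20-pair stem, well above the 18-pair detection floor.
* **Read classes.** Per miRNA read: 25% templated length variants (80% of
  them at the 3' end, shifts of 1-3 nt), 15% untemplated 3' tails (U:A at
  2:1, 1-2 nt), a 5% star-strand fraction, and — at four designated loci —
  an 8% internal-substitution rate at a planted GGU motif whose U sits at
  mature position 14. The two templated bases downstream of every mature
  3' end are fixed to `CG`, so a simulated A or U tail is always
  untemplated and the tail/length-variant distinction has an exact truth.
* **Depth and errors.** 12,000 reads per library (about 1,000 per locus
  per library) with a 0.5% per-base error rate applied to the whole raw
  read, including barcode and adapter — so demultiplexing losses are part
  of the simulation.
* **Sex bias.** Ordinary Z loci are expressed with a male:female factor
  of 2 (the two-Z-copy dosage expectation in birds, which lack
  chromosome-wide dosage compensation); the designated locus uses a
  factor of 10. Z-linked loci carry small expression weights (5% and 2%
  of an autosomal locus) so that, with fixed per-library depth, the
  multinomial renormalisation does not compress the planted ratios — in
  real libraries sex-linked miRNAs are likewise a minor fraction of the
  pool. Library depth is fixed per sample, so a residual compression of a
  few percent remains; it is well inside the binomial noise at the
  default depth.
* **Targets.** `sim_utrs()` builds a 600-gene universe (12% on chrZ) with
  random 150-400 nt 3' UTRs and plants exact seed matches for the
  male-biased locus with a strong chrZ bias (30 Z targets, 25 autosomal)
  and for one ordinary Z locus uniformly, giving one true enrichment and
  one true null.
* **Conservation.** `sim_species_sets()` assigns each locus a tier
  (species-specific through pan-animal, the male-biased locus fixed
  avian-specific) and embeds the full foldable precursor in synthetic
  "genomes" of the species implied by the tier, plus one mature-only
  plant that must *not* count as a homolog.

What the generator does **not** emulate: ligation and PCR bias, quality
score structure, genuine genome complexity (background is i.i.d. uniform),
spliced or repetitive miRNA loci, SNPs, and free-energy-realistic
secondary structure. Passing the recovery tests therefore demonstrates
that the pipeline's rules are implemented correctly and are mutually
consistent — not that they would achieve the same sensitivity on real
tissue libraries.

# Preprocessing

Reads are of the form insert + 5-nt barcode + constant 3' adapter,
truncated to 36 nt, so the adapter is always present as a (possibly
partial) suffix. `trim_and_demux()` takes the longest exact suffix match
of at least 6 nt against the adapter prefix; the five preceding bases are
the barcode. There is no mismatch tolerance in the adapter or barcode:
the constant regions are known exactly, and with a 0.5% error rate the
cost is a ~7% loss of reads, which the simulation reproduces. Inserts
outside 18-32 nt, with an N, or with an unknown barcode are tallied and
dropped; the QC tallies always sum to the number of raw reads.
`drop_orphans()` then removes sequences whose total count across all
samples is one — with collapse-then-filter semantics, a sequence seen
once anywhere in the experiment.

# Mapping and class partition

`map_exact()` reports every exact occurrence of each distinct sequence on
both genome strands (minus-strand hits on forward coordinates); sequences
with more than 100 loci are excluded, and unmapped sequences are retained
for homology rescue. Classification is a strict precedence partition:
homology to known tRNA/rRNA/ncRNA sequences (Hamming distance at most one
mismatch on equal-length windows, no indels — matching the sliding-window
reading of "at most one mismatch") wins over repeat-interval overlap
(>= 1 nt), which wins over miRNA candidacy. Multi-locus reads keep their
full count at every locus, un-split; expression later counts each
distinct sequence once.

# Hairpin detection

Candidate loci are read stacks: mapped candidate reads merged across gaps
of up to 30 nt, so the two arms of one precursor (separated by the loop)
form a single stack. For each stack, windows of 120/100/80/60 nt are
extracted with the most abundant read placed on either arm.

Structure is assessed without an external folding program.
`fold_max_pairs()` is a maximum base-pairing (Nussinov-style) dynamic
program over Watson-Crick plus G·U pairs with a minimum loop of three,
with a deterministic traceback; it defines the package's structure
strings and is property-tested against exhaustive enumeration.
For the hairpin *decision*, however, the pair list of one optimal
structure is an unstable statistic: maximum-pairing optima are massively
degenerate, and the returned optimum frequently trades a few planted stem
pairs for loop-internal pairs, fragmenting the stem. `detect_hairpin()`
therefore scores the longest **bulged inverted repeat** (`stem_chain()`):
the longest run of nested pairs with at most 4 skipped bases between
consecutive pairs *and at most 4 skipped bases in total*, computed by
dynamic programming over all pairable positions, and **anchored** so the
stem's outermost pair starts at the outer end of the mature read. Both
restrictions are essential: without the total-bulge budget the longest
chain in a random 120-nt window averages ~20 pairs (G·U wobble makes
pairing probability 6/16, and free bulges make chain growth
supercritical), and without the anchor the best chain rarely coincides
with the candidate read. A window is a hairpin when the anchored stem has
at least 18 pairs, the mature lies on one arm of it (it may not intrude
into the opposite arm's paired span, and may dangle at most 2 nt beyond
the outer stem end), and at least 60% of mature bases are paired. Among
passing window configurations the one pairing the largest fraction of
mature bases wins, so a genuine precursor beats an incidental chain.

A novel miRNA call requires all four criteria: the hairpin; more than 10
stack reads; a star sequence — the most abundant opposite-arm read whose
span matches the duplex partner span of the mature within 3 nt at each
end (covering the canonical 2-nt overhang); and 5'-end precision,
operationalised as the modal 5' position holding at least 90% of
mature-arm reads (star reads, which legitimately have their own 5' end,
are excluded from this tally). Sequences within one mismatch of a known
mature at equal length are accepted as known homologs without the
star/precision requirements, and unmapped sequences matching a known
mature are rescued without a precursor; close variants of an
already-annotated miRNA never create additional records — they are
isomiRs of that record.

# Conservation and clusters

`find_homolog()` scans a species' sequence set for occurrences of the
mature with at most one mismatch and requires a detected hairpin in the
flanking windows; a hit without a hairpin is `mature-only` and does not
count. Tiers widen monotonically from species-specific to pan-animal as
homologs appear in avian, mammalian, other-vertebrate, and invertebrate
groups. Clustering is single-linkage with a 10 kb cutoff measured
start-to-start (configurable to end-to-start; the distance anchor is not
fixed by convention), strand-ignored; clusters are named
`<first member>(n)` and flagged as tandem duplications when two members
share a mature sequence.

# isomiR classification and substitution sites

`classify_read()` aligns a read to a canonical miRNA end-anchored, with
no indels in the read body, sliding the 5' end within 4 nt over the
templated genomic context. Priority: perfect templated match (canonical
or 5'/3'/both-end length variant), then an untemplated 1-2 nt tail (each
tail base must differ from the templated base at its position; tails take
precedence over length variation of the read body, since a trimmed body
plus tail is read as a tailed isoform), then a single internal
substitution. Reads classifiable to more than one miRNA are excluded as
ambiguous. Substitution sites are called per position when the miRNA's
total profiled reads exceed 100, substituted reads (summed over alternate
bases — the per-alternate alternative is stricter and not used) exceed 5%
of the total, and the position is at least 2 from either terminus
(positions 2 through L-1). A-to-G sites are flagged as putative editing,
and every site carries a one-sided binomial p-value against the 0.5%
sequencing error floor as an annotation — the 5% rule, not the p-value,
is the call criterion. Motif analysis extracts 6-nt windows with the
substituted base at position 3, so a GGU reference motif ending at the
site occupies window positions 1-3; per-position information content is
`2 - H` in bits with no small-sample correction.

# Expression and sex bias

RPM normalises each library to one million miRNA reads. Tissue enrichment
combines sexes per tissue and requires at least 100 reads summed over all
tissues with one tissue holding >= 90% — the total is across tissues
combined, not per tissue, which is the only reading consistent with
deeply brain-enriched miRNAs that still have a few hundred reads
elsewhere. Male:female ratios are computed on RPM with a 0.5 pseudocount
in numerator and denominator, per tissue and pooled; miRNAs under 100
combined reads are excluded as too thin to ratio.

# Targets and enrichment

The seed is mature positions 2-8; a gene is a target when its 3' UTR
(>= 10 nt, shorter UTRs excluded from the universe) contains the exact
reverse complement of the seed on the sense strand, counted once per
gene. Chromosomal enrichment is the one-sided (greater) exact
hypergeometric tail on the 2x2 target-by-chromosome table over the
UTR-bearing universe — enrichment only, not depletion. The test is exact
and therefore conservative: its null p-values are super-uniform, and the
test suite checks uniformity on the mid-p corrected values while checking
the raw p only for absence of excess small values.

# Numerical and degenerate-input choices

Problem sizes throughout (12 loci, 96,000 reads, 600-gene universe,
five synthetic species) were chosen so a full run takes under a minute on
one CPU while every statistic of interest sits far from its decision
boundary at 3-sigma binomial noise. Folding windows are clipped at
chromosome ends; zero-locus configurations produce decoy-only libraries
and an empty (but valid) report; empty window sets and empty gene
universes are errors rather than silent zeros. All RNG is seeded from a
single configuration seed with fixed small offsets per stage, so every
artifact is byte-reproducible; identical configurations reproduce
identical FASTQ/FASTA/BED/TSV files.

# Known limitations

Pair-count structure detection cannot substitute for thermodynamic
folding on real genomes: its false-positive control here leans on the
read-level criteria (read depth, star strand, 5' precision) and on the
generator's designed stems. The adapter trimmer assumes the library
layout above and does not handle 5'-adapter read-through or quality-based
trimming. Homology searches are Hamming-based (no indels), as are
known-mature matches. The expression matrix counts mapped mature-arm
reads; untemplated-tail and substitution reads appear in isomiR profiles
but not in expression counts, a choice that affects absolute RPM slightly
but cancels in the sex-ratio and enrichment analyses.
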