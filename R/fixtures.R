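# Published reference tables of the zebra finch small-RNA study, transcribed
# as machine-readable fixtures so the analysis rules can be re-applied to
# the printed numbers.

#' Brain-enriched miRNAs: read counts and cross-species conservation
#'
#' The printed table of brain-enriched zebra finch miRNAs with their total
#' and brain read counts (sexes combined) and detection in human, mouse,
#' and Aplysia nervous tissue.
#'
#' @return Data.frame: mirna, total_reads, brain_reads, human, mouse,
#'   aplysia.
#' @export
table1_fixture <- function() {
  tab <- c(
    "miR-9",    357811, 354947, 1, 1, 0,
    "miR-124",  111628, 111170, 1, 1, 1,
    "miR-137",   28008,  27599, 1, 1, 1,
    "miR-153",   16599,  16188, 1, 0, 1,
    "miR-212",    8361,   8168, 0, 0, 0,
    "miR-135a",   7451,   7053, 0, 0, 0,
    "miR-219",    7228,   7198, 0, 0, 0,
    "miR-132",    6496,   6172, 0, 0, 0,
    "miR-34b",    6401,   6322, 0, 0, 1,
    "miR-129",    5909,   5535, 1, 0, 0,
    "miR-551",    4992,   4949, 0, 0, 0,
    "miR-218",    4221,   4024, 1, 1, 0,
    "miR-383",    3822,   3743, 0, 0, 0,
    "miR-34c",    3628,   3593, 0, 0, 0,
    "miR-460b",   1447,   1402, 0, 0, 0,
    "miR-458",    1013,    958, 0, 0, 0,
    "miR-138b",    386,    358, 1, 1, 0,
    "miR-1805",    306,    297, 0, 0, 0,
    "miR-489",     304,    285, 0, 0, 0,
    "miR-1803",    264,    261, 0, 0, 0)
  m <- matrix(tab, ncol = 6L, byrow = TRUE)
  data.frame(mirna = m[, 1L],
             total_reads = as.integer(m[, 2L]),
             brain_reads = as.integer(m[, 3L]),
             human = m[, 4L] == "1", mouse = m[, 5L] == "1",
             aplysia = m[, 6L] == "1", stringsAsFactors = FALSE)
}

#' miRNAs with internal substitutions at the GGU motif
#'
#' The printed table of miRNAs whose internal substitution site falls at
#' the uridine of a GGU motif: canonical sequences, substituted read
#' counts, and substitution percentages.
#'
#' @return Data.frame: mirna, canonical (RNA), modified_reads, percentage.
#' @export
table2_fixture <- function() {
  tab <- c(
    "tgu-let-7a",   "UGAGGUAGUAGGUUGUAUAGUU",   11500,  5.5,
    "tgu-let-7b",   "UGAGGUAGUAGGUUGUGUGGUU",    1629,  6.7,
    "tgu-let-7c",   "UGAGGUAGUAGGUUGUAUGGUU",    1556,  5.2,
    "tgu-let-7d",   "AGAGGUAGUAGGUUGCAUAGUU",     395,  5.5,
    "tgu-let-7e",   "UGAGGUAGUAGAUUGAAUAGUU",    3864,  5.2,
    "tgu-let-7f",   "UGAGGUAGUAGAUUGUAUAGUU",   12490,  5.1,
    "tgu-let-7i",   "UGAGGUAGUAGUUUGUGCUGUU",    3792,  8.2,
    "tgu-miR-122",  "UGGAGUGUGACAAUGGUGUUUG",    6211, 14.0,
    "tgu-miR-133b", "UUGGUCCCCUUCAACCAGCUAU",      18,  5.1,
    "tgu-miR-140",  "ACCACAGGGUAGAACCACGGAC",     674,  5.0,
    "tgu-miR-15a",  "UAGCAGCACAUAAUGGUUUGU",      382,  5.4,
    "tgu-miR-15c",  "UAGCAGCACAUCAUGGUUUGU",      187,  5.4,
    "tgu-miR-181b", "AACAUUCAUUGCUGUCGGUGGGU",    254,  6.2,
    "tgu-miR-183",  "UAUGGCACUGGUAGAAUUCACU",       5,  5.1,
    "tgu-miR-18a",  "UAAGGUGCAUCUAGUGCAGAUA",     228, 12.5,
    "tgu-miR-18b",  "UAAGGUGCAUCUAGUGCAGUU",        7,  5.0,
    "tgu-miR-196",  "UAGGUAGUUUCAUGUUGUUGGG",       8, 10.0,
    "tgu-miR-221",  "AGCUACAUUGUCUGCUGGGUUUC",   2636,  6.4,
    "tgu-miR-222",  "AGCUACAUCUGGCUACUGGGUCUC",  1413,  6.5,
    "tgu-miR-2970", "GACAGUCAGCAGUUGGUCUGG",      219, 11.7,
    "tgu-miR-363",  "AAUUGCACGGUAUCCAUCUGU",       83,  6.8,
    "tgu-miR-383",  "CAGAUCAGAAGGUGAUUGUGGC",     101,  7.3,
    "tgu-miR-456",  "CAGGCUGGUUAGAUGGUUGUC",       34,  7.8,
    "tgu-miR-458",  "AUAGCUCUUGGAAUGGUUCUGC",      31,  5.1,
    "tgu-miR-551",  "GCGACCCAUACUUGGUUUCAG",       69,  5.0)
  m <- matrix(tab, ncol = 4L, byrow = TRUE)
  data.frame(mirna = m[, 1L], canonical = m[, 2L],
             modified_reads = as.integer(m[, 3L]),
             percentage = as.numeric(m[, 4L]), stringsAsFactors = FALSE)
}

#' Printed repertoire summary counts
#'
#' Headline counts of the published repertoire used for contingency
#' arithmetic: repertoire size, conservation-group sizes, tissue-enrichment
#' counts, and the chicken/zebra finch miR-2954 target tallies.
#'
#' @return Named list of integers.
#' @export
repertoire_counts <- function() {
  list(n_mirnas = 193L,
       n_avian_specific = 29L,
       n_finch_specific = 19L,
       n_conserved_invertebrate = 37L,
       n_conserved_vertebrate = 103L,
       n_avian_mammal = 24L,
       n_single_tissue_enriched = 32L,
       n_brain_enriched = 20L,
       finch_targets_total = 100L,
       finch_targets_z = 27L,
       chicken_targets_total = 403L,
       chicken_targets_z = 70L)
}
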