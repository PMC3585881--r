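# Synthetic study generator: a toy genome carrying designed miRNA stem-loop
# loci plus tRNA/rRNA and repeat decoys, and multiplexed barcoded reads from
# a multi-tissue, two-sex library design with a fully known truth table.
#
# Design notes:
# * Precursors are built as perfect-complement stem-loops (two 22-nt arms
#   separated by a 10-nt loop), so foldability of every planted locus is
#   guaranteed by construction and discovery tests have deterministic truth.
# * The two templated bases immediately 3' of every mature end are fixed to
#   "CG", so simulated A/U tails are always untemplated.
# * Z-linked loci carry small expression weights relative to autosomal loci,
#   mirroring real libraries where sex-linked miRNAs are a minor fraction of
#   the pool; per-sample totals are then nearly sex-balanced and male:female
#   count ratios stay centred on the planted dosage factors.
# * Coordinates are 0-based half-open in BED/truth tables, 1-based inclusive
#   in report-facing structures.

SIM_TIER_CYCLE <- c("species-specific", "avian-specific", "avian+mammal",
                    "vertebrate", "pan-animal")

#' Configuration for the synthetic study generator
#'
#' Defaults encode the study conditions the pipeline is designed around:
#' eight libraries (brain/heart/liver/muscle x M/F), length variants at 25%
#' of miRNA reads with >80% of them 3' variants, untemplated tailing at 15%
#' split U:A about 2:1, an 8% substitution rate at planted GGU sites, a
#' 0.5% per-base sequencing error rate, ordinary Z-linked loci expressed at
#' a 2:1 male:female dosage, and one strongly male-biased Z locus (10x).
#'
#' @param seed Integer RNG seed; identical configurations give byte-identical
#'   outputs.
#' @param chrom_lens Named chromosome lengths (nt); must include `"chrZ"`.
#' @param n_mirna_loci Total planted miRNA loci (cluster members and Z loci
#'   included).
#' @param n_z_loci Loci placed on chrZ; the first is the designated
#'   male-biased ("miR-2954-like") locus when `male_biased_z` is TRUE.
#' @param male_biased_z Flag one Z locus as strongly male-biased.
#' @param cluster_spec List of `list(n=, spacing=)` genomic clusters placed
#'   on chr1; spacings are start-to-start and must be < 10000 nt.
#' @param tissues,sexes Sample labels; one library per (tissue, sex).
#' @param depth_per_sample Reads per library.
#' @param frac_len_variants Fraction of miRNA reads that are length variants.
#' @param frac_3p_among_len_variants Fraction of length variants at the 3'
#'   end.
#' @param frac_tailing Fraction of miRNA reads with an untemplated 3' tail.
#' @param tail_u_fraction U share among tails (remainder is A).
#' @param subst_site_rate Per-read substitution probability at a planted GGU
#'   site (loci with such a site only).
#' @param frac_star Fraction of miRNA reads drawn from the star strand.
#' @param frac_decoy Fraction of each library drawn from decoy (tRNA/rRNA/
#'   repeat) intervals.
#' @param seq_error_rate Per-base sequencing error rate on the full read.
#' @param male_bias_factor Male fold-excess for the male-biased Z locus.
#' @param z_dosage_factor Male fold-excess for ordinary Z loci.
#' @param n_subst_loci Autosomal loci carrying a planted GGU substitution
#'   site.
#' @param n_decoys Decoy intervals (half tRNA/rRNA, half repeat).
#' @param mature_len,loop_len Arm and loop lengths of planted precursors.
#' @param read_length Raw read length before trimming.
#' @param tissue_profiles Optional loci x tissues weight matrix; by default
#'   three autosomal loci are strongly single-tissue enriched (share 0.94)
#'   and the rest are flat.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lens = c(chr1 = 60000L, chr2 = 40000L,
                                      chrZ = 30000L),
                       n_mirna_loci = 12L,
                       n_z_loci = 3L,
                       male_biased_z = TRUE,
                       cluster_spec = list(list(n = 3L, spacing = 5000L)),
                       tissues = c("brain", "heart", "liver", "muscle"),
                       sexes = c("M", "F"),
                       depth_per_sample = 12000L,
                       frac_len_variants = 0.25,
                       frac_3p_among_len_variants = 0.8,
                       frac_tailing = 0.15,
                       tail_u_fraction = 2 / 3,
                       subst_site_rate = 0.08,
                       frac_star = 0.05,
                       frac_decoy = 0.04,
                       seq_error_rate = 0.005,
                       male_bias_factor = 10,
                       z_dosage_factor = 2,
                       n_subst_loci = 4L,
                       n_decoys = 6L,
                       mature_len = 22L,
                       loop_len = 10L,
                       read_length = 36L,
                       tissue_profiles = NULL) {
  cfg <- list(seed = as.integer(seed), chrom_lens = chrom_lens,
              n_mirna_loci = as.integer(n_mirna_loci),
              n_z_loci = as.integer(n_z_loci),
              male_biased_z = isTRUE(male_biased_z),
              cluster_spec = cluster_spec,
              tissues = tissues, sexes = sexes,
              depth_per_sample = as.integer(depth_per_sample),
              frac_len_variants = frac_len_variants,
              frac_3p_among_len_variants = frac_3p_among_len_variants,
              frac_tailing = frac_tailing,
              tail_u_fraction = tail_u_fraction,
              subst_site_rate = subst_site_rate,
              frac_star = frac_star, frac_decoy = frac_decoy,
              seq_error_rate = seq_error_rate,
              male_bias_factor = male_bias_factor,
              z_dosage_factor = z_dosage_factor,
              n_subst_loci = as.integer(n_subst_loci),
              n_decoys = as.integer(n_decoys),
              mature_len = as.integer(mature_len),
              loop_len = as.integer(loop_len),
              read_length = as.integer(read_length),
              tissue_profiles = tissue_profiles)
  fracs <- c(cfg$frac_len_variants, cfg$frac_3p_among_len_variants,
             cfg$frac_tailing, cfg$tail_u_fraction, cfg$subst_site_rate,
             cfg$frac_star, cfg$frac_decoy, cfg$seq_error_rate)
  if (any(fracs < 0 | fracs > 1)) stop("all fractions must lie in [0, 1]")
  tot <- cfg$frac_len_variants + cfg$frac_tailing + cfg$frac_star +
    cfg$subst_site_rate
  if (tot >= 1) stop("variant-class fractions must sum to less than 1")
  if (cfg$depth_per_sample <= 0) stop("depth_per_sample must be positive")
  if (abs(cfg$seed) > 2^31 - 100) stop("seed too large for a 32-bit integer")
  if (!"chrZ" %in% names(cfg$chrom_lens)) stop("chrom_lens must include chrZ")
  if (cfg$n_z_loci > cfg$n_mirna_loci)
    stop("n_z_loci cannot exceed n_mirna_loci")
  for (cl in cfg$cluster_spec) {
    if (cl$n < 2L) stop("clusters need at least two members")
    if (cl$spacing >= 10000L) stop("cluster spacing must be < 10000 nt")
  }
  n_in_clusters <- sum(vapply(cfg$cluster_spec, function(cl) cl$n, 0L))
  if (cfg$n_mirna_loci > 0L &&
      n_in_clusters + cfg$n_z_loci > cfg$n_mirna_loci)
    stop("cluster members plus Z loci exceed n_mirna_loci")
  structure(cfg, class = "sim_config")
}

# deterministic locus placement; errors if a chromosome cannot hold its loci
place_loci <- function(cfg) {
  prec_len <- 2L * cfg$mature_len + cfg$loop_len
  flank <- 200L
  placements <- list()
  add <- function(chrom, start0, in_cluster) {
    len <- cfg$chrom_lens[[chrom]]
    if (start0 < flank || start0 + prec_len + flank > len)
      stop("genome too short to hold all loci with 200 nt flanks")
    placements[[length(placements) + 1L]] <<-
      list(chrom = chrom, start0 = as.integer(start0), cluster = in_cluster)
  }
  if (cfg$n_mirna_loci == 0L) return(placements)
  n_in_clusters <- sum(vapply(cfg$cluster_spec, function(cl) cl$n, 0L))
  n_singles <- cfg$n_mirna_loci - cfg$n_z_loci - n_in_clusters
  autos <- setdiff(names(cfg$chrom_lens), "chrZ")
  if (length(autos) == 0L) stop("genome needs at least one autosome")
  cursor <- stats::setNames(rep(5000L, length(autos)), autos)
  ci <- 0L
  for (cl in cfg$cluster_spec) {
    ci <- ci + 1L
    first <- cursor[[autos[1L]]]
    for (k in seq_len(cl$n))
      add(autos[1L], first + (k - 1L) * cl$spacing, paste0("cl", ci))
    cursor[[autos[1L]]] <- first + (cl$n - 1L) * cl$spacing + 12000L
  }
  for (k in seq_len(max(n_singles, 0L))) {
    chrom <- autos[(k - 1L) %% length(autos) + 1L]
    add(chrom, cursor[[chrom]], NA_character_)
    cursor[[chrom]] <- cursor[[chrom]] + 12000L
  }
  zc <- 4000L
  for (k in seq_len(cfg$n_z_loci)) {
    add("chrZ", zc, NA_character_)
    zc <- zc + 11000L
  }
  placements
}

#' Generate the synthetic genome, planted loci, and decoy annotation
#'
#' Builds i.i.d. uniform background chromosomes, embeds designed stem-loop
#' precursors (perfect-complement arms) at deterministic, non-overlapping
#' coordinates, and lays down tRNA/rRNA and repeat decoy intervals. Every
#' planted mature sequence occurs verbatim at its recorded coordinates.
#'
#' @param cfg A [sim_config()].
#' @return A list with `genome` (a named [Biostrings::DNAStringSet]), `loci`
#'   (the locus truth table, 0-based half-open coordinates), `decoys`
#'   (decoy interval table with class labels), `known_ncrna` (the tRNA/rRNA
#'   decoy sequences as a `DNAStringSet`), and `cfg`.
#' @export
make_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_rng(cfg$seed, {
    chroms <- lapply(cfg$chrom_lens, random_dna)
    placements <- place_loci(cfg)
    n <- length(placements)
    ml <- cfg$mature_len
    ll <- cfg$loop_len
    prec_len <- 2L * ml + ll

    loci <- data.frame(
      name = sprintf("mir-sim-%02d", seq_len(max(n, 0L))),
      chrom = character(n), strand = rep("+", n),
      prec_start0 = integer(n), prec_end0 = integer(n),
      mat_start0 = integer(n), mat_end0 = integer(n),
      star_start0 = integer(n), star_end0 = integer(n),
      arm = character(n), mature = character(n), star = character(n),
      cluster = character(n), z_class = character(n),
      subst_pos = rep(NA_integer_, n), base_weight = numeric(n),
      stringsAsFactors = FALSE
    )

    z_idx <- which(vapply(placements, function(p) p$chrom == "chrZ", TRUE))
    auto_idx <- setdiff(seq_len(n), z_idx)
    subst_idx <- head(auto_idx, cfg$n_subst_loci)

    for (i in seq_len(n)) {
      p <- placements[[i]]
      mature <- random_dna(ml)
      if (i %in% subst_idx) {
        # plant a GGU motif whose U sits well inside the read (pos 12..14)
        substr(mature, 12L, 14L) <- "GGT"
        loci$subst_pos[i] <- 14L
      }
      arm <- if (i %% 2L == 1L) "5p" else "3p"
      loop <- random_dna(ll)
      if (arm == "5p") substr(loop, 1L, 2L) <- "CG"
      # the star arm carries two planted mismatches (real duplexes are not
      # perfect complements; this also keeps any single-error read from
      # recreating an exact antisense match of either arm)
      star <- revcomp(mature)
      for (mm_at in c(6L, 15L)) {
        partner <- substr(mature, ml - mm_at + 1L, ml - mm_at + 1L)
        pairs_with <- switch(partner, A = "T", C = "G", G = c("C", "T"),
                             T = c("A", "G"))
        choices <- setdiff(DNA_BASES,
                           c(pairs_with, substr(star, mm_at, mm_at)))
        substr(star, mm_at, mm_at) <- sample(choices, 1L)
      }
      prec <- if (arm == "5p") paste0(mature, loop, star)
              else paste0(star, loop, mature)
      s0 <- p$start0
      chroms[[p$chrom]] <- `substr<-`(chroms[[p$chrom]], s0 + 1L,
                                      s0 + prec_len, prec)
      if (arm == "3p") {
        # fix the two templated bases downstream of the mature 3' end
        chroms[[p$chrom]] <- `substr<-`(chroms[[p$chrom]], s0 + prec_len + 1L,
                                        s0 + prec_len + 2L, "CG")
      }
      mat_s0 <- if (arm == "5p") s0 else s0 + ml + ll
      star_s0 <- if (arm == "5p") s0 + ml + ll else s0
      loci$chrom[i] <- p$chrom
      loci$prec_start0[i] <- s0
      loci$prec_end0[i] <- s0 + prec_len
      loci$mat_start0[i] <- mat_s0
      loci$mat_end0[i] <- mat_s0 + ml
      loci$star_start0[i] <- star_s0
      loci$star_end0[i] <- star_s0 + ml
      loci$arm[i] <- arm
      loci$mature[i] <- mature
      loci$star[i] <- star
      loci$cluster[i] <- p$cluster
      loci$z_class[i] <- if (p$chrom != "chrZ") "autosomal"
        else if (cfg$male_biased_z && i == z_idx[1L]) "Z-male-biased" else "Z"
      loci$base_weight[i] <- switch(loci$z_class[i],
                                    autosomal = 1, Z = 0.05,
                                    `Z-male-biased` = 0.02)
    }
    if (n > 0L) {
      gr <- GenomicRanges::GRanges(loci$chrom,
                                   IRanges::IRanges(loci$prec_start0 + 1L,
                                                    loci$prec_end0))
      if (any(GenomicRanges::countOverlaps(gr, gr) > 1L))
        stop("planted loci overlap")
    }

    # decoy intervals at the tail end of chr1/chr2, clear of planted loci
    nd <- cfg$n_decoys
    decoys <- data.frame(name = character(0), chrom = character(0),
                         start0 = integer(0), end0 = integer(0),
                         class = character(0), stringsAsFactors = FALSE)
    if (nd > 0L) {
      autos <- setdiff(names(cfg$chrom_lens), "chrZ")
      if (length(autos) == 0L) autos <- names(cfg$chrom_lens)
      dchrom <- rep(autos, length.out = nd)
      dclass <- rep(c("tRNA", "rRNA", "repeat"), length.out = nd)
      dstart <- integer(nd)
      off <- c(chr1 = 0L, chr2 = 0L)
      for (k in seq_len(nd)) {
        ch <- dchrom[k]
        dstart[k] <- cfg$chrom_lens[[ch]] - 400L - off[[ch]]
        off[[ch]] <- off[[ch]] + 120L
      }
      decoys <- data.frame(
        name = sprintf("%s-decoy-%d", dclass, seq_len(nd)),
        chrom = dchrom, start0 = dstart, end0 = dstart + 80L,
        class = dclass, stringsAsFactors = FALSE)
    }

    genome <- Biostrings::DNAStringSet(unlist(chroms))
    names(genome) <- names(cfg$chrom_lens)
    ncr <- decoys[decoys$class %in% c("tRNA", "rRNA"), , drop = FALSE]
    known_ncrna <- Biostrings::DNAStringSet(
      vapply(seq_len(nrow(ncr)),
             function(k) chrom_sub(genome, ncr$chrom[k], ncr$start0[k] + 1L,
                                   ncr$end0[k]),
             character(1)))
    names(known_ncrna) <- ncr$name
    list(genome = genome, loci = loci, decoys = decoys,
         known_ncrna = known_ncrna, cfg = cfg)
  })
}

# loci x tissues expression weights (before sex factors)
sim_weights <- function(cfg, loci) {
  n <- nrow(loci)
  nt <- length(cfg$tissues)
  if (!is.null(cfg$tissue_profiles)) {
    prof <- cfg$tissue_profiles
    stopifnot(nrow(prof) == n, ncol(prof) == nt)
  } else {
    prof <- matrix(1 / nt, n, nt, dimnames = list(loci$name, cfg$tissues))
    auto <- which(loci$z_class == "autosomal")
    enriched <- head(auto, min(3L, length(auto), nt))
    for (k in seq_along(enriched)) {
      prof[enriched[k], ] <- 0.06 / (nt - 1)
      prof[enriched[k], k] <- 0.94
    }
  }
  prof * loci$base_weight
}

sample_barcodes <- function(samples) {
  pool <- c("AAACC", "AACGG", "ACTGA", "AGGTT", "CATCC", "CCAGT",
            "CGTAA", "CTTGG", "GAACT", "GCATG", "GGTAC", "GTCCA",
            "TACAG", "TCGGA", "TGACC", "TTGCA")
  if (length(samples) > length(pool)) stop("too many samples for barcode pool")
  stats::setNames(samples, pool[seq_along(samples)])
}

#' Generate multiplexed barcoded reads with a read-level truth table
#'
#' Draws reads per library from the planted loci (canonical, 5'/3' length
#' variants, untemplated A/U tails, planted-site substitutions, star strand)
#' and decoy intervals, injects per-base sequencing errors, and assembles
#' raw reads as insert + pentamer barcode + 3' adapter, truncated to the
#' configured read length. Expected male:female count ratios equal the
#' configured dosage factors for Z-linked loci.
#'
#' @param cfg A [sim_config()].
#' @param sim The output of [make_genome()] for the same configuration.
#' @return A list with `reads` (data.frame: read_id, seq, sample), `truth`
#'   (one row per read: sample, source, locus, class, shifts, tail,
#'   substitution position/base, error count), and `barcodes` (named vector
#'   barcode -> sample label).
#' @export
make_reads <- function(cfg, sim) {
  stopifnot(inherits(cfg, "sim_config"))
  loci <- sim$loci
  genome <- sim$genome
  samples <- as.vector(outer(cfg$tissues, cfg$sexes, paste, sep = "_"))
  barcodes <- sample_barcodes(samples)
  if (anyDuplicated(names(barcodes))) stop("barcode collision")
  adapter <- library_adapters()$adapter3

  w <- if (nrow(loci) > 0L) sim_weights(cfg, loci) else NULL
  chrom_strs <- stats::setNames(as.character(genome), names(genome))

  block <- function(n, sample, locus, class, insert, tail = NA_character_,
                    shift5 = 0L, shift3 = 0L, subst_pos = NA_integer_,
                    alt = NA_character_, source = "mirna") {
    if (n == 0L) return(NULL)
    data.frame(sample = sample, source = source, locus = locus,
               class = class, tail = tail, shift5 = shift5, shift3 = shift3,
               subst_pos = subst_pos, alt = alt, insert = insert,
               stringsAsFactors = FALSE)
  }

  with_rng(cfg$seed + 1L, {
    out <- list()
    for (si in seq_along(samples)) {
      smp <- samples[si]
      tissue <- sub("_[^_]*$", "", smp)
      sex <- sub("^.*_", "", smp)
      D <- cfg$depth_per_sample
      n_dec <- if (nrow(sim$decoys) == 0L) 0L
        else if (nrow(loci) == 0L) D  # no miRNA loci: all reads are decoys
        else rbinom(1L, D, cfg$frac_decoy)
      n_mir <- D - n_dec

      if (n_mir > 0L && nrow(loci) > 0L) {
        sexfac <- ifelse(loci$z_class == "autosomal", 1,
                         ifelse(loci$z_class == "Z", cfg$z_dosage_factor,
                                cfg$male_bias_factor))
        if (sex != "M") sexfac <- rep(1, nrow(loci))
        lw <- w[, tissue] * sexfac
        counts <- as.vector(rmultinom(1L, n_mir, lw))
        for (li in which(counts > 0L)) {
          lc <- loci[li, ]
          cs <- chrom_strs[[lc$chrom]]
          p_sub <- if (is.na(lc$subst_pos)) 0 else cfg$subst_site_rate
          probs <- c(
            canonical = 1 - cfg$frac_len_variants - cfg$frac_tailing -
              cfg$frac_star - p_sub,
            len5 = cfg$frac_len_variants * (1 - cfg$frac_3p_among_len_variants),
            len3 = cfg$frac_len_variants * cfg$frac_3p_among_len_variants,
            tailU = cfg$frac_tailing * cfg$tail_u_fraction,
            tailA = cfg$frac_tailing * (1 - cfg$tail_u_fraction),
            subst = p_sub,
            star = cfg$frac_star)
          ncl <- as.vector(rmultinom(1L, counts[li], probs))
          names(ncl) <- names(probs)
          s1 <- lc$mat_start0 + 1L
          e1 <- lc$mat_end0
          d5 <- sample(c(-3:-1, 1:3), ncl[["len5"]], replace = TRUE)
          d3 <- sample(c(-3:-1, 1:3), ncl[["len3"]], replace = TRUE)
          tu <- strrep("T", sample(1:2, ncl[["tailU"]], replace = TRUE))
          ta <- strrep("A", sample(1:2, ncl[["tailA"]], replace = TRUE))
          alt <- if (ncl[["subst"]] > 0L)
            sample(setdiff(DNA_BASES,
                           substr(lc$mature, lc$subst_pos, lc$subst_pos)),
                   ncl[["subst"]], replace = TRUE) else character(0)
          out[[length(out) + 1L]] <- rbind(
            block(ncl[["canonical"]], smp, lc$name, "canonical",
                  rep(lc$mature, ncl[["canonical"]])),
            block(ncl[["len5"]], smp, lc$name, "len5",
                  substring(cs, s1 + d5, e1), shift5 = d5),
            block(ncl[["len3"]], smp, lc$name, "len3",
                  substring(cs, s1, e1 + d3), shift3 = d3),
            block(ncl[["tailU"]], smp, lc$name, "tail",
                  paste0(lc$mature, tu), tail = tu),
            block(ncl[["tailA"]], smp, lc$name, "tail",
                  paste0(lc$mature, ta), tail = ta),
            block(ncl[["subst"]], smp, lc$name, "subst",
                  paste0(substr(lc$mature, 1L, lc$subst_pos - 1L), alt,
                         substr(lc$mature, lc$subst_pos + 1L,
                                nchar(lc$mature))),
                  subst_pos = lc$subst_pos, alt = alt),
            block(ncl[["star"]], smp, lc$name, "star",
                  rep(lc$star, ncl[["star"]])))
        }
      }
      if (n_dec > 0L) {
        di <- sample(nrow(sim$decoys), n_dec, replace = TRUE)
        len <- sample(18:25, n_dec, replace = TRUE)
        d <- sim$decoys[di, , drop = FALSE]
        st <- d$start0 + floor(runif(n_dec) * (d$end0 - d$start0 - len + 1L))
        out[[length(out) + 1L]] <- block(
          n_dec, smp, d$name, "decoy",
          substring(chrom_strs[d$chrom], st + 1L, st + len),
          source = "decoy")
      }
    }

    truth <- do.call(rbind, out)
    if (is.null(truth))
      truth <- block(1L, "x", "x", "x", "x")[0L, , drop = FALSE]
    inserts <- truth$insert

    # assemble raw reads and inject sequencing errors over the full read
    bc <- names(barcodes)[match(truth$sample, barcodes)]
    raw <- substr(paste0(inserts, bc, adapter), 1L, cfg$read_length)
    n_err <- rbinom(length(raw), nchar(raw), cfg$seq_error_rate)
    for (ri in which(n_err > 0L)) {
      pos <- sample(nchar(raw[ri]), n_err[ri])
      for (p in pos) {
        cur <- substr(raw[ri], p, p)
        substr(raw[ri], p, p) <- sample(setdiff(DNA_BASES, cur), 1L)
      }
    }
    truth$n_errors <- n_err

    ord <- sample(length(raw))  # interleave libraries in the multiplexed file
    truth <- truth[ord, , drop = FALSE]
    raw <- raw[ord]
    truth$read_id <- sprintf("r%07d", seq_along(raw))
    rownames(truth) <- NULL
    reads <- data.frame(read_id = truth$read_id, seq = raw,
                        sample = truth$sample, stringsAsFactors = FALSE)
    list(reads = reads, truth = truth, barcodes = barcodes)
  })
}

#' Known-mature reference set from the planted truth
#'
#' @param sim Output of [make_genome()].
#' @return A named [Biostrings::DNAStringSet] of the planted mature
#'   sequences (stands in for a species miRBase extract).
#' @export
sim_known_matures <- function(sim) {
  x <- Biostrings::DNAStringSet(sim$loci$mature)
  names(x) <- sim$loci$name
  x
}

#' Synthetic 3' UTR set with planted seed-match targets
#'
#' Generates a gene universe with chromosome assignments and random 3' UTRs,
#' then plants perfect seed matches (reverse complement of mature positions
#' 2-8) for the male-biased Z locus with a strong chrZ bias, and for the
#' first ordinary Z locus uniformly (no bias), so both a positive and a null
#' chromosomal enrichment are available with known truth.
#'
#' @param cfg A [sim_config()].
#' @param sim Output of [make_genome()].
#' @param n_genes Gene universe size.
#' @param frac_z Fraction of genes on chrZ.
#' @param n_biased_z,n_biased_auto Planted targets of the male-biased locus
#'   on chrZ / autosomes.
#' @param n_unbiased Planted targets of the ordinary Z locus, placed without
#'   regard to chromosome.
#' @return A list: `utrs` (data.frame gene/chrom/utr), `planted` (named list
#'   of planted target gene sets per locus name).
#' @export
sim_utrs <- function(cfg, sim, n_genes = 600L, frac_z = 0.12,
                     n_biased_z = 30L, n_biased_auto = 25L,
                     n_unbiased = 40L) {
  loci <- sim$loci
  with_rng(cfg$seed + 2L, {
    chrom <- sample(c("chr1", "chr2", "chrZ"), n_genes, replace = TRUE,
                    prob = c((1 - frac_z) / 2, (1 - frac_z) / 2, frac_z))
    lens <- sample(150:400, n_genes, replace = TRUE)
    utr <- vapply(lens, random_dna, character(1))
    utrs <- data.frame(gene = sprintf("g%04d", seq_len(n_genes)),
                       chrom = chrom, utr = utr, stringsAsFactors = FALSE)
    planted <- list()
    plant <- function(mature, genes) {
      site <- revcomp(substr(as_dna(mature), 2L, 8L))
      for (g in genes) {
        i <- match(g, utrs$gene)
        p <- sample(nchar(utrs$utr[i]) - 7L, 1L)
        substr(utrs$utr[i], p, p + 6L) <<- site
      }
      genes
    }
    biased <- loci$name[loci$z_class == "Z-male-biased"]
    if (length(biased) == 1L) {
      zg <- sample(utrs$gene[utrs$chrom == "chrZ"], n_biased_z)
      ag <- sample(utrs$gene[utrs$chrom != "chrZ"], n_biased_auto)
      planted[[biased]] <- plant(loci$mature[loci$name == biased], c(zg, ag))
    }
    ordz <- loci$name[loci$z_class == "Z"]
    if (length(ordz) >= 1L) {
      gg <- sample(utrs$gene, n_unbiased)
      planted[[ordz[1L]]] <- plant(loci$mature[loci$name == ordz[1L]], gg)
    }
    list(utrs = utrs, planted = planted)
  })
}

#' Synthetic cross-species sequence sets for conservation analysis
#'
#' Assigns each planted locus a conservation tier (the male-biased Z locus
#' is fixed avian-specific; the rest cycle through the tiers), then emits
#' one synthetic "genome" per species in which loci conserved at that level
#' carry their full foldable precursor. One species-specific locus is
#' additionally planted in the avian genome as mature-only (no complement
#' arm), exercising the rule that mature-only hits do not count as homologs.
#'
#' @param cfg A [sim_config()].
#' @param sim Output of [make_genome()].
#' @return A list: `species` (named list of single-sequence
#'   [Biostrings::DNAStringSet]s), `groups` (species group membership used
#'   by [assign_tier()]), `tiers` (truth data.frame name/tier).
#' @export
sim_species_sets <- function(cfg, sim) {
  loci <- sim$loci
  species <- c("chicken", "human", "mouse", "zebrafish", "fly")
  groups <- list(avian = "chicken", mammal = c("human", "mouse"),
                 vertebrate_other = "zebrafish", invertebrate = "fly")
  tier_species <- list(
    "species-specific" = character(0),
    "avian-specific" = "chicken",
    "avian+mammal" = c("chicken", "human", "mouse"),
    "vertebrate" = c("chicken", "human", "mouse", "zebrafish"),
    "pan-animal" = species)
  n <- nrow(loci)
  tiers <- rep(SIM_TIER_CYCLE, length.out = n)
  tiers[loci$z_class == "Z-male-biased"] <- "avian-specific"
  with_rng(cfg$seed + 3L, {
    blocks <- stats::setNames(vector("list", length(species)), species)
    prec_of <- function(i) chrom_sub(sim$genome, loci$chrom[i],
                                     loci$prec_start0[i] + 1L,
                                     loci$prec_end0[i])
    for (i in seq_len(n)) {
      for (sp in tier_species[[tiers[i]]]) {
        blocks[[sp]] <- c(blocks[[sp]],
                          paste0(random_dna(150L), prec_of(i),
                                 random_dna(150L)))
      }
    }
    sp_specific <- which(tiers == "species-specific")
    if (length(sp_specific) >= 1L) {
      i <- sp_specific[1L]
      blocks[["chicken"]] <- c(blocks[["chicken"]],
                               paste0(random_dna(150L), loci$mature[i],
                                      random_dna(150L)))
    }
    seqs <- lapply(species, function(sp) {
      x <- Biostrings::DNAStringSet(paste(c(blocks[[sp]], random_dna(400L)),
                                          collapse = ""))
      names(x) <- sp
      x
    })
    names(seqs) <- species
    list(species = seqs, groups = groups,
         tiers = data.frame(name = loci$name, tier = tiers,
                            stringsAsFactors = FALSE))
  })
}

#' Write the synthetic genome bundle to disk
#'
#' Emits `genome.fa`, `loci.bed` and `annotation.bed` (BED6, 0-based
#' half-open), `known_ncrna.fa`, and `truth_loci.tsv` under `dir`.
#'
#' @param sim Output of [make_genome()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
sim_write_genome <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  loci <- sim$loci
  if (nrow(loci) > 0L) {
    gr <- GenomicRanges::GRanges(loci$chrom,
                                 IRanges::IRanges(loci$prec_start0 + 1L,
                                                  loci$prec_end0),
                                 strand = loci$strand, name = loci$name,
                                 score = 0L)
  } else {
    gr <- GenomicRanges::GRanges()
  }
  rtracklayer::export(gr, file.path(dir, "loci.bed"), format = "BED")
  dec <- sim$decoys
  if (nrow(dec) > 0L) {
    dgr <- GenomicRanges::GRanges(dec$chrom,
                                  IRanges::IRanges(dec$start0 + 1L, dec$end0),
                                  strand = "+", name = dec$name, score = 0L)
  } else {
    dgr <- GenomicRanges::GRanges()
  }
  rtracklayer::export(dgr, file.path(dir, "annotation.bed"), format = "BED")
  Biostrings::writeXStringSet(sim$known_ncrna,
                              file.path(dir, "known_ncrna.fa"))
  write.table(loci, file.path(dir, "truth_loci.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write the multiplexed reads bundle to disk
#'
#' Emits `reads.fastq` (Phred+33, constant "I" qualities), `barcodes.tsv`,
#' and `truth_reads.tsv` under `dir`.
#'
#' @param rd Output of [make_reads()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
sim_write_reads <- function(rd, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sr <- Biostrings::DNAStringSet(rd$reads$seq)
  names(sr) <- rd$reads$read_id
  quals <- Biostrings::BStringSet(strrep("I", nchar(rd$reads$seq)))
  Biostrings::writeXStringSet(sr, file.path(dir, "reads.fastq"),
                              format = "fastq", qualities = quals)
  write.table(data.frame(barcode = names(rd$barcodes),
                         sample = unname(rd$barcodes)),
              file.path(dir, "barcodes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(rd$truth, file.path(dir, "truth_reads.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
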