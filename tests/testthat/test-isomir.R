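canonical <- "TGAGGTAGTAGGTTGTATAGTT"   # 22 nt
up <- "ACGA"
down <- "CGACCA"                        # next templated base is C

test_that("read classification covers the variant taxonomy", {
  cl <- function(read) classify_read(read, canonical, up, down)
  expect_equal(cl(canonical)$class, "canonical")

  # untemplated tails: added base differs from the templated C
  expect_equal(cl(paste0(canonical, "T"))$class, "tail-U")
  expect_equal(cl(paste0(canonical, "AA"))$class, "tail-A")
  expect_equal(cl(paste0(canonical, "G"))$class, "tail-other")
  # a templated extension is a 3' length variant, not a tail
  r <- cl(paste0(canonical, "C"))
  expect_equal(r$class, "len3")
  expect_equal(r$shift3, 1L)

  # 5' start shifted 1 nt in the 3' direction, genome-templated
  r5 <- cl(substr(canonical, 2L, 22L))
  expect_equal(r5$class, "len5")
  expect_equal(r5$shift5, 1L)
  # 5' extension into the upstream template
  rext <- cl(paste0("A", canonical))
  expect_equal(rext$class, "len5")
  expect_equal(rext$shift5, -1L)

  # trimmed body plus an untemplated base: the tail takes precedence
  trimmed <- substr(canonical, 1L, 21L)  # ends ...AGT
  rt <- cl(paste0(trimmed, "A"))
  expect_equal(rt$class, "tail-A")
  expect_equal(rt$shift3, -1L)

  # single internal mismatch
  sub <- canonical
  substr(sub, 15L, 15L) <- "C"
  rs <- cl(sub)
  expect_equal(rs$class, "subst")
  expect_equal(rs$subst_pos, 15L)
  expect_equal(rs$alt, "C")

  # unalignable read
  expect_equal(cl("GGGGGGGGGGGGGGGGGGGGGG")$class, "unclassified")
})

make_profile <- function(total, subst_reads, pos, alt = "G",
                         canonical_rna = "UAUCACAGCCAGCUAUGAAGGC") {
  L <- nchar(canonical_rna)
  subst <- matrix(0, 4L, L, dimnames = list(c("A", "C", "G", "U"), NULL))
  subst[alt, pos] <- subst_reads
  structure(list(name = "mir-t", canonical = canonical_rna, arm = "5p",
                 class_counts = c(canonical = total - subst_reads,
                                  len5 = 0, len3 = 0, `both-ends` = 0,
                                  `tail-U` = 0, `tail-A` = 0,
                                  `tail-other` = 0, subst = subst_reads),
                 subst = subst, total = total),
            class = "isomir_profile")
}

test_that("substitution sites respect rate, depth, and position rules", {
  # A-to-G at position 15, 9% of 1000 reads: called, putative editing
  p <- make_profile(1000, 90, 15L)
  s <- call_sites(p)
  expect_equal(nrow(s), 1L)
  expect_equal(s$position, 15L)
  expect_equal(s$rate, 0.09)
  expect_true(s$putative_editing)
  expect_lt(s$p_error, 1e-10)

  # below the 5% rate
  expect_equal(nrow(call_sites(make_profile(1000, 40, 15L))), 0L)
  # too few total reads (100 is not > 100)
  expect_equal(nrow(call_sites(make_profile(90, 10, 15L))), 0L)
  expect_equal(nrow(call_sites(make_profile(100, 10, 15L))), 0L)
  # terminal positions are never called
  expect_equal(nrow(call_sites(make_profile(1000, 90, 1L))), 0L)
  expect_equal(nrow(call_sites(make_profile(1000, 90, 22L))), 0L)
})

test_that("motif windows put the substituted base at position 3", {
  mir122 <- "UGGAGUGUGACAAUGGUGUUUG"
  sites <- data.frame(mirna = c("mir-122", "mir-122", "mir-122"),
                      position = c(17L, 10L, 2L),
                      stringsAsFactors = FALSE)
  mw <- motif_windows(sites, c("mir-122" = mir122))
  expect_equal(nrow(mw$windows), 2L)
  w17 <- mw$windows[mw$windows$position == 17L, ]
  expect_equal(w17$window, "GGUGUU")
  expect_true(w17$in_GGU)                  # reference triplet 15-17 is GGU
  w10 <- mw$windows[mw$windows$position == 10L, ]
  expect_false(w10$in_GGU)                 # preceding context is not GG
  expect_equal(mw$dropped, 1L)             # position 2: no 5' context
})

test_that("information content follows the closed forms", {
  expect_equal(information_content(rep("GGGGGG", 8L))$ic, rep(2, 6L))
  unif <- c("AAAAAA", "CCCCCC", "GGGGGG", "UUUUUU")
  expect_equal(information_content(unif)$ic, rep(0, 6L))
  half <- c("GGGGGG", "UUUUUU")
  expect_equal(information_content(half)$ic, rep(1, 6L))
  expect_error(information_content(character(0)), "empty")

  set.seed(61)
  ws <- replicate(50, paste(sample(c("A", "C", "G", "U"), 6L, TRUE),
                            collapse = ""))
  ic <- information_content(ws)$ic
  expect_true(all(ic >= 0 & ic <= 2))
})

test_that("tailing summary reproduces the extended-read ratio pattern", {
  p1 <- make_profile(800, 0, 15L)
  p1$class_counts["tail-U"] <- 700
  p1$class_counts["canonical"] <- 100
  p1$name <- "mir-456-like"
  out <- tailing_summary(list(p1))
  expect_equal(out$per_mirna$extended_ratio, 7)
  expect_equal(out$n_U_mirnas, 1L)
  expect_equal(out$n_A_mirnas, 0L)

  # no tailing at all
  empty <- tailing_summary(list(make_profile(500, 0, 15L)))
  expect_equal(empty$n_tailed, 0L)
})

test_that("profiles partition assigned reads and recover planted rates", {
  res <- small_run()
  cfg <- small_cfg()
  for (p in res$profiles) {
    expect_equal(sum(p$class_counts), p$total)
    expect_equal(sum(p$per_sample), p$total)
  }
  # U:A tail ratio across profiles within 3 SE of the planted 2:1
  tails <- tailing_summary(res$profiles)$per_mirna
  u <- sum(tails$tail_U); a <- sum(tails$tail_A)
  p_u <- cfg$tail_u_fraction
  expect_lt(abs(u / (u + a) - p_u), 3 * sqrt(p_u * (1 - p_u) / (u + a)))
  # every planted GGU site is recovered at the planted position
  planted <- res$sim$loci[!is.na(res$sim$loci$subst_pos), ]
  expect_gt(nrow(planted), 0L)
  planted_seqs <- gsub("T", "U", planted$mature)
  called <- res$sites
  for (i in seq_len(nrow(planted))) {
    rec <- res$records[res$records$sequence == planted_seqs[i], ]
    hit <- called[called$mirna == rec$name, ]
    expect_equal(hit$position, planted$subst_pos[i])
    expect_true(hit$in_GGU)
  }
})

test_that("the 5% rule is sharp at planted rates of 4% and 8%", {
  base <- function(rate, seed) {
    cfg <- sim_config(seed = seed, n_mirna_loci = 2L, n_z_loci = 0L,
                      cluster_spec = list(), n_subst_loci = 1L,
                      depth_per_sample = 1250L,  # 10000 reads over 8 libraries
                      subst_site_rate = rate,
                      chrom_lens = c(chr1 = 40000L, chrZ = 5000L))
    sim <- make_genome(cfg)
    rd <- make_reads(cfg, sim)
    td <- trim_and_demux(rd$reads, rd$barcodes)
    collapsed <- drop_orphans(td$collapsed)
    map <- map_exact(collapsed, sim$genome)
    classified <- classify_reads(map, repeats = sim$decoys,
                                 known_ncrna = sim$known_ncrna)
    rec <- call_candidates(collapsed, classified, map, sim$genome,
                           known_matures = sim_known_matures(sim))
    prof <- isomir_profiles(rec, collapsed, sim$genome, classified)
    sites <- do.call(rbind, lapply(prof, call_sites))
    planted <- sim$loci$name[!is.na(sim$loci$subst_pos)]
    list(sites = sites, planted = planted)
  }
  hi <- base(0.08, 67L)
  expect_true(any(hi$sites$mirna %in% hi$planted &
                    hi$sites$position == 14L))
  lo <- base(0.04, 67L)
  expect_true(is.null(lo$sites) || nrow(lo$sites) == 0L)
})
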