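test_that("generator is reproducible byte for byte", {
  cfg <- sim_config(seed = 9L, n_mirna_loci = 4L, n_z_loci = 1L,
                    cluster_spec = list(), depth_per_sample = 400L)
  s1 <- make_genome(cfg)
  s2 <- make_genome(cfg)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$loci, s2$loci)
  r1 <- make_reads(cfg, s1)
  r2 <- make_reads(cfg, s2)
  expect_identical(r1$reads, r2$reads)
  expect_identical(r1$truth, r2$truth)

  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  sim_write_genome(s1, d1); sim_write_genome(s2, d2)
  sim_write_reads(r1, d1); sim_write_reads(r2, d2)
  for (f in c("genome.fa", "loci.bed", "annotation.bed", "reads.fastq",
              "truth_reads.tsv")) {
    expect_identical(readBin(file.path(d1, f), "raw", 2e6),
                     readBin(file.path(d2, f), "raw", 2e6), label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("zero-locus configuration yields background and decoys only", {
  cfg <- sim_config(seed = 3L, n_mirna_loci = 0L, n_z_loci = 0L,
                    cluster_spec = list(), depth_per_sample = 200L)
  sim <- make_genome(cfg)
  expect_equal(nrow(sim$loci), 0L)
  expect_gt(nrow(sim$decoys), 0L)
  rd <- make_reads(cfg, sim)
  expect_true(all(rd$truth$source == "decoy"))
})

test_that("read counts are conserved and every read has one truth row", {
  cfg <- sim_config(seed = 5L, n_mirna_loci = 4L, n_z_loci = 1L,
                    cluster_spec = list(), depth_per_sample = 1000L)
  sim <- make_genome(cfg)
  rd <- make_reads(cfg, sim)
  n_samples <- length(cfg$tissues) * length(cfg$sexes)
  expect_equal(nrow(rd$reads), 1000L * n_samples)
  expect_equal(nrow(rd$truth), nrow(rd$reads))
  expect_identical(rd$truth$read_id, rd$reads$read_id)
  expect_equal(as.vector(table(rd$truth$sample)),
               rep(1000L, n_samples))
})

test_that("planted sequences are templated and tails are not", {
  sim <- make_genome(sim_config(seed = 11L))
  for (i in seq_len(nrow(sim$loci))) {
    l <- sim$loci[i, ]
    chrom <- as.character(sim$genome[[l$chrom]])
    expect_identical(substr(chrom, l$mat_start0 + 1L, l$mat_end0), l$mature)
    expect_identical(substr(chrom, l$star_start0 + 1L, l$star_end0), l$star)
    # the two templated bases downstream of the mature 3' end never match
    # a simulated A or U tail base
    nxt <- substr(chrom, l$mat_end0 + 1L, l$mat_end0 + 2L)
    expect_false(grepl("[AT]", nxt))
  }
})

test_that("variant-class frequencies converge to the configured rates", {
  cfg <- sim_config(seed = 13L, depth_per_sample = 12000L)
  sim <- make_genome(cfg)
  rd <- make_reads(cfg, sim)
  tr <- rd$truth[rd$truth$source == "mirna", ]
  n <- nrow(tr)
  within3se <- function(obs_frac, p, n) {
    abs(obs_frac - p) < 3 * sqrt(p * (1 - p) / n)
  }
  expect_true(within3se(mean(tr$class %in% c("len5", "len3")),
                        cfg$frac_len_variants, n))
  len <- tr[tr$class %in% c("len5", "len3"), ]
  expect_true(within3se(mean(len$class == "len3"),
                        cfg$frac_3p_among_len_variants, nrow(len)))
  expect_true(within3se(mean(tr$class == "tail"), cfg$frac_tailing, n))
  tails <- tr$tail[tr$class == "tail"]
  expect_true(within3se(mean(grepl("^T+$", tails)), cfg$tail_u_fraction,
                        length(tails)))
  expect_true(within3se(mean(tr$class == "star"), cfg$frac_star, n))
})

test_that("male:female read ratios track the planted dosage factors", {
  cfg <- sim_config(seed = 17L)
  sim <- make_genome(cfg)
  rd <- make_reads(cfg, sim)
  tr <- rd$truth[rd$truth$source == "mirna", ]
  tr$sex <- sub("^.*_", "", tr$sample)
  for (zc in c("Z", "Z-male-biased")) {
    for (nm in sim$loci$name[sim$loci$z_class == zc]) {
      m <- sum(tr$locus == nm & tr$sex == "M")
      f <- sum(tr$locus == nm & tr$sex == "F")
      fac <- if (zc == "Z") cfg$z_dosage_factor else cfg$male_bias_factor
      p <- fac / (fac + 1)
      se <- sqrt(p * (1 - p) / (m + f))
      expect_lt(abs(m / (m + f) - p), 3.5 * se + 0.01,
                label = sprintf("%s (%s)", nm, zc))
    }
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(frac_tailing = 1.2), "fractions")
  expect_error(sim_config(depth_per_sample = 0), "depth")
  expect_error(sim_config(cluster_spec = list(list(n = 2, spacing = 12000))),
               "spacing")
  expect_error(sim_config(n_mirna_loci = 2, n_z_loci = 3), "exceed")
  expect_error(make_genome(sim_config(chrom_lens = c(chr1 = 2000L,
                                                     chrZ = 1000L))),
               "too short")
})
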