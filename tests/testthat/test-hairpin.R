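# candidate calling on a constructed one-locus genome
cand_setup <- function(mature_n = 12L, star_n = 2L, extra = NULL) {
  sim <- one_locus_sim()
  l <- sim$loci[1L, ]
  seqs <- c(l$mature, l$star)
  counts <- c(mature_n, star_n)
  if (!is.null(extra)) {
    seqs <- c(seqs, extra$seq)
    counts <- c(counts, extra$n)
  }
  keep <- counts > 0L
  collapsed <- make_collapsed(seqs[keep], brain_M = counts[keep])
  map <- map_exact(collapsed, sim$genome)
  classified <- classify_reads(map, repeats = sim$decoys,
                               known_ncrna = sim$known_ncrna)
  list(sim = sim, collapsed = collapsed, map = map,
       classified = classified)
}

test_that("a locus meeting all four criteria is called as novel", {
  s <- cand_setup(mature_n = 12L, star_n = 2L)
  rec <- call_candidates(s$collapsed, s$classified, s$map, s$sim$genome)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$status, "novel")
  expect_equal(rec$sequence, gsub("T", "U", s$sim$loci$mature))
  expect_equal(rec$arm, s$sim$loci$arm)
  expect_equal(rec$star_count, 2L)
})

test_that("read support below the threshold rejects the locus", {
  s <- cand_setup(mature_n = 6L, star_n = 2L)  # total 8 <= 10
  rec <- call_candidates(s$collapsed, s$classified, s$map, s$sim$genome)
  expect_equal(nrow(rec), 0L)
  # acceptance is monotone in read count: scaling counts up never revokes
  s2 <- cand_setup(mature_n = 60L, star_n = 20L)
  rec2 <- call_candidates(s2$collapsed, s2$classified, s2$map,
                          s2$sim$genome)
  expect_equal(rec2$status, "novel")
})

test_that("a missing star or imprecise 5' end rejects a novel locus", {
  s <- cand_setup(mature_n = 30L, star_n = 0L)
  rec <- call_candidates(s$collapsed, s$classified, s$map, s$sim$genome)
  expect_equal(nrow(rec), 0L)

  # an abundant 5'-shifted isoform breaks criterion 4
  sim <- one_locus_sim()
  l <- sim$loci[1L, ]
  chrom <- as.character(sim$genome[[l$chrom]])
  shifted <- substr(chrom, l$mat_start0 + 2L, l$mat_end0 + 1L)
  s2 <- cand_setup(mature_n = 30L, star_n = 3L,
                   extra = list(seq = shifted, n = 10L))
  rec2 <- call_candidates(s2$collapsed, s2$classified, s2$map,
                          s2$sim$genome)
  expect_equal(nrow(rec2), 0L)
})

test_that("known-homolog status bypasses the star requirement", {
  s <- cand_setup(mature_n = 12L, star_n = 0L)
  known <- sim_known_matures(s$sim)
  rec <- call_candidates(s$collapsed, s$classified, s$map, s$sim$genome,
                         known_matures = known)
  expect_equal(rec$status, "known-homolog")
  expect_equal(rec$name, s$sim$loci$name)
})

test_that("unmapped reads matching a known mature are rescued", {
  sim <- one_locus_sim()
  # a known mature absent from this genome
  foreign <- "TCCCTGAGACCCTAACTTGTGA"
  known <- Biostrings::DNAStringSet(c(`mir-x` = foreign))
  collapsed <- make_collapsed(foreign, brain_M = 25L)
  map <- map_exact(collapsed, sim$genome)
  classified <- classify_reads(map, known_ncrna = sim$known_ncrna)
  rec <- call_candidates(collapsed, classified, map, sim$genome,
                         known_matures = known)
  expect_equal(rec$status, "known-homolog-unmapped")
  expect_equal(rec$name, "mir-x")
  expect_true(is.na(rec$chrom))
})

test_that("star detection respects the duplex-partner span slack", {
  sim <- one_locus_sim()
  l <- sim$loci[1L, ]
  fi <- finchmir:::best_hairpin_window(sim$genome, l$chrom,
                                       l$mat_start0 + 1L, l$mat_end0, "+")
  w0 <- fi$window_start1
  star_span <- c(l$star_start0 + 1L - w0 + 1L, l$star_end0 - w0 + 1L)
  ok_stack <- data.frame(sequence = l$star, start1 = star_span[1L],
                         end1 = star_span[2L], count = 5L)
  st <- detect_star(fi, ok_stack)
  expect_equal(st$star_sequence, l$star)
  expect_equal(st$star_count, 5L)

  # a read 10 nt away from the partner span is not a star
  far_stack <- transform(ok_stack, start1 = start1 + 10L,
                         end1 = end1 + 10L)
  expect_true(is.na(detect_star(fi, far_stack)$star_sequence))
  # no opposite-arm reads at all
  empty <- ok_stack[0L, , drop = FALSE]
  expect_equal(detect_star(fi, empty)$star_count, 0L)
})

test_that("arm balance applies the ten-fold rule", {
  expect_true(arm_balance(1000, 150))    # ratio 6.7
  expect_false(arm_balance(1000, 10))    # ratio 100
  expect_false(arm_balance(1000, 0))
  expect_false(arm_balance(0, 10))
})
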