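test_that("homolog search distinguishes precursor, mature-only, absent", {
  sim <- one_locus_sim()
  l <- sim$loci[1L, ]
  prec <- substr(as.character(sim$genome[[l$chrom]]), l$prec_start0 + 1L,
                 l$prec_end0)
  set.seed(51)
  rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                            collapse = "")
  with_prec <- Biostrings::DNAStringSet(paste0(rand(150), prec, rand(150)))
  mature_only <- Biostrings::DNAStringSet(paste0(rand(150), l$mature,
                                                 rand(150)))
  unrelated <- Biostrings::DNAStringSet(rand(400))
  expect_equal(find_homolog(l$mature, with_prec), "precursor-homolog")
  expect_equal(find_homolog(l$mature, mature_only), "mature-only")
  expect_equal(find_homolog(l$mature, unrelated), "absent")
  # one mismatch still finds the homolog
  mm <- l$mature
  substr(mm, 10, 10) <- if (substr(mm, 10, 10) == "A") "G" else "A"
  expect_equal(find_homolog(mm, with_prec), "precursor-homolog")
})

test_that("tier assignment is deterministic and monotone", {
  groups <- list(avian = "chicken", mammal = c("human", "mouse"),
                 vertebrate_other = "zebrafish", invertebrate = "worm")
  call_of <- function(...) {
    sp <- c(chicken = "absent", human = "absent", mouse = "absent",
            zebrafish = "absent", worm = "absent")
    hits <- c(...)
    sp[hits] <- "precursor-homolog"
    sp
  }
  expect_equal(assign_tier(call_of("chicken"), groups), "avian-specific")
  expect_equal(assign_tier(call_of(), groups), "species-specific")
  expect_equal(assign_tier(call_of("chicken", "human", "zebrafish",
                                   "worm"), groups), "pan-animal")
  expect_equal(assign_tier(call_of("chicken", "human", "mouse"), groups),
               "avian+mammal")
  expect_equal(assign_tier(call_of("chicken", "zebrafish"), groups),
               "vertebrate")
  # mature-only does not count as a homolog
  calls <- call_of("chicken")
  calls["human"] <- "mature-only"
  expect_equal(assign_tier(calls, groups), "avian-specific")
  expect_error(assign_tier(character(0), groups), "empty")

  # monotonicity: adding a homolog never narrows the tier
  ranks <- c("species-specific" = 1, "avian-specific" = 2,
             "avian+mammal" = 3, "vertebrate" = 4, "pan-animal" = 5)
  species <- c("chicken", "human", "mouse", "zebrafish", "worm")
  set.seed(53)
  for (r in 1:30) {
    base_hits <- species[runif(5) < 0.4]
    extra <- sample(setdiff(species, base_hits), 1)
    t1 <- assign_tier(call_of(base_hits), groups)
    t2 <- assign_tier(call_of(c(base_hits, extra)), groups)
    expect_gte(ranks[[t2]], ranks[[t1]])
  }
})

test_that("genomic clustering follows the 10 kb single-linkage rule", {
  loci <- data.frame(name = c("mir-a", "mir-b", "mir-c"),
                     chrom = "chr1", start0 = c(1000L, 8500L, 17000L),
                     stringsAsFactors = FALSE)
  cl <- cluster_loci(loci)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$cluster, "mir-a(3)")
  expect_equal(cl$n, 3L)

  far <- data.frame(name = c("mir-a", "mir-b"), chrom = "chr1",
                    start0 = c(1000L, 12000L), stringsAsFactors = FALSE)
  expect_equal(nrow(cluster_loci(far)), 0L)

  dup <- data.frame(name = c("mir-d1", "mir-d2"), chrom = "chr8",
                    start0 = c(1000L, 3000L),
                    mature = rep("ACGTACGTACGTACGTACGTAC", 2L),
                    stringsAsFactors = FALSE)
  cld <- cluster_loci(dup)
  expect_equal(cld$cluster, "mir-d1(2)")
  expect_true(cld$tandem)
})

test_that("clustering is order-invariant and matches transitive closure", {
  set.seed(59)
  for (r in 1:20) {
    n <- sample(3:12, 1L)
    loci <- data.frame(
      name = sprintf("m%02d", seq_len(n)),
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      start0 = sample.int(60000L, n), stringsAsFactors = FALSE)
    cl1 <- cluster_loci(loci)
    cl2 <- cluster_loci(loci[sample(n), , drop = FALSE])
    expect_equal(cl1[order(cl1$cluster), ], cl2[order(cl2$cluster), ],
                 ignore_attr = TRUE)
    # membership equals the brute-force closure of the <= 10 kb relation
    memb <- bf_cluster_membership(loci$chrom, loci$start0)
    bf_sizes <- sort(as.integer(table(memb)[table(memb) >= 2L]))
    expect_equal(sort(cl1$n), bf_sizes)
  }
})
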