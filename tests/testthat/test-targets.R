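let7a <- "UGAGGUAGUAGGUUGUAUAGUU"

test_that("seed matching finds the reverse complement of positions 2-8", {
  utrs <- data.frame(
    gene = c("hit", "miss", "short"),
    chrom = c("chr1", "chr1", "chr2"),
    utr = c(paste0("AAAAAAAAAA", "CTACCTC", "AAAAAAAAAA"),
            strrep("AGGG", 10L),
            "ACGTACG"),               # 7 nt: excluded before matching
    stringsAsFactors = FALSE)
  expect_equal(seed_match(let7a, utrs), "hit")
  # case and alphabet invariance
  utrs2 <- utrs
  utrs2$utr[1L] <- tolower(gsub("T", "U", utrs2$utr[1L]))
  expect_equal(seed_match(let7a, utrs2), "hit")
  expect_equal(seed_match(gsub("U", "t", tolower(let7a)), utrs), "hit")
  expect_error(seed_match("UGAGGUA", utrs), "8 nt")
})

test_that("seed matching equals a naive substring scan on random UTRs", {
  set.seed(71)
  utrs <- data.frame(
    gene = sprintf("g%03d", 1:200),
    chrom = sample(c("chr1", "chrZ"), 200, replace = TRUE),
    utr = vapply(1:200, function(i)
      paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = ""),
      character(1)),
    stringsAsFactors = FALSE)
  site <- revcomp(substr(gsub("U", "T", let7a), 2L, 8L))
  naive <- utrs$gene[vapply(utrs$utr, function(u)
    any(gregexpr(site, u, fixed = TRUE)[[1L]] > 0L), logical(1))]
  expect_equal(seed_match(let7a, utrs), naive)
})

test_that("enrichment p-values equal the hypergeometric tail", {
  utr_of <- function(n_chrom, n_other) {
    data.frame(gene = sprintf("g%04d", seq_len(n_chrom + n_other)),
               chrom = c(rep("chrZ", n_chrom), rep("chr1", n_other)),
               utr = strrep("A", 30L), stringsAsFactors = FALSE)
  }
  # proportional targets: no enrichment signal
  u <- utr_of(100L, 900L)
  tg <- c(u$gene[1:10], u$gene[101:190])   # 10 of 100 on chrZ, 90 off
  e <- fisher_enrichment(tg, u, "chrZ")
  expect_equal(e$table[1L, ], c(on_chrom = 10L, elsewhere = 90L))
  expect_equal(e$p_value, bf_hyper_tail(10L, 90L, 90L, 810L),
               tolerance = 1e-12)
  expect_gt(e$p_value, 0.4)

  # small table against exhaustive tail enumeration
  u2 <- utr_of(13L, 87L)
  tg2 <- c(u2$gene[1:3], u2$gene[14:20])   # table [[3,7],[10,80]]
  e2 <- fisher_enrichment(tg2, u2, "chrZ")
  expect_equal(unname(e2$table), matrix(c(3L, 7L, 10L, 80L), 2L,
                                        byrow = TRUE))
  expect_equal(e2$p_value, bf_hyper_tail(3L, 7L, 10L, 80L),
               tolerance = 1e-12)

  # degenerate: no genes at all on the tested chromosome
  u3 <- utr_of(0L, 50L)
  e3 <- fisher_enrichment(u3$gene[1:5], u3, "chrZ")
  expect_equal(e3$p_value, 1)
  expect_error(fisher_enrichment(character(0), u3[0L, ], "chrZ"), "empty")
})

test_that("exact test equals brute-force tails over random tables", {
  set.seed(73)
  for (r in 1:60) {
    N <- sample(20:200, 1L)
    n_chrom <- sample(1:(N - 1L), 1L)
    K <- sample(1:(N - 1L), 1L)
    genes <- sprintf("g%04d", seq_len(N))
    chrom <- sample(c(rep("chrZ", n_chrom), rep("chr1", N - n_chrom)))
    u <- data.frame(gene = genes, chrom = chrom, utr = strrep("A", 30L),
                    stringsAsFactors = FALSE)
    tg <- sample(genes, K)
    e <- fisher_enrichment(tg, u, "chrZ")
    a <- e$table[1L, 1L]
    expect_equal(e$p_value,
                 bf_hyper_tail(a, K - a, n_chrom - a, N - n_chrom - K + a),
                 tolerance = 1e-9)
  }
})

test_that("target reports tally chromosome percentages", {
  u <- data.frame(gene = sprintf("g%03d", 1:100),
                  chrom = rep(c("chrZ", "chr1", "chr2"), c(20, 40, 40)),
                  utr = strrep("A", 30L), stringsAsFactors = FALSE)
  tg <- c(u$gene[1:7], u$gene[21:53])      # 7 on chrZ, 33 elsewhere
  rep_ <- target_report(tg, u)
  expect_equal(rep_$targets[rep_$chrom == "chrZ"], 7L)
  expect_equal(rep_$target_pct[rep_$chrom == "chrZ"], 17.5)
  expect_equal(sum(rep_$target_pct), 100, tolerance = 0.2)
  expect_equal(nrow(target_report(character(0), u)), 0L)
})

test_that("planted chrZ-biased seed sites are detected as enrichment", {
  res <- small_run()
  truth <- res$sim$loci
  biased_name <- truth$name[truth$z_class == "Z-male-biased"]
  rec_name <- res$records$name[res$records$sequence ==
                                 gsub("T", "U", truth$mature[
                                   truth$name == biased_name])]
  enr <- res$targets$results[[rec_name]]$enrichment
  expect_lt(enr$p_value, 0.01)
  expect_gte(enr$table[1L, 1L], 25L)

  # unbiased planting: ordinary-Z miRNA shows no such signal across
  # replicate universes (p-values consistent with the uniform null)
  cfg <- small_cfg()
  sim <- res$sim
  ordz <- truth[truth$z_class == "Z", ][1L, ]
  set.seed(79)
  ps <- vapply(1:200, function(r) {
    n <- 200L
    chrom <- sample(c("chr1", "chr2", "chrZ"), n, TRUE,
                    prob = c(0.44, 0.44, 0.12))
    utr <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), 250L, TRUE), collapse = ""),
      character(1))
    u <- data.frame(gene = sprintf("g%03d", seq_len(n)), chrom = chrom,
                    utr = utr, stringsAsFactors = FALSE)
    site <- revcomp(substr(ordz$mature, 2L, 8L))
    for (g in sample(n, 30L)) {
      p <- sample(250L - 7L, 1L)
      substr(u$utr[g], p, p + 6L) <- site
    }
    tg <- seed_match(ordz$mature, u)
    e <- fisher_enrichment(tg, u, "chrZ")
    # mid-p alongside the exact p: the exact one-sided p of a discrete
    # test is super-uniform (conservative), so strict uniformity is only
    # expected after the mid-p correction
    a <- e$table[1L, 1L]
    K <- sum(e$table[1L, ]); m <- sum(e$table[, 1L]); N <- sum(e$table)
    c(p = e$p_value,
      midp = e$p_value - 0.5 * stats::dhyper(a, m, N - m, K))
  }, numeric(2))
  expect_gt(suppressWarnings(stats::ks.test(ps["midp", ],
                                            "punif"))$p.value, 0.01)
  # the exact p never shows excess small values (no spurious enrichment)
  for (alpha in c(0.01, 0.05, 0.1))
    expect_lte(mean(ps["p", ] < alpha), alpha + 0.03)
})
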