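test_that("RPM normalisation satisfies its identities", {
  mat <- matrix(c(100L, 0L, 999900L,
                  50L, 0L, 499950L), ncol = 2L,
                dimnames = list(c("a", "b", "c"), c("brain_M", "brain_F")))
  r <- rpm(mat)
  expect_equal(r["a", "brain_M"], 100)
  expect_equal(r["b", ], c(brain_M = 0, brain_F = 0))
  expect_equal(unname(colSums(r)), c(1e6, 1e6))
  bad <- mat; bad[, 2L] <- 0L
  expect_error(rpm(bad), "zero")
})

test_that("tissue enrichment applies the share and depth rules", {
  mat <- matrix(c(111170L, 458L,     # brain-dominated, deep
                  890L, 110L,        # 89% / 11%
                  86L, 4L,           # 95% share but only 90 reads
                  500L, 500L),       # tie
                ncol = 2L, byrow = TRUE,
                dimnames = list(c("mir124", "mid", "thin", "tied"),
                                c("brain", "other")))
  calls <- call_tissue_enrichment(mat)
  expect_equal(calls$enriched_tissue[calls$mirna == "mir124"], "brain")
  expect_true(is.na(calls$enriched_tissue[calls$mirna == "mid"]))
  expect_true(is.na(calls$enriched_tissue[calls$mirna == "thin"]))
  expect_true(is.na(calls$enriched_tissue[calls$mirna == "tied"]))

  # invariant to uniform scaling of all samples (among miRNAs already
  # above the absolute read-depth floor, which is deliberately not
  # scale-free)
  calls2 <- call_tissue_enrichment(mat * 10L)
  deep <- calls$total >= 100
  expect_equal(calls$enriched_tissue[deep], calls2$enriched_tissue[deep])

  # sexes are combined per tissue before the rule is applied
  m2 <- matrix(c(60L, 55L, 3L, 4L), ncol = 4L,
               dimnames = list("m", c("brain_M", "brain_F", "heart_M",
                                      "heart_F")))
  expect_equal(call_tissue_enrichment(m2)$enriched_tissue, "brain")
})

test_that("male:female ratios use RPM, pseudocounts, and depth filter", {
  mat <- matrix(c(5000L, 5000L,
                  400L, 200L,
                  30L, 15L), ncol = 2L, byrow = TRUE,
                dimnames = list(c("flat", "dosage", "thin"),
                                c("brain_M", "brain_F")))
  mf <- mf_ratio(mat, chrom = c(flat = "chr1", dosage = "chrZ",
                                thin = "chrZ"))
  # equal counts with equal library sizes give ratio 1 after the (tiny)
  # library-size correction
  flat <- mf[mf$mirna == "flat" & mf$tissue == "brain", ]
  expect_equal(flat$ratio, (flat$rpm_M + 0.5) / (flat$rpm_F + 0.5))
  expect_false(flat$z_linked)
  expect_true(mf$z_linked[mf$mirna == "dosage"][1L])
  # below 100 combined reads: excluded
  expect_false("thin" %in% mf$mirna)
  expect_true(all(c("brain", "all") %in% mf$tissue))

  eq <- matrix(c(200L, 200L, 800L, 800L), ncol = 2L, byrow = TRUE,
               dimnames = list(c("x", "y"), c("brain_M", "brain_F")))
  mfe <- mf_ratio(eq)
  expect_equal(mfe$ratio[mfe$mirna == "x" & mfe$tissue == "brain"], 1)
})

test_that("pipeline recovers planted dosage and male bias", {
  res <- small_run()
  cfg <- small_cfg()
  truth <- res$sim$loci
  mf <- res$expression$mf
  mf <- mf[mf$tissue == "all", ]
  seq_of <- stats::setNames(gsub("T", "U", truth$mature), truth$name)
  name_of <- function(lname)
    res$records$name[res$records$sequence == seq_of[[lname]]]

  mat <- res$expression$matrix
  sex <- sub("^.*_", "", colnames(mat))
  for (lname in truth$name[truth$z_class == "Z"]) {
    rn <- name_of(lname)
    m <- sum(mat[rn, sex == "M"]); f <- sum(mat[rn, sex == "F"])
    p <- 2 / 3
    se <- sqrt(p * (1 - p) / (m + f))
    expect_lt(abs(m / (m + f) - p), 3 * se + 0.02, label = lname)
  }
  biased <- truth$name[truth$z_class == "Z-male-biased"]
  rn <- name_of(biased)
  m <- sum(mat[rn, sex == "M"]); f <- sum(mat[rn, sex == "F"])
  # significantly beyond the 2:1 dosage expectation
  expect_lt(binom.test(m, m + f, 2 / 3, alternative = "greater")$p.value,
            0.01)
  expect_gt(mf$ratio[mf$mirna == rn], 2)
})
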