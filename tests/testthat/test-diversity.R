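test_that("segregating sites counts variable retained columns", {
  expect_equal(segregating_sites(tiny_aln(c("ACGT", "ACGT", "ACGT"))), 0)
  expect_equal(segregating_sites(tiny_aln(c("AAAA", "AAAT"))), 1)
  expect_error(segregating_sites(tiny_aln("ACGT")), class = "mothwaves_input_error")
  # planted variable columns from the generator are counted exactly
  for (seed in c(3, 17)) {
    sim <- simulate_haplotypes(seed = seed)
    expect_equal(segregating_sites(sim$alignment), sim$manifest$planted_S)
  }
})

test_that("mean pairwise differences match hand and brute-force values", {
  expect_equal(mean_pairwise_differences(tiny_aln(rep("ACGT", 4))), 0)
  expect_equal(mean_pairwise_differences(tiny_aln(c("AAAA", "AATT", "AAAA"))), 4 / 3)
  set.seed(42)
  for (i in 1:5) {
    aln <- random_aln(n = sample(5:12, 1), len = sample(8:20, 1))
    expect_equal(mean_pairwise_differences(aln), oracle_mpd(aln$sequence))
  }
  # 50-sequence synthetic sample equals the O(n^2 L) double loop exactly
  sim <- simulate_haplotypes(
    n_samples = 50, seq_length = 80,
    founder_spectrum = data.frame(count = c(20, 15, 10), steps = c(0, 1, 2)),
    n_singletons = 5, n_demes = 2, seed = 9
  )
  expect_equal(mean_pairwise_differences(sim$alignment),
               oracle_mpd(sim$alignment$sequence))
})

test_that("haplotype diversity follows the unbiased estimator", {
  expect_equal(haplotype_diversity(c(7)), 0)
  expect_equal(haplotype_diversity(c(1, 1)), 1)
  expect_error(haplotype_diversity(c(1)), class = "mothwaves_input_error")
  # permutation invariance and strict increase when a duplicate is split off
  set.seed(1)
  for (i in 1:20) {
    cts <- sample(1:30, sample(2:8, 1), replace = TRUE)
    expect_equal(haplotype_diversity(cts), haplotype_diversity(sample(cts)))
    big <- which(cts >= 2)[1]
    if (!is.na(big)) {
      split <- c(cts, 1)
      split[big] <- split[big] - 1
      expect_gt(haplotype_diversity(split), haplotype_diversity(cts))
    }
  }
})

test_that("major haplotype fraction pools the m largest counts", {
  expect_equal(major_haplotype_fraction(c(3, 1), 1), 75)
  expect_equal(major_haplotype_fraction(c(3, 1), 2), 100)
  expect_error(major_haplotype_fraction(c(3, 1), 3), class = "mothwaves_input_error")
})

test_that("Tajima's D matches independent closed-form arithmetic at n = 4", {
  # from-scratch rational evaluation of the constants for n = 4
  a1 <- 1 + 1 / 2 + 1 / 3
  a2 <- 1 + 1 / 4 + 1 / 9
  b1 <- 5 / 9
  b2 <- 2 * (16 + 4 + 3) / (9 * 4 * 3)
  c1 <- b1 - 1 / a1
  c2 <- b2 - 6 / (a1 * 4) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  S <- 2; k <- 1.0
  expected <- (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  expect_equal(tajimas_d(S = 2, k = 1.0, n = 4), expected, tolerance = 1e-12)
})

test_that("Tajima's D is zero at k = S/a1 and carries the sign of k - S/a1", {
  set.seed(7)
  for (i in 1:10) {
    n <- sample(5:200, 1)
    S <- sample(1:30, 1)
    a1 <- sum(1 / seq_len(n - 1))
    expect_equal(tajimas_d(S, S / a1, n), 0, tolerance = 1e-12)
    k <- stats::runif(1, 0, 2 * S / a1)
    d <- tajimas_d(S, k, n)
    expect_equal(sign(d), sign(k - S / a1))
  }
})

test_that("undefined statistics signal instead of returning numbers", {
  expect_warning(d <- tajimas_d(0, 0, 10), class = "mothwaves_undefined_stat")
  expect_true(is.na(d))
  expect_error(tajimas_d(2, 1, 3), class = "mothwaves_input_error")
  expect_warning(f <- fus_fs(0, 10, 2), class = "mothwaves_undefined_stat")
  expect_true(is.na(f))
})

test_that("diversity_stats summarises pooled and per-population samples", {
  sim <- simulate_haplotypes(seed = 4)
  ds <- diversity_stats(sim$alignment, sim$popmap)
  expect_equal(nrow(ds), 7) # pooled + 6 demes
  pooled <- ds[ds$population == "pooled", ]
  expect_equal(pooled$n, 220)
  expect_equal(pooled$h, 16L)
  expect_equal(pooled$Pi * pooled$effective_length, pooled$k, tolerance = 1e-12)
  expect_equal(pooled$S, sim$manifest$planted_S)
  expect_equal(pooled$Hd, sim$manifest$planted_Hd, tolerance = 1e-12)
})
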