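test_that("demography objects validate their epochs", {
  expect_error(piecewise_demography(c(100, 200), c(5, 10)),
               "start at 0")
  expect_error(piecewise_demography(c(100, 200), c(0, 0)), "increasing")
  expect_error(piecewise_demography(c(100, -5), c(0, 10)), "positive")
  d <- default_demography()
  expect_s3_class(d, "piecewise_demography")
  expect_equal(d$sizes[length(d$sizes)], 23706)
})

test_that("replicates are seed-stable and empty without mutation", {
  d <- constant_demography(1000)
  r0 <- neutral_chromosome_replicate(d, 1e5, mu = 0, seed = 1)
  expect_equal(nrow(r0$records), 0L)
  r1 <- neutral_chromosome_replicate(d, 1e5, seed = 9, genotypes = TRUE)
  r2 <- neutral_chromosome_replicate(d, 1e5, seed = 9, genotypes = TRUE)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$genotypes, r2$genotypes)
  expect_error(neutral_chromosome_replicate(d, 1e5), "seed")
  # genotype matrix is consistent with the folded records
  cnt <- colSums(r1$genotypes)
  expect_equal(pmin(cnt, 10 - cnt), r1$records$x)
  expect_true(all(r1$records$position >= 1 & r1$records$position <= 1e5))
  expect_false(is.unsorted(r1$records$position, strictly = TRUE))
})

test_that("constant-N replicates match Watterson and the folded SFS", {
  # analytic oracles: E[S] = 4 N mu L sum(1/i); folded class proportions
  # proportional to (1/i + 1/(n-i)) / (1 + ind(i = n/2))
  N <- 2000; L <- 5e5; mu <- 1.52e-8; n <- 10; R <- 100
  d <- constant_demography(N)
  S <- numeric(R)
  sfs <- numeric(5)
  for (i in seq_len(R)) {
    rec <- neutral_chromosome_replicate(d, L, mu, seed = 1000 + i)$records
    S[i] <- nrow(rec)
    sfs <- sfs + tabulate(rec$x, 5)
  }
  EW <- 4 * N * mu * L * sum(1 / (1:(n - 1)))
  expect_lt(abs(mean(S) - EW), 3 * sd(S) / sqrt(R))
  w <- (1 / (1:5) + 1 / (9:5)) / (1 + (1:5 == 5))
  w <- w / sum(w)
  tot <- sum(sfs)
  for (k in 1:5) {
    se <- sqrt(w[k] * (1 - w[k]) / tot)
    # SNPs within a replicate are correlated; allow for that in the SE
    expect_lt(abs(sfs[k] / tot - w[k]), 3 * se * sqrt(10))
  }
})

test_that("the bottleneck depresses diversity below the ancestral level", {
  d <- default_demography()
  pis <- vapply(1:100, function(i) {
    pairwise_diversity(neutral_chromosome_replicate(d, 5e4, seed = 200 + i))
  }, numeric(1))
  theta_anc <- 4 * 23706 * 1.52e-8
  expect_lt(mean(pis), theta_anc)
  # and clearly so, not just by noise
  expect_lt(mean(pis) + 3 * sd(pis) / 10, theta_anc)
})
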