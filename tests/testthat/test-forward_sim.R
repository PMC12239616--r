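test_that("the genomic architecture tiles to the study total", {
  arch <- build_architecture()
  expect_equal(architecture_length(arch), 91161L)
  # elements tile [1, L] without gaps or overlaps
  expect_equal(arch$start[1], 1L)
  expect_true(all(arch$start[-1] == arch$end[-nrow(arch)] + 1L))
  # exon fraction of the region
  ex_bp <- sum(arch$end[arch$class == "exon"] -
                 arch$start[arch$class == "exon"] + 1L)
  expect_equal(ex_bp / 91161, 3 * 9 * 130 / 91161)
  expect_equal(ex_bp / 91161, 0.0385, tolerance = 0.002)
  one <- build_architecture(1, 1, 130, 1591, 0)
  expect_equal(architecture_length(one), 130L)
  expect_error(build_architecture(0), "at least one")
})

test_that("DFE draws respect their class bins", {
  set.seed(2)
  d0 <- sample_dfe(dfe_config(c(1, 0, 0, 0)), 2000)
  expect_true(all(d0$twoNs >= 0 & d0$twoNs < 1))
  d2 <- sample_dfe(dfe_config(c(0, 0, 1, 0)), 1e5)
  expect_true(all(d2$twoNs >= 10 & d2$twoNs < 100))
  expect_equal(mean(d2$twoNs), 55, tolerance = 0.01)
  expect_equal(d2$s, d2$twoNs / (2 * 23706))
  expect_error(dfe_config(c(-0.1, 0.5, 0.3, 0.3)), "non-negative")
  expect_error(dfe_config(c(0.5, 0.5, 0.2, 0)), "sum to 1")
})

test_that("rate maps obey their bounds and mean-matching", {
  expect_equal(assign_rate_map(1e5, 1000, 1e-8, 1e-8, 1e-8), rep(1e-8, 100))
  set.seed(5)
  r <- assign_rate_map(1e6, 1000, target_mean = 1e-8, lo = 1e-10, hi = 1e-7,
                       mode = "literal")
  expect_true(all(r >= 1e-10 & r <= 1e-7))
  m <- assign_rate_map(1e6, 1000, target_mean = 1e-8, lo = 1e-10, hi = 1e-7)
  expect_true(all(m >= 1e-10 & m <= 1e-7))
  expect_lt(abs(mean(m) - 1e-8), 0.01 * 1e-8)
  mu <- assign_rate_map(1e6, 1000, target_mean = 1.52e-8, lo = 0.61e-8,
                        hi = 3.8e-8)
  expect_lt(abs(mean(mu) - 1.52e-8), 0.01 * 1.52e-8)
  expect_error(assign_rate_map(1e5, 1000, target_mean = 5e-7, lo = 1e-10,
                               hi = 1e-7), "outside")
})

test_that("the frequency-dependent coefficient is F_eq - F_bp", {
  expect_equal(frequency_dependent_coefficient(0.5, 0.5), 0)
  expect_equal(frequency_dependent_coefficient(0.5, 0.2), 0.3)
  expect_equal(frequency_dependent_coefficient(0.5, 0.9), -0.4)
  expect_error(frequency_dependent_coefficient(1.2, 0.5), "\\[0, 1\\]")
})

test_that("forward replicates honor scenario contracts", {
  model <- default_demography()
  arch <- build_architecture()
  dfe <- dfe_config()
  # no mutation, no polymorphism
  r0 <- run_forward(model, arch, dfe, selection_scenario("neutral"),
                    mu_map = 0, Q = 200, seed = 1)
  expect_equal(nrow(r0$records), 0L)
  # retained sweep replicates carry a fixed beneficial mutation
  sw <- run_forward(model, arch, dfe,
                    selection_scenario("sweep", twoNs = 10000, tau = 0.1),
                    Q = 100, seed = 2)
  expect_equal(sw$sel_state, "fixed")
  expect_equal(sw$sel_freq, 1)
  # balanced mutation still segregates at sampling
  bl <- run_forward(model, arch, dfe,
                    selection_scenario("balancing", tau = 10, run_N = 12),
                    Q = 100, seed = 3)
  expect_equal(bl$sel_state, "segregating")
  expect_true(bl$sel_freq > 0 && bl$sel_freq < 1)
  # genotypes agree with folded records
  cnt <- colSums(bl$genotypes)
  expect_equal(pmin(cnt, 10 - cnt), bl$records$x)
  # seed determinism
  sw2 <- run_forward(model, arch, dfe,
                     selection_scenario("sweep", twoNs = 10000, tau = 0.1),
                     Q = 100, seed = 2)
  expect_identical(sw$records, sw2$records)
})

test_that("an infeasible weak, recent sweep hits the restart cap", {
  model <- default_demography()
  arch <- build_architecture()
  dfe <- dfe_config(c(1, 0, 0, 0))
  expect_error(
    run_forward(model, arch, dfe,
                selection_scenario("sweep", twoNs = 100, tau = 0.1),
                Q = 100, seed = 4, max_restarts = 20L),
    "restart cap")
})

test_that("burn-in reaches the neutral equilibrium diversity", {
  # constant N, neutral DFE, sampled immediately after the 10N burn-in:
  # mean diversity should sit within 10% of theta = 4 N mu
  model <- constant_demography(23706)
  arch <- build_architecture()
  dfe <- dfe_config(c(1, 0, 0, 0))
  pis <- vapply(1:20, function(i) {
    r <- run_forward(model, arch, dfe,
                     selection_scenario("neutral", run_N = 0),
                     Q = 100, seed = 500 + i)
    pairwise_diversity(list(records = r$records, L = r$L))
  }, numeric(1))
  theta <- 4 * 23706 * 1.52e-8
  expect_lt(abs(mean(pis) - theta), 0.1 * theta)
})

test_that("rescaled runs agree on diversity across Q", {
  model <- constant_demography(23706)
  arch <- build_architecture()
  dfe <- dfe_config(c(1, 0, 0, 0))
  pi_at <- function(Q, seeds) {
    vapply(seeds, function(s) {
      r <- run_forward(model, arch, dfe,
                       selection_scenario("neutral", run_N = 0),
                       Q = Q, seed = s)
      pairwise_diversity(list(records = r$records, L = r$L))
    }, numeric(1))
  }
  p100 <- pi_at(100, 700 + 1:8)
  p50 <- pi_at(50, 800 + 1:8)
  se <- sqrt(sd(p100)^2 / 8 + sd(p50)^2 / 8)
  expect_lt(abs(mean(p100) - mean(p50)), 3 * se)
})

test_that("the balanced allele is mean-reverting around its equilibrium", {
  traj <- simulate_balanced_locus(N = 1000, generations = 20000, seed = 77)
  post <- traj[5001:20000]
  expect_lt(abs(mean(post) - 0.5), 0.05)
  # deviations decorrelate: lagged autocorrelation decays
  dev <- post - mean(post)
  ac <- function(l) cor(dev[-(1:l)], dev[1:(length(dev) - l)])
  expect_gt(ac(1), ac(200))
  expect_lt(abs(ac(2000)), 0.2)
})
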