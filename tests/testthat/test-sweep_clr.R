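test_that("escape probability follows its closed form with clamping", {
  expect_equal(escape_probability(0.01, 0), 1e-12)
  expect_equal(escape_probability(1, log(2)), 0.5)
  expect_equal(escape_probability(1, 1e6), 1)
  expect_equal(escape_probability(2e-4, 5000), 1 - exp(-1))
})

test_that("sweep spectrum reduces to the background when all escape", {
  G <- tiny_G()
  expect_equal(sweep_spectrum(G, 1)$G, G$G, tolerance = 1e-12)
})

test_that("sweep spectrum matches the brute-force enumeration oracle", {
  for (n in c(4L, 6L)) {
    K <- n %/% 2L
    set.seed(n)
    for (rep in 1:3) {
      g <- runif(K) + 0.1
      G <- folded_sfs(g / sum(g), n)
      for (pe in c(0.1, 0.5, 0.9)) {
        got <- sweep_spectrum(G, pe)$G
        expect_equal(sum(got), 1, tolerance = 1e-12)
        expect_equal(unname(got), sweep_spectrum_oracle(G, pe),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("singleton excess relaxes toward the background as p_e grows", {
  G <- tiny_G()
  pe_grid <- c(0.001, 0.01, 0.1, 0.3, 0.6, 0.9)
  m1 <- vapply(pe_grid, function(p) sweep_spectrum(G, p)$G[[1L]], numeric(1))
  expect_true(all(diff(m1) < 1e-9))
  expect_gt(m1[1], G$G[[1L]])
  expect_equal(sweep_spectrum(G, 0.999)$G[[1L]], G$G[[1L]],
               tolerance = 0.01)
})

test_that("degenerate p_e below the polymorphism floor is an error", {
  # a background with all mass on the self-symmetric class keeps no
  # polymorphic mass when essentially every lineage is swept
  G <- folded_sfs(c(0, 1), 4L)
  expect_error(sweep_spectrum(G, 1e-320), "degenerate")
})

test_that("the CLR vanishes when the data carry no sweep information", {
  # n = 2: the only folded class is 1, both models assign probability 1
  G2 <- folded_sfs(1, 2L)
  rec <- make_records(500, 1, n = 2L)
  expect_equal(sweep_clr_at(250, rec, G2)$clr, 0, tolerance = 1e-9)
  # i.i.d. background data at unlinked distances: all alpha*d beyond cutoff
  G <- tiny_G()
  set.seed(21)
  rec <- make_records(seq(1, by = 1000, length.out = 50), draw_classes(G, 50))
  far <- sweep_clr_at(1e13, rec, G)
  expect_lt(abs(far$clr), 1e-6)
})

test_that("scan evaluates every grid position deterministically", {
  G <- tiny_G()
  rec <- make_records(c(100L, 200L, 300L), c(1L, 2L, 5L))
  sc <- scan_sweep(rec, G)
  expect_equal(nrow(sc), 3L)
  expect_equal(sc$position, c(100, 200, 300))
  # permuting input rows does not change the result
  sc2 <- scan_sweep(rec[c(3, 1, 2), ], G)
  expect_equal(sc, sc2)
  # grid override restricts test positions
  sc3 <- scan_sweep(rec, G, grid = c(150, 250))
  expect_equal(sc3$position, c(150, 250))
  expect_error(scan_sweep(rec, G, grid = numeric()), "empty")
  # zero-probability observed class is rejected
  G0 <- background_spectrum(make_records(1:2, c(1, 2)))
  expect_error(scan_sweep(rec, G0), "zero probability")
})

test_that("scan core agrees with the exact single-position evaluation", {
  G <- tiny_G()
  set.seed(31)
  rec <- make_records(sort(sample.int(2e5, 60)), draw_classes(G, 60))
  sc <- scan_sweep(rec, G, grid = rec$position[c(10, 30, 50)])
  for (i in 1:3) {
    exact <- sweep_clr_at(sc$position[i], rec, G)
    expect_equal(sc$clr[i], exact$clr, tolerance = 0.02)
  }
})

test_that("CLR is non-negative over random datasets", {
  set.seed(41)
  for (i in 1:25) {
    K <- 5L
    g <- runif(K) + 0.05
    G <- folded_sfs(g / sum(g), 10L)
    m <- sample(10:60, 1)
    rec <- make_records(sort(sample.int(5e5, m)), draw_classes(G, m))
    sc <- scan_sweep(rec, G)
    expect_true(all(sc$clr >= -1e-9))
  }
})

test_that("a strong recent sweep leaves its signature in the region", {
  # at these selection strengths the sweep footprint spans the whole 91-kb
  # region, so the region-wide signature (diversity loss, scannable skew)
  # is the testable consequence rather than within-region localization
  model <- default_demography()
  arch <- build_architecture()
  dfe <- dfe_config()
  neut <- lapply(1:8, function(i) {
    run_forward(model, arch, dfe, selection_scenario("neutral"),
                Q = 100, seed = 9000 + i)
  })
  G <- background_spectrum(do.call(rbind, lapply(neut, `[[`, "records")),
                           smooth = 0.5)
  spectra <- ayescan:::sweep_model_spectra(G)
  n_rep <- 10L
  sweeps <- lapply(seq_len(n_rep), function(i) {
    run_forward(model, arch, dfe,
                selection_scenario("sweep", twoNs = 10000, tau = 0.1),
                Q = 100, seed = 9100 + i)
  })
  n_sweep <- vapply(sweeps, function(r) nrow(r$records), integer(1))
  n_neut <- vapply(neut, function(r) nrow(r$records), integer(1))
  expect_lt(mean(n_sweep), 0.5 * mean(n_neut))
  # scans stay well-defined on swept data
  for (r in sweeps[1:3]) {
    sc <- scan_sweep(r$records, G, spectra = spectra)
    expect_true(all(is.finite(sc$clr)) && all(sc$clr >= -1e-9))
  }
})
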