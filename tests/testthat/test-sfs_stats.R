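test_that("folding maps counts onto the minor-allele scale", {
  expect_identical(fold(7L, 10L), 3L)
  expect_identical(fold(5L, 10L), 5L)
  expect_identical(fold(0L, 10L), 0L)
  expect_identical(fold(c(1L, 9L, 10L), 10L), c(1L, 1L, 0L))
  expect_error(fold(11L, 10L), "\\[0, n\\]")
})

test_that("background spectrum is the normalized folded class tally", {
  rec <- make_records(seq_len(100),
                      rep(1:5, times = c(50, 30, 10, 6, 4)))
  G <- background_spectrum(rec)
  expect_equal(unname(G$G), c(0.5, 0.3, 0.1, 0.06, 0.04))
  G1 <- background_spectrum(make_records(5, 2))
  expect_equal(unname(G1$G), c(0, 1, 0, 0, 0))
  mixed <- rbind(make_records(1, 2, n = 10L), make_records(2, 2, n = 8L))
  expect_error(background_spectrum(mixed), "mixed sample sizes")
  expect_error(background_spectrum(rec[0, ]), "zero records")
})

test_that("smoothing keeps unobserved classes supported", {
  G <- background_spectrum(make_records(1:3, c(1, 1, 2)), smooth = 0.5)
  expect_true(all(G$G > 0))
  expect_equal(sum(G$G), 1)
})

test_that("hypergeometric projection matches hand and closed-form cases", {
  # n = 4, unfolded mass (0.6, 0.2, 0.2) on k = 1..3
  p <- c(0, 0.6, 0.2, 0.2, 0)
  P2 <- project_spectrum(p, 2L)
  expect_equal(P2[2L], 0.6 * 0.5 + 0.2 * (2 / 3) + 0.2 * 0.5,
               tolerance = 1e-15)
  # j = n is the identity
  expect_equal(project_spectrum(p, 4L), p, tolerance = 1e-15)
  # j = 1: P(a = 1) = sum_k p(k) k / n
  P1 <- project_spectrum(p, 1L)
  expect_equal(P1[2L], sum(p * (0:4) / 4), tolerance = 1e-15)
  expect_error(project_spectrum(p, 0L), "must lie in")
})

test_that("projection conserves mass, commutes, and matches enumeration", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(3:6, 1)
    p <- runif(n + 1)
    p <- p / sum(p)
    for (j in seq_len(n)) {
      Pj <- project_spectrum(p, j)
      expect_equal(sum(Pj), 1, tolerance = 1e-12)
      expect_equal(Pj, project_oracle(p, j), tolerance = 1e-12)
      for (m in seq_len(j)) {
        expect_equal(project_spectrum(Pj, m), project_spectrum(p, m),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("symmetrize/refold round-trips a folded spectrum", {
  G <- tiny_G()
  expect_equal(refold_spectrum(symmetrize_spectrum(G))$G, G$G,
               tolerance = 1e-15)
  # self-symmetric class keeps its whole mass
  sym <- symmetrize_spectrum(G)
  expect_equal(sym[6L], 0.04)
  expect_equal(sym[2L], 0.25)
  expect_equal(sum(sym), 1)
})

test_that("SNP windows advance by the step and drop partial windows", {
  rec <- make_records(seq(100, by = 100, length.out = 20), rep(1L, 20))
  w <- snp_windows(rec, 10L, 5L)
  expect_equal(nrow(w), 3L)
  expect_equal(w$first, c(1L, 6L, 11L))
  expect_equal(w$last, c(10L, 15L, 20L))
  expect_equal(w$center, (w$start + w$end) / 2)
  expect_equal(nrow(snp_windows(rec[1:9, ], 10L, 5L)), 0L)
  expect_equal(nrow(snp_windows(rec[1:10, ], 10L, 5L)), 1L)
})

test_that("spectrum files round-trip", {
  G <- tiny_G()
  f <- withr::local_tempfile()
  write_spect_file(G, f)
  expect_equal(read_spect_file(f, 10L)$G, G$G, tolerance = 1e-12)
})
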