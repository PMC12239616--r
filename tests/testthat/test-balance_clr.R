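test_that("balanced-class spectrum is a folded binomial around x_eq", {
  f5 <- balanced_class_spectrum(0.5, 10L)
  expect_equal(sum(f5$G), 1, tolerance = 1e-12)
  # intermediate classes dominate rare ones (folding merges k and n - k, so
  # the folded mode sits at class 4 for x_eq = 0.5, n = 10)
  expect_gt(f5$G[[5L]], f5$G[[1L]])
  expect_equal(unname(which.max(f5$G)), 4L)
  k <- 1:5
  ref5 <- dbinom(k, 10, 0.5) + ifelse(k == 5, 0, dbinom(k, 10, 0.5))
  expect_equal(unname(f5$G), ref5 / sum(ref5), tolerance = 1e-12)
  f1 <- balanced_class_spectrum(0.1, 10L)
  expect_gt(f1$G[[1L]], f1$G[[5L]])
  # direct binomial evaluation
  k <- 1:5
  ref <- dbinom(k, 10, 0.1) + ifelse(k == 5, 0, dbinom(k, 10, 0.9))
  expect_equal(unname(f1$G), ref / sum(ref), tolerance = 1e-12)
  expect_error(balanced_class_spectrum(0.6, 10L), "\\(0, 0.5\\]")
  expect_error(balanced_class_spectrum(0, 10L), "\\(0, 0.5\\]")
})

test_that("the A -> infinity limit collapses the mixture onto the null", {
  G <- tiny_G()
  set.seed(13)
  rec <- make_records(seq(1000, by = 50, length.out = 10),
                      draw_classes(G, 10))
  out <- b0maf_window(rec, mean(range(rec$position)), G,
                      grids = list(x = seq(0.05, 0.5, 0.05), A = Inf))
  expect_equal(out$clr, 0, tolerance = 1e-12)
})

test_that("intermediate-frequency windows score high with xhat = 0.5", {
  G <- tiny_G()
  rec <- make_records(seq(1000, by = 50, length.out = 100), rep(5L, 100))
  out <- b0maf_window(rec, mean(range(rec$position)), G)
  expect_gt(out$clr, 0)
  expect_equal(out$xhat, 0.5)
  # window made of the background's modal class drives xhat to the lowest
  # grid value
  rec1 <- make_records(seq(1000, by = 50, length.out = 100), rep(1L, 100))
  out1 <- b0maf_window(rec1, mean(range(rec1$position)), G)
  expect_equal(out1$xhat, 0.05)
})

test_that("grid-evaluation oracle reproduces the window CLR", {
  G <- tiny_G()
  set.seed(14)
  rec <- make_records(sort(sample.int(2e4, 10)), draw_classes(G, 10))
  center <- mean(range(rec$position))
  grids <- default_balance_grids()
  r <- 1e-8
  # direct R evaluation of the mixture likelihood surface
  L0 <- sum(log(G$G[rec$x]))
  best <- L0
  for (A in grids$A) {
    w <- if (is.infinite(A)) rep(0, 10) else {
      exp(-A * r * abs(rec$position - center))
    }
    for (x in grids$x) {
      fB <- balanced_class_spectrum(x, 10L)$G
      L1 <- sum(log(w * fB[rec$x] + (1 - w) * G$G[rec$x]))
      best <- max(best, L1)
    }
  }
  expect_equal(b0maf_window(rec, center, G)$clr, 2 * (best - L0),
               tolerance = 1e-9)
})

test_that("windowed scans cover the chromosome deterministically", {
  G <- tiny_G()
  set.seed(15)
  rec <- make_records(sort(sample.int(1e5, 20)), draw_classes(G, 20))
  sc <- scan_balancing(rec, 10L, 5L, G)
  expect_equal(nrow(sc), 3L)
  expect_true(all(sc$clr >= -1e-9))
  expect_identical(sc, scan_balancing(rec, 10L, 5L, G))
  expect_equal(nrow(scan_balancing(rec[1:9, ], 10L, 5L, G)), 0L)
})

test_that("CLR is non-negative and ~0 for unlinked background windows", {
  set.seed(16)
  for (i in 1:25) {
    g <- runif(5) + 0.05
    G <- folded_sfs(g / sum(g), 10L)
    m <- sample(c(10L, 20L), 1)
    rec <- make_records(sort(sample.int(1e6, m)), draw_classes(G, m))
    sc <- scan_balancing(rec, 10L, 5L, G)
    expect_true(all(sc$clr >= -1e-9))
  }
  # sites spread so far apart that every finite A gives zero weight
  G <- tiny_G()
  rec <- data.frame(position = seq(1, by = 1e13, length.out = 10),
                    x = draw_classes(G, 10), n = 10L, folded = TRUE)
  sc <- scan_balancing(rec, 10L, 5L, G)
  expect_lt(max(abs(sc$clr)), 1e-6)
})
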