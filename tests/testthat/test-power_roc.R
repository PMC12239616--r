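test_that("replicate scores aggregate windowed maxima", {
  one <- data.frame(position = 50, clr = 7)
  expect_equal(replicate_score(one, 100), 7)
  sc <- data.frame(position = c(10, 150, 950), clr = c(1, 5, 3))
  expect_equal(replicate_score(sc, 100), 5)
  # refining the window subdivision cannot change the max of a signal
  expect_equal(replicate_score(sc, 100), replicate_score(sc, 10))
  # monotone under adding a higher-CLR record
  sc2 <- rbind(sc, data.frame(position = 500, clr = 9))
  expect_gte(replicate_score(sc2, 100), replicate_score(sc, 100))
  expect_equal(replicate_score(sc[0, ], 100), -Inf)
})

test_that("ROC curves honor separation, ties and the pairwise oracle", {
  perfect <- roc_curve(c(2, 3), c(0, 1))
  expect_equal(roc_auc(perfect), 1)
  expect_equal(power_at_fpr(perfect, 0), 1)
  same <- roc_curve(c(1, 2, 3), c(1, 2, 3))
  expect_equal(roc_auc(same), 0.5)
  # Mann-Whitney pairwise count: {1,3} vs {2} -> one win, one loss
  mid <- roc_curve(c(1, 3), 2)
  expect_equal(roc_auc(mid), 0.5)
  # curve invariants: monotone, anchored at (0,0) and (1,1)
  set.seed(10)
  for (i in 1:5) {
    rc <- roc_curve(rnorm(20, 1), rnorm(15))
    expect_true(all(diff(rc$fpr) >= 0))
    expect_true(all(diff(rc$tpr) >= 0))
    expect_equal(rc$fpr[1], 0)
    expect_equal(rc$tpr[1], 0)
    expect_equal(rc$fpr[nrow(rc)], 1)
    expect_equal(rc$tpr[nrow(rc)], 1)
  }
})

test_that("the power grid is reproducible and structured per scenario", {
  model <- default_demography()
  arch <- build_architecture()
  dfe <- dfe_config()
  scen <- list(selection_scenario("sweep", twoNs = 10000, tau = 0.1))
  g1 <- power_grid(scen, model, arch, dfe, n_reps = 2L, Q = 200,
                   seed = 3L, window_bp = c(1000, 10000))
  g2 <- power_grid(scen, model, arch, dfe, n_reps = 2L, Q = 200,
                   seed = 3L, window_bp = c(1000, 10000))
  expect_equal(g1[[1]]$curves, g2[[1]]$curves)
  expect_named(g1[[1]]$curves, c("bp1000", "bp10000"))
  for (rc in g1[[1]]$curves) {
    expect_s3_class(rc, "roc_curve")
    expect_true(all(diff(rc$fpr) >= 0))
  }
})

test_that("an infeasible scenario is recorded as an absent panel", {
  model <- default_demography()
  arch <- build_architecture()
  dfe <- dfe_config(c(1, 0, 0, 0))
  scen <- list(selection_scenario("sweep", twoNs = 100, tau = 0.1))
  g <- power_grid(scen, model, arch, dfe, n_reps = 2L, Q = 100, seed = 4L,
                  max_restarts = 10L)
  expect_null(g[[1]]$curves)
  expect_equal(g[[1]]$n_feasible, 0L)
})
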