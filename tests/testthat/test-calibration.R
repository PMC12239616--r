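test_that("the null threshold is the maximum over pooled replicates", {
  expect_equal(null_threshold(c(1.2, 5.3, 3.1)), 5.3)
  expect_equal(null_threshold(list(c(1.2, 5.3), 3.1)), 5.3)
  expect_error(null_threshold(numeric()), "no CLR")
  # non-decreasing in the replicate set
  set.seed(8)
  vals <- replicate(10, runif(20), simplify = FALSE)
  th <- vapply(seq_along(vals),
               function(k) null_threshold(vals[seq_len(k)]), numeric(1))
  expect_true(all(diff(th) >= 0))
  th2 <- null_thresholds(list(sweep = c(1, 2), b10 = c(5, 1)))
  expect_equal(th2, c(sweep = 2, b10 = 5))
})

test_that("candidate calling is a strict greater-than filter", {
  scan <- data.frame(position = 1:3, clr = c(1, 6, 6.0001))
  expect_equal(nrow(call_candidates(scan, 6)), 1L)
  expect_equal(call_candidates(scan, 6)$position, 3L)
  expect_equal(nrow(call_candidates(scan[0, ], 6)), 0L)
  expect_equal(nrow(call_candidates(scan, max(scan$clr))), 0L)
})

test_that("gene overlap uses closed intervals for points and windows", {
  genes <- data.frame(chrom = "chr1", start = 100L, end = 200L,
                      gene_id = "geneA")
  hit <- overlap_genes(data.frame(position = 150, clr = 10), genes)
  expect_equal(hit$hit, "geneA")
  none <- overlap_genes(data.frame(position = 201, clr = 10), genes)
  expect_equal(nrow(none), 0L)
  win <- overlap_genes(data.frame(start = 90L, end = 110L, clr = 10), genes)
  expect_equal(win$hit, "geneA")
})

test_that("SV overlap reproduces the inversion-window case", {
  svs <- data.frame(chrom = "scaffold1", start = 315972759L,
                    end = 316062009L, sv_class = "inversion")
  cand <- data.frame(start = 315975047L, end = 315981365L, clr = 300)
  expect_equal(overlap_svs(cand, svs)$hit, "inversion")
  expect_equal(nrow(overlap_svs(data.frame(start = 1L, end = 100L, clr = 1),
                                svs)), 0L)
  nested <- data.frame(start = 315980000L, end = 315980100L, clr = 1)
  expect_equal(nrow(overlap_svs(nested, svs)), 1L)
})

test_that("the empirical-tail comparator flags the expected fraction", {
  out <- empirical_tail_quantile(data.frame(clr = 1:100), 0.05)
  expect_equal(out$n_candidates, 5L)
  out2 <- empirical_tail_quantile(1:10, 0.5)
  expect_equal(out2$n_candidates, 5L)
  expect_error(empirical_tail_quantile(1:10, 0), "q > 0")
})

test_that("thresholds are conservative on their own training set", {
  set.seed(9)
  scans <- replicate(20, data.frame(position = 1:50, clr = rexp(50, 0.5)),
                     simplify = FALSE)
  th <- null_threshold(lapply(scans, `[[`, "clr"))
  n_cand <- sum(vapply(scans, function(s) nrow(call_candidates(s, th)),
                       integer(1)))
  expect_equal(n_cand, 0L)
})
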