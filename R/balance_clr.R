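#' Expected folded spectrum at a balanced polymorphism
#'
#' Folded binomial spectrum around the equilibrium minor-allele frequency
#' `x_eq`: `f_B(k)` proportional to `Binom(k; n, x_eq) + Binom(k; n,
#' 1 - x_eq)` for `k < n/2` and the single symmetric term for `k = n/2`,
#' restricted to polymorphic folded classes and renormalized.
#'
#' @param x_eq Equilibrium minor-allele frequency in `(0, 0.5]`.
#' @param n Sample size in chromosomes.
#' @return A [folded_sfs()].
#' @export
balanced_class_spectrum <- function(x_eq, n) {
  if (x_eq <= 0 || x_eq > 0.5) stop("x_eq must lie in (0, 0.5]")
  K <- n %/% 2L
  k <- seq_len(K)
  f <- dbinom(k, n, x_eq) + ifelse(2L * k == n, 0, dbinom(k, n, 1 - x_eq))
  folded_sfs(f / sum(f), n)
}

#' Default grids for the balancing-selection scan
#'
#' Equilibrium frequencies `0.05, 0.10, ..., 0.50` and a log-spaced
#' linkage-decay grid on the per-morgan scale, with an infinite value
#' appended so the neutral model is always nested in the alternative.
#'
#' @param n_A Number of finite linkage-decay grid points (default 21).
#' @return List with elements `x` and `A`.
#' @export
default_balance_grids <- function(n_A = 21L) {
  list(x = seq(0.05, 0.5, by = 0.05),
       A = c(exp(seq(log(1e-2), log(1e6), length.out = n_A)), Inf))
}

#' Balancing-selection CLR for one SNP window
#'
#' Mixture composite likelihood over the `W` member SNPs: site `i` at
#' distance `d_i` from the window center mixes the balanced-class spectrum
#' `f_B` (weight `exp(-A r d_i)`) with the background `G`. The CLR is
#' `2 [max_{x, A} L1 - L0]`; the `A -> Inf` limit collapses onto the
#' background, so the CLR is non-negative.
#'
#' @param records Allele-frequency data frame of the window members only.
#' @param center Window center position (bp).
#' @param G Background [folded_sfs()].
#' @param grids Parameter grids from [default_balance_grids()].
#' @param r Recombination rate per bp used to convert physical distance to
#'   map distance (default 1e-8).
#' @return One-row data frame with `center`, `clr`, `xhat`, `Ahat`.
#' @export
b0maf_window <- function(records, center, G, grids = default_balance_grids(),
                         r = 1e-8) {
  check_background_support(records, G)
  n <- G$n
  fB <- t(vapply(grids$x, function(x) balanced_class_spectrum(x, n)$G,
                 numeric(n %/% 2L)))
  res <- balance_scan_cpp(as.numeric(records$position),
                          as.integer(records$x), unname(G$G),
                          1L, nrow(records), center, fB,
                          grids$x, grids$A, r)
  data.frame(center = res$center, clr = res$clr, xhat = res$xhat,
             Ahat = res$Ahat)
}

#' Genome scan for balancing selection over SNP-count windows
#'
#' Applies the window CLR to every full window of `W` consecutive SNPs with
#' step `S` (the study's schemes: 10/5 and 100/50).
#'
#' @param records Allele-frequency data frame (whole chromosome).
#' @param W Window size in SNPs.
#' @param S Step size in SNPs.
#' @inheritParams b0maf_window
#' @return Data frame with one row per window: `center`, `clr`, `xhat`,
#'   `Ahat`, plus window spans `start`, `end`. Zero rows when fewer than
#'   `W` SNPs.
#' @export
scan_balancing <- function(records, W, S, G,
                           grids = default_balance_grids(), r = 1e-8) {
  records <- records[order(records$position), , drop = FALSE]
  win <- snp_windows(records, W, S)
  if (nrow(win) == 0L) {
    return(data.frame(center = numeric(), clr = numeric(),
                      xhat = numeric(), Ahat = numeric(),
                      start = integer(), end = integer()))
  }
  check_background_support(records, G)
  n <- G$n
  fB <- t(vapply(grids$x, function(x) balanced_class_spectrum(x, n)$G,
                 numeric(n %/% 2L)))
  res <- balance_scan_cpp(as.numeric(records$position),
                          as.integer(records$x), unname(G$G),
                          win$first, win$last, win$center, fB,
                          grids$x, grids$A, r)
  data.frame(center = res$center, clr = res$clr, xhat = res$xhat,
             Ahat = res$Ahat, start = win$start, end = win$end)
}
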