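#' Escape probability of a lineage from a sweeping haplotype
#'
#' The chance that a sampled lineage at distance `d` from the selected site
#' recombines off the sweeping haplotype before coalescing into it, under
#' the composite sweep-intensity parameter `alpha` (per bp; absorbs
#' recombination rate and sweep strength/duration).
#'
#' @param alpha Sweep intensity, `> 0`.
#' @param d Distance in bp, `>= 0`.
#' @return `1 - exp(-alpha * d)`, clamped to `[1e-12, 1]`.
#' @export
escape_probability <- function(alpha, d) {
  stopifnot(all(alpha > 0), all(d >= 0))
  pmin(1, pmax(1e-12, -expm1(-alpha * d)))
}

#' Sweep-perturbed folded spectrum
#'
#' The expected folded SFS at a site whose lineages each escape the sweep
#' independently with probability `p_e`, starting from the (symmetrized)
#' background spectrum. Of `n` sampled lineages, `e ~ Binomial(n, p_e)`
#' escape; the non-escaped lineages coalesce into one ancestral lineage at
#' the sweep, so the ancestral sample has `j = e + 1` lineages whose derived
#' count `a` follows the background projected to size `j`. The swept-class
#' ancestor is one of the `j` uniformly; if it is derived (probability
#' `a / j`) the observed derived count is `a - 1 + (n - e)`, otherwise `a`.
#' The result is folded, conditioned on polymorphism and renormalized.
#'
#' @param G Background [folded_sfs()].
#' @param p_e Escape probability in `(0, 1]`.
#' @return A [folded_sfs()] for the same `n`.
#' @export
sweep_spectrum <- function(G, p_e) {
  stopifnot(inherits(G, "folded_sfs"), p_e > 0, p_e <= 1)
  n <- G$n
  sym <- symmetrize_spectrum(G)
  out <- numeric(n + 1L)
  we <- dbinom(0:n, n, p_e)
  for (e in 0:n) {
    if (we[e + 1L] == 0) next
    if (e == n) {
      out <- out + we[e + 1L] * sym
      next
    }
    j <- e + 1L
    P <- project_spectrum(sym, j)
    for (a in 0:j) {
      if (P[a + 1L] == 0) next
      w <- we[e + 1L] * P[a + 1L]
      p_der <- a / j
      if (p_der > 0) {
        obs <- a - 1L + (n - e)
        out[obs + 1L] <- out[obs + 1L] + w * p_der
      }
      out[a + 1L] <- out[a + 1L] + w * (1 - p_der)
    }
  }
  refold_spectrum(out, drop_monomorphic = TRUE)
}

#' Default log-spaced sweep-intensity grid
#'
#' @param n_points Number of grid points (default 48).
#' @param lo,hi Range in per-bp units (default `1e-8` to `1e-1`). The
#'   neutral limit (CLR 0) is always part of the maximization.
#' @return Numeric vector.
#' @export
default_alpha_grid <- function(n_points = 48L, lo = 1e-8, hi = 1e-1) {
  exp(seq(log(lo), log(hi), length.out = n_points))
}

# Precompute log sweep spectra over a log-spaced grid of u = alpha * d.
# Returns the binning parameters consumed by the C++ scan core.
sweep_model_spectra <- function(G, n_bins = 256L, u_min = 1e-9,
                                u_max = 20) {
  u <- exp(seq(log(u_min), log(u_max), length.out = n_bins))
  K <- length(G$G)
  logP <- matrix(NA_real_, n_bins, K)
  for (i in seq_len(n_bins)) {
    pe <- escape_probability(1, u[i])
    logP[i, ] <- log(sweep_spectrum(G, pe)$G)
  }
  list(log_u0 = log(u_min),
       dlog = (log(u_max) - log(u_min)) / (n_bins - 1L),
       logP = logP, u = u)
}

check_background_support <- function(records, G) {
  gx <- G$G[records$x]
  if (any(!is.finite(gx) | gx <= 0)) {
    stop("background spectrum assigns zero probability to an observed ",
         "class; smooth the spectrum (see background_spectrum(smooth=))")
  }
  gx
}

#' Sweep CLR at a single test position
#'
#' Exact (unbinned) evaluation of the composite likelihood ratio
#' `2 [max_alpha sum_i log P_{alpha, d_i}(x_i) - sum_i log G(x_i)]`, with
#' the neutral limit included in the maximization so the CLR is
#' non-negative.
#'
#' @param t Test position in bp.
#' @param records Allele-frequency data frame (sorted positions).
#' @param G Background [folded_sfs()].
#' @param alpha_grid Sweep-intensity grid (default [default_alpha_grid()]).
#' @param cutoff Sites with `alpha * d > cutoff` (default 20) are treated as
#'   exactly background.
#' @return One-row data frame with `position`, `clr`, `alpha`.
#' @export
sweep_clr_at <- function(t, records, G, alpha_grid = default_alpha_grid(),
                         cutoff = 20) {
  if (nrow(records) == 0L) stop("no records")
  gx <- check_background_support(records, G)
  loggx <- log(gx)
  d <- abs(records$position - t)
  best <- 0
  best_a <- NA_real_
  for (al in alpha_grid) {
    use <- which(al * d <= cutoff)
    if (length(use) == 0L) next
    s <- 0
    for (i in use) {
      pe <- escape_probability(al, d[i])
      sp <- sweep_spectrum(G, pe)
      s <- s + log(sp$G[records$x[i]]) - loggx[i]
    }
    if (s > best) {
      best <- s
      best_a <- al
    }
  }
  data.frame(position = t, clr = 2 * best, alpha = best_a)
}

#' Genome scan for completed selective sweeps
#'
#' Evaluates the sweep CLR at every SNP position (or a supplied grid) using
#' precomputed sweep spectra on a fine log grid of `alpha * d`.
#'
#' @inheritParams sweep_clr_at
#' @param grid Test positions; default every SNP position.
#' @param spectra Optional precomputed result of the internal spectrum
#'   tabulation, reused across replicates scanned against the same `G`.
#' @return Data frame with columns `position`, `clr`, `alpha`, one row per
#'   test position.
#' @export
scan_sweep <- function(records, G, grid = NULL,
                       alpha_grid = default_alpha_grid(), cutoff = 20,
                       spectra = NULL) {
  records <- records[order(records$position), , drop = FALSE]
  if (is.null(grid)) grid <- records$position
  if (length(grid) == 0L) stop("empty test-position grid")
  check_background_support(records, G)
  if (is.null(spectra)) spectra <- sweep_model_spectra(G)
  res <- sweep_scan_cpp(as.numeric(records$position),
                        as.integer(records$x), log(unname(G$G)),
                        as.numeric(grid), alpha_grid,
                        spectra$log_u0, spectra$dlog, spectra$logP, cutoff)
  data.frame(position = res$position, clr = res$clr, alpha = res$alpha)
}
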