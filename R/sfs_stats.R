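#' Fold an allele count
#'
#' Maps a derived/alternate allele count onto the minor-allele (folded) scale,
#' as used when ancestral states are unknown.
#'
#' @param k Allele count(s), integer in `[0, n]`.
#' @param n Sample size in chromosomes.
#' @return `min(k, n - k)`, vectorized over `k`.
#' @export
#' @examples
#' fold(7, 10)  # 3
fold <- function(k, n) {
  stopifnot(length(n) == 1L, n >= 1)
  if (any(k < 0 | k > n)) {
    stop("allele count k must lie in [0, n]")
  }
  pmin(k, n - k)
}

#' Construct a folded site frequency spectrum object
#'
#' @param probs Numeric vector of probabilities for folded classes
#'   `1..floor(n/2)`.
#' @param n Sample size in chromosomes.
#' @return An object of class `folded_sfs` with fields `n` and `G`
#'   (probabilities named by class).
#' @export
folded_sfs <- function(probs, n) {
  K <- n %/% 2L
  if (length(probs) != K) {
    stop("expected ", K, " folded classes for n = ", n)
  }
  if (any(probs < 0)) stop("spectrum probabilities must be non-negative")
  s <- sum(probs)
  if (abs(s - 1) > 1e-12) stop("spectrum probabilities must sum to 1")
  structure(list(n = as.integer(n), G = setNames(as.numeric(probs), seq_len(K))),
            class = "folded_sfs")
}

#' @export
print.folded_sfs <- function(x, ...) {
  cat("Folded SFS (n =", x$n, "chromosomes)\n")
  print(round(x$G, 6))
  invisible(x)
}

#' Empirical background spectrum from pooled polymorphic sites
#'
#' Tallies folded minor-allele counts across all supplied sites into the
#' genome-wide background ("SpectFile") spectrum used as the null model by
#' both scan statistics.
#'
#' @param records Data frame of allele-frequency records with columns
#'   `position`, `x`, `n`, `folded` (see [read_freq_file()]); rows may pool
#'   many chromosomes.
#' @param smooth Pseudo-count added to every folded class before
#'   normalization. The default 0 reproduces the plain empirical proportions;
#'   set a small positive value (e.g. 0.5) when classes may be unobserved,
#'   since the scan likelihoods require `G(k) > 0` for every observed class.
#' @return A [folded_sfs()] object.
#' @export
background_spectrum <- function(records, smooth = 0) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("cannot estimate a spectrum from zero records")
  }
  n <- unique(records$n)
  if (length(n) != 1L) {
    stop("mixed sample sizes in records: ", paste(n, collapse = ", "))
  }
  K <- n %/% 2L
  counts <- tabulate(records$x, nbins = K)
  probs <- (counts + smooth) / sum(counts + smooth)
  folded_sfs(probs, n)
}

#' Symmetrize a folded spectrum to the unfolded scale
#'
#' Splits each folded class's mass equally between derived counts `k` and
#' `n - k` (self-symmetric class `n/2` kept whole). Used to bridge folded
#' data into generative models defined on derived alleles.
#'
#' @param sfs A [folded_sfs()] object.
#' @return Numeric vector of length `n + 1` over derived counts `0..n`
#'   (monomorphic entries zero).
#' @export
symmetrize_spectrum <- function(sfs) {
  n <- sfs$n
  p <- numeric(n + 1L)
  for (k in seq_along(sfs$G)) {
    if (2L * k == n) {
      p[k + 1L] <- sfs$G[[k]]
    } else {
      p[k + 1L] <- p[k + 1L] + sfs$G[[k]] / 2
      p[n - k + 1L] <- p[n - k + 1L] + sfs$G[[k]] / 2
    }
  }
  p
}

#' Re-fold an unfolded spectrum
#'
#' @param p Numeric vector over derived counts `0..n` (length `n + 1`).
#' @param drop_monomorphic Drop classes 0 and `n` and renormalize over the
#'   polymorphic folded classes (default `TRUE`).
#' @return A [folded_sfs()] object if `drop_monomorphic`, otherwise a vector
#'   over folded classes `0..floor(n/2)`.
#' @export
refold_spectrum <- function(p, drop_monomorphic = TRUE) {
  n <- length(p) - 1L
  K <- n %/% 2L
  folded <- numeric(K + 1L)
  for (k in 0:n) {
    f <- min(k, n - k)
    folded[f + 1L] <- folded[f + 1L] + p[k + 1L]
  }
  if (!drop_monomorphic) {
    return(folded)
  }
  poly <- folded[-1L]
  mass <- sum(poly)
  if (mass < 1e-300) stop("degenerate spectrum: no polymorphic mass left")
  folded_sfs(poly / mass, n)
}

#' Hypergeometric projection of an unfolded spectrum to a smaller sample
#'
#' Computes the spectrum expected in a subsample of `j` of the `n`
#' chromosomes: `P_j(a) = sum_k G(k) C(k,a) C(n-k, j-a) / C(n,j)`.
#'
#' @param p Numeric vector over derived counts `0..n` (length `n + 1`).
#' @param j Subsample size, `1 <= j <= n`.
#' @return Numeric vector over derived counts `0..j` (length `j + 1`),
#'   including monomorphic mass at 0 and `j`.
#' @export
project_spectrum <- function(p, j) {
  n <- length(p) - 1L
  if (j < 1L || j > n) stop("subsample size j must lie in [1, n]")
  out <- numeric(j + 1L)
  for (k in 0:n) {
    if (p[k + 1L] == 0) next
    a <- 0:j
    out <- out + p[k + 1L] * dhyper(a, k, n - k, j)
  }
  out
}

#' Partition sorted SNPs into fixed-SNP-count sliding windows
#'
#' Windows contain exactly `W` consecutive SNPs and advance by `S` SNPs;
#' trailing partial windows are dropped. The reported window position is the
#' physical midpoint of the first and last member SNP.
#'
#' @param records Data frame with a sorted `position` column.
#' @param W Window size in SNPs (`>= 2`).
#' @param S Step size in SNPs (`1 <= S <= W`).
#' @return Data frame with columns `first`, `last` (row indices into
#'   `records`), `start`, `end` (bp of first/last member) and `center`
#'   (physical midpoint, bp). Zero rows when fewer than `W` SNPs.
#' @export
snp_windows <- function(records, W, S) {
  stopifnot(W >= 2L, S >= 1L, S <= W)
  m <- nrow(records)
  if (is.unsorted(records$position, strictly = TRUE)) {
    stop("record positions must be strictly increasing")
  }
  if (m < W) {
    return(data.frame(first = integer(), last = integer(),
                      start = integer(), end = integer(), center = numeric()))
  }
  first <- seq.int(1L, m - W + 1L, by = S)
  last <- first + W - 1L
  start <- records$position[first]
  end <- records$position[last]
  data.frame(first = first, last = last, start = start, end = end,
             center = (start + end) / 2)
}

#' Write a spectrum file ("SpectFile")
#'
#' Two whitespace-separated columns: folded class and probability.
#'
#' @param sfs A [folded_sfs()] object.
#' @param path Output file path.
#' @export
write_spect_file <- function(sfs, path) {
  df <- data.frame(class = as.integer(names(sfs$G)), prob = unname(sfs$G))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a spectrum file written by [write_spect_file()]
#'
#' @param path File path.
#' @param n Sample size in chromosomes the spectrum refers to.
#' @return A [folded_sfs()] object.
#' @export
read_spect_file <- function(path, n) {
  df <- read.table(path, header = TRUE)
  K <- n %/% 2L
  if (nrow(df) != K || !identical(as.integer(df[[1L]]), seq_len(K))) {
    stop("spectrum file does not cover folded classes 1..", K)
  }
  folded_sfs(df[[2L]] / sum(df[[2L]]), n)
}
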