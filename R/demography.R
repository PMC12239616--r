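#' Piecewise-constant demographic history
#'
#' Epochs are given looking backward in time: the first epoch starts at 0
#' generations before sampling, and each later epoch starts further in the
#' past. Sizes are diploid effective sizes.
#'
#' @param sizes Integer vector of diploid sizes, one per epoch.
#' @param starts Numeric vector of epoch start times (generations before
#'   sampling), same length as `sizes`; `starts[1]` must be 0 and the vector
#'   strictly increasing.
#' @return Object of class `piecewise_demography`.
#' @export
piecewise_demography <- function(sizes, starts) {
  if (length(sizes) != length(starts) || length(sizes) < 1L) {
    stop("sizes and starts must be non-empty and of equal length")
  }
  if (starts[1L] != 0) stop("most recent epoch must start at 0")
  if (is.unsorted(starts, strictly = TRUE)) {
    stop("epoch start times must be strictly increasing backward in time")
  }
  if (any(sizes <= 0) || any(sizes != floor(sizes))) {
    stop("all epoch sizes must be positive integers")
  }
  structure(list(sizes = as.numeric(sizes), starts = as.numeric(starts)),
            class = "piecewise_demography")
}

#' @export
print.piecewise_demography <- function(x, ...) {
  cat("Piecewise-constant demography (", length(x$sizes), " epochs)\n", sep = "")
  print(data.frame(start_gen = x$starts, diploid_size = x$sizes))
  invisible(x)
}

#' Default three-epoch aye-aye-like demography
#'
#' Ancestral diploid size 23,706, an ancient ~5-fold reduction dated to
#' about 4,000 years ago, and a recent collapse over the last few decades.
#' Only the ancestral size is an inferred published value; the reduction
#' sizes, dates and the generation time are configurable stand-ins chosen to
#' reproduce the qualitative bottleneck shape (NOT inferred values from this
#' study's source model, whose epoch parameters are not published here).
#'
#' @param ancestral Ancestral diploid size (default 23706).
#' @param ancient_size Diploid size after the ancient reduction (default
#'   4741, i.e. ~0.2x ancestral; stand-in value).
#' @param ancient_years Years before sampling of the ancient reduction
#'   (default 4000).
#' @param recent_size Present-day diploid size (default 1000; stand-in).
#' @param recent_years Years before sampling of the recent collapse
#'   (default 30).
#' @param generation_time Years per generation (default 5; configurable,
#'   not published in this study).
#' @return A [piecewise_demography()].
#' @export
default_demography <- function(ancestral = 23706, ancient_size = 4741,
                               ancient_years = 4000, recent_size = 1000,
                               recent_years = 30, generation_time = 5) {
  piecewise_demography(
    sizes = c(recent_size, ancient_size, ancestral),
    starts = c(0, recent_years / generation_time,
               ancient_years / generation_time)
  )
}

#' Constant-size demography
#'
#' @param N Diploid size.
#' @return A [piecewise_demography()] with a single epoch.
#' @export
constant_demography <- function(N) piecewise_demography(N, 0)

#' Simulate one neutral chromosome replicate
#'
#' Draws a sample of `n_chrom` chromosomes under the SMC' coalescent with the
#' given piecewise-constant demography, drops mutations at infinite-sites
#' intensity onto integer positions (duplicate positions rejected), folds
#' allele counts and keeps polymorphic sites only.
#'
#' @param model A [piecewise_demography()].
#' @param L Chromosome length in bp.
#' @param mu Mutation rate per bp per generation (default 1.52e-8).
#' @param r Recombination rate per bp per generation (default 1e-8,
#'   i.e. 1 cM/Mb).
#' @param n_chrom Number of sampled chromosomes (default 10 = 5 diploids).
#' @param seed Integer seed (required; replicates are bit-stable for a fixed
#'   seed).
#' @param genotypes Also return the 0/1 haplotype-by-site matrix (default
#'   `FALSE`).
#' @return List of class `neutral_replicate` with elements `records` (folded
#'   allele-frequency data frame, see [read_freq_file()]), `L`, `mu`, `r`,
#'   `seed` and optionally `genotypes` (rows = haplotypes; columns line up
#'   with `records`).
#' @export
neutral_chromosome_replicate <- function(model, L, mu = 1.52e-8, r = 1e-8,
                                         n_chrom = 10L, seed,
                                         genotypes = FALSE) {
  stopifnot(inherits(model, "piecewise_demography"), L >= 1,
            mu >= 0, r >= 0, n_chrom >= 2L)
  if (missing(seed)) stop("a seed is required for reproducibility")
  set.seed(seed)
  sim <- smc_replicate_cpp(model$starts, model$sizes, L, mu, r,
                           as.integer(n_chrom), genotypes)
  x <- fold(sim$derived_count, n_chrom)
  poly <- which(x >= 1L)
  records <- data.frame(position = sim$position[poly],
                        x = as.integer(x[poly]),
                        n = rep(as.integer(n_chrom), length(poly)),
                        folded = rep(TRUE, length(poly)))
  out <- list(records = records, L = L, mu = mu, r = r, seed = seed)
  if (genotypes) {
    out$genotypes <- sim$genotypes[, poly, drop = FALSE]
  }
  structure(out, class = "neutral_replicate")
}

#' Mean pairwise diversity per site of a replicate
#'
#' Computes nucleotide diversity (pi) per bp from folded counts:
#' `sum_i 2 x_i (n - x_i) / (n (n-1))`, divided by the sequence length.
#'
#' @param rep A `neutral_replicate` (or any list with `records` and `L`).
#' @return Numeric scalar.
#' @export
pairwise_diversity <- function(rep) {
  rec <- rep$records
  if (nrow(rec) == 0L) return(0)
  n <- rec$n[1L]
  sum(2 * rec$x * (n - rec$x) / (n * (n - 1))) / rep$L
}
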