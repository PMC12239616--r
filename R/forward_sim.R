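#' Build the simulated genomic architecture
#'
#' Tiles a chromosome with `n_genes` functional regions, each consisting of
#' `exons_per_gene` exons alternating with `exons_per_gene - 1` introns,
#' followed by one intergenic block per gene. With the default parameters
#' (3 genes of 9 x 130-bp exons separated by 1,591-bp introns, 16,489-bp
#' intergenic blocks) the total is 91,161 bp.
#'
#' @param n_genes Number of functional regions (default 3).
#' @param exons_per_gene Exons per region (default 9).
#' @param exon_len Exon length in bp (default 130).
#' @param intron_len Intron length in bp (default 1591).
#' @param intergenic_len Intergenic block length in bp (default 16489).
#' @return Object of class `genome_architecture`: a data frame with columns
#'   `class` (exon/intron/intergenic), `start`, `end` (1-based closed) tiling
#'   `[1, L]` without gaps, with attribute `L` (total length).
#' @export
build_architecture <- function(n_genes = 3L, exons_per_gene = 9L,
                               exon_len = 130L, intron_len = 1591L,
                               intergenic_len = 16489L) {
  if (n_genes < 1L) stop("need at least one gene")
  stopifnot(exons_per_gene >= 1L, exon_len >= 1L, intron_len >= 1L,
            intergenic_len >= 0L)
  cls <- character()
  len <- integer()
  for (g in seq_len(n_genes)) {
    for (e in seq_len(exons_per_gene)) {
      cls <- c(cls, "exon")
      len <- c(len, exon_len)
      if (e < exons_per_gene) {
        cls <- c(cls, "intron")
        len <- c(len, intron_len)
      }
    }
    if (intergenic_len > 0L) {
      cls <- c(cls, "intergenic")
      len <- c(len, intergenic_len)
    }
  }
  end <- cumsum(len)
  start <- end - len + 1L
  out <- data.frame(class = cls, start = start, end = end)
  attr(out, "L") <- end[length(end)]
  class(out) <- c("genome_architecture", "data.frame")
  out
}

#' Total length of a genome architecture
#' @param arch A [build_architecture()] object.
#' @return Length in bp.
#' @export
architecture_length <- function(arch) attr(arch, "L")

#' Discretized distribution of fitness effects
#'
#' Four fixed classes on the population-scaled scale: effectively neutral
#' `0 <= 2Ns < 1`, weakly deleterious `[1, 10)`, moderately deleterious
#' `[10, 100)` and strongly deleterious `[100, 2N)`; within each class
#' `2Ns` is uniform. The default class proportions follow discrete-class
#' DFE estimates published for humans and aye-ayes; they are external
#' defaults, not values inferred in this study, and should be treated as
#' configuration.
#'
#' @param proportions Numeric vector `(f0, f1, f2, f3)` summing to 1.
#' @param refN Reference diploid size for the `2Ns` scale (default 23706).
#' @param h Dominance coefficient (default 0.5).
#' @return Object of class `dfe_config`.
#' @export
dfe_config <- function(proportions = c(0.25, 0.49, 0.04, 0.22),
                       refN = 23706, h = 0.5) {
  if (length(proportions) != 4L) stop("need 4 class proportions")
  if (any(proportions < 0)) stop("DFE proportions must be non-negative")
  if (abs(sum(proportions) - 1) > 1e-12) {
    stop("DFE proportions must sum to 1")
  }
  structure(list(proportions = proportions,
                 lo = c(0, 1, 10, 100),
                 hi = c(1, 10, 100, 2 * refN),
                 refN = refN, h = h),
            class = "dfe_config")
}

#' Draw selection coefficients from the DFE
#'
#' @param config A [dfe_config()].
#' @param n Number of draws.
#' @return Data frame with columns `class` (0-3), `twoNs` and `s`
#'   (homozygote fitness reduction, `s = 2Ns / (2 refN)`; the
#'   negative-effect sign convention is applied by the simulator).
#' @export
sample_dfe <- function(config, n = 1L) {
  stopifnot(inherits(config, "dfe_config"))
  cls <- sample.int(4L, n, replace = TRUE, prob = config$proportions) - 1L
  twoNs <- config$lo[cls + 1L] +
    runif(n) * (config$hi[cls + 1L] - config$lo[cls + 1L])
  data.frame(class = cls, twoNs = twoNs, s = twoNs / (2 * config$refN))
}

#' Assign per-block mutation or recombination rates
#'
#' Each `block`-bp region receives its own rate, mimicking fine-scale rate
#' heterogeneity (hot and cold spots). Two modes: `"literal"` draws each
#' block rate from `Uniform(lo, hi)` as stated bounds; `"mean_matched"`
#' additionally rescales the draws (with clamping back into `[lo, hi]`) so
#' the realized chromosome-wide mean is within 1% of `target_mean`.
#'
#' @param L Chromosome length in bp.
#' @param block Block size in bp (default 1000).
#' @param target_mean Target chromosome-wide mean rate (used by
#'   `mean_matched`; also the constant value when `lo == hi`).
#' @param lo,hi Uniform bounds on the per-block rate.
#' @param mode `"literal"` or `"mean_matched"`.
#' @return Numeric vector of per-block rates, length `ceiling(L / block)`.
#' @export
assign_rate_map <- function(L, block = 1000L, target_mean, lo, hi,
                            mode = c("mean_matched", "literal")) {
  mode <- match.arg(mode)
  if (lo > hi) stop("lo must not exceed hi")
  nb <- ceiling(L / block)
  if (lo == hi) return(rep(lo, nb))
  r <- runif(nb, lo, hi)
  if (mode == "mean_matched") {
    if (target_mean < lo || target_mean > hi) {
      stop("target_mean outside [lo, hi]")
    }
    for (i in 1:50) {
      m <- mean(r)
      if (abs(m - target_mean) <= 0.01 * target_mean) break
      r <- pmin(hi, pmax(lo, r * target_mean / m))
    }
    if (abs(mean(r) - target_mean) > 0.01 * target_mean) {
      stop("mean-matched rescaling failed to converge")
    }
  }
  r
}

#' Frequency-dependent selection coefficient of a balanced allele
#'
#' `S_bp = F_eq - F_bp`: positive (favored) below the equilibrium frequency,
#' negative above it, zero at equilibrium.
#'
#' @param F_eq Equilibrium frequency of the balanced allele.
#' @param F_bp Current population frequency of the balanced allele.
#' @return `F_eq - F_bp`.
#' @export
frequency_dependent_coefficient <- function(F_eq, F_bp) {
  if (any(F_eq < 0 | F_eq > 1) || any(F_bp < 0 | F_bp > 1)) {
    stop("frequencies must lie in [0, 1]")
  }
  F_eq - F_bp
}

#' Define a selection scenario
#'
#' @param mode `"neutral"`, `"sweep"` or `"balancing"`.
#' @param twoNs Population-scaled selection coefficient of the beneficial
#'   mutation (sweep mode; study grid 100, 1000, 10000).
#' @param tau Introduction time of the selected mutation in units of `N`
#'   generations before sampling (sweep grid 0.1, 0.2, 0.5, 1, 2; balancing
#'   grid 10, 50, 75).
#' @param F_eq Equilibrium frequency of the balanced mutation (default 0.5).
#' @param sel_pos Position of the selected mutation in bp; default is the
#'   center of the middle gene's middle exon of the default architecture.
#' @param run_N Post-burn-in run length in units of `N` generations
#'   (default 10 for neutral/sweep, 85 for balancing).
#' @return Object of class `selection_scenario`.
#' @export
selection_scenario <- function(mode = c("neutral", "sweep", "balancing"),
                               twoNs = NULL, tau = NULL, F_eq = 0.5,
                               sel_pos = NULL, run_N = NULL) {
  mode <- match.arg(mode)
  if (mode == "sweep" && (is.null(twoNs) || is.null(tau))) {
    stop("sweep scenarios need twoNs and tau")
  }
  if (mode == "balancing" && is.null(tau)) {
    stop("balancing scenarios need tau")
  }
  if (is.null(run_N)) run_N <- if (mode == "balancing") 85 else 10
  if (mode != "neutral" && tau > run_N) {
    stop("tau must not exceed the post-burn-in run length")
  }
  structure(list(mode = mode, twoNs = twoNs, tau = tau, F_eq = F_eq,
                 sel_pos = sel_pos, run_N = run_N),
            class = "selection_scenario")
}

# center of the middle gene's middle exon
default_selected_position <- function(arch) {
  ex <- arch[arch$class == "exon", ]
  mid <- ex[ceiling(nrow(ex) / 2), ]
  as.integer((mid$start + mid$end) %/% 2)
}

#' Run one forward Wright-Fisher replicate
#'
#' Simulates the full demographic history forward in time: a `10N`
#' generation burn-in at the ancestral size, followed by `run_N * N`
#' generations over which the piecewise demography unfolds, with the
#' selected mutation (if any) introduced `tau * N` generations before
#' sampling. Replicates in which a sweep fails to fix by sampling, or a
#' balanced mutation fixes or is lost, restart from the saved
#' introduction-time state.
#'
#' @param model A [piecewise_demography()]; the last epoch is the ancestral
#'   size `N` used for time scaling.
#' @param arch A [build_architecture()] object.
#' @param dfe A [dfe_config()].
#' @param scenario A [selection_scenario()].
#' @param mu_map,rec_map Per-kb rate vectors from [assign_rate_map()]
#'   (unscaled, per bp per generation); scalars are recycled.
#' @param Q Rescaling factor (default 100): sizes and durations divided by
#'   `Q`, rates and selection coefficients multiplied by `Q`.
#' @param seed Integer seed (required).
#' @param n_sample_dip Diploid sample size (default 5).
#' @param max_restarts Restart cap before the scenario is declared
#'   infeasible (default 1000).
#' @param block Rate-map block size in bp (default 1000).
#' @param track_traj Record the selected-allele frequency each generation
#'   (default `FALSE`).
#' @return Object of class `simulation_result`: `records` (folded
#'   allele-frequency data frame), `genotypes` (haplotype-by-site 0/1
#'   matrix), `sel_pos`, `sel_state` (`"fixed"`, `"segregating"` or
#'   `"none"`), `sel_freq`, `restarts`, `Q`, `seed`, `L` and optionally
#'   `trajectory`.
#' @export
run_forward <- function(model, arch, dfe, scenario, mu_map = 1.52e-8,
                        rec_map = 1e-8, Q = 100, seed, n_sample_dip = 5L,
                        max_restarts = 1000L, block = 1000L,
                        track_traj = FALSE) {
  stopifnot(inherits(model, "piecewise_demography"),
            inherits(arch, "genome_architecture"),
            inherits(dfe, "dfe_config"),
            inherits(scenario, "selection_scenario"))
  if (missing(seed)) stop("a seed is required for reproducibility")
  L <- architecture_length(arch)
  nb <- ceiling(L / block)
  if (length(mu_map) == 1L) mu_map <- rep(mu_map, nb)
  if (length(rec_map) == 1L) rec_map <- rep(rec_map, nb)
  stopifnot(length(mu_map) == nb, length(rec_map) == nb)
  N_anc <- model$sizes[length(model$sizes)]
  mode_i <- match(scenario$mode, c("neutral", "sweep", "balancing")) - 1L
  sel_pos <- scenario$sel_pos
  if (is.null(sel_pos)) sel_pos <- default_selected_position(arch)
  if (sel_pos < 1L || sel_pos > L) stop("selected site outside chromosome")
  sel_par <- 0
  if (mode_i == 1L) sel_par <- scenario$twoNs / (2 * N_anc)
  if (mode_i == 2L) sel_par <- scenario$F_eq
  tau_gens <- if (mode_i == 0L) 0 else scenario$tau * N_anc
  ex <- arch[arch$class == "exon", ]
  set.seed(seed)
  sim <- wf_forward_cpp(model$starts, model$sizes, L,
                        as.integer(ex$start), as.integer(ex$end),
                        dfe$proportions, dfe$lo, dfe$hi, dfe$refN, dfe$h,
                        mu_map, rec_map, as.integer(block), Q, mode_i,
                        sel_par, tau_gens, as.integer(sel_pos),
                        10 * N_anc, scenario$run_N * N_anc,
                        as.integer(n_sample_dip), as.integer(max_restarts),
                        50L, track_traj)
  n <- sim$n_sample
  x <- fold(sim$derived_count, n)
  poly <- which(x >= 1L)
  records <- data.frame(position = sim$position[poly],
                        x = as.integer(x[poly]),
                        n = rep(as.integer(n), length(poly)),
                        folded = rep(TRUE, length(poly)))
  state <- if (mode_i == 0L) "none" else if (isTRUE(sim$sel_fixed)) {
    "fixed"
  } else {
    "segregating"
  }
  out <- list(records = records,
              genotypes = sim$genotypes[, poly, drop = FALSE],
              scenario = scenario, sel_pos = sel_pos, sel_state = state,
              sel_freq = sim$sel_freq, restarts = sim$restarts, Q = Q,
              seed = seed, L = L)
  if (track_traj) out$trajectory <- sim$trajectory
  structure(out, class = "simulation_result")
}

#' Single-locus Wright-Fisher simulation of a balanced polymorphism
#'
#' Tracks one biallelic locus under negative frequency-dependent selection
#' with per-generation coefficient `S_bp = F_eq - F_bp` and genotype
#' fitnesses `1 + S_bp`, `1 + h S_bp`, `1` (mutant homozygote,
#' heterozygote, wild type). The run restarts from the introduction
#' frequency whenever the allele is lost or fixes.
#'
#' @param N Diploid population size (default 1000).
#' @param F_eq Equilibrium frequency (default 0.5).
#' @param h Dominance coefficient (default 0.5).
#' @param init_freq Introduction frequency (default 0.05).
#' @param generations Number of generations to record (default 25000).
#' @param seed Integer seed (required).
#' @return Numeric vector of allele frequencies, one per generation after
#'   introduction, with attribute `restarts`.
#' @export
simulate_balanced_locus <- function(N = 1000L, F_eq = 0.5, h = 0.5,
                                    init_freq = 0.05, generations = 25000L,
                                    seed) {
  if (missing(seed)) stop("a seed is required for reproducibility")
  set.seed(seed)
  twoN <- 2L * N
  traj <- numeric(generations)
  restarts <- 0L
  g <- 1L
  p <- init_freq
  while (g <= generations) {
    S <- frequency_dependent_coefficient(F_eq, p)
    wAA <- 1 + S
    wAa <- 1 + h * S
    q <- 1 - p
    wbar <- p^2 * wAA + 2 * p * q * wAa + q^2
    pstar <- p * (p * wAA + q * wAa) / wbar
    cnt <- rbinom(1L, twoN, pstar)
    p <- cnt / twoN
    if (cnt == 0L || cnt == twoN) {
      restarts <- restarts + 1L
      p <- init_freq
      g <- 1L
      next
    }
    traj[g] <- p
    g <- g + 1L
  }
  attr(traj, "restarts") <- restarts
  traj
}
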