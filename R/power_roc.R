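#' Score a replicate scan for detection
#'
#' Per-SNP (or per-window) CLR values are aggregated into fixed-bp windows
#' by maximum, and the replicate's detection score is the maximum windowed
#' CLR over the region ("was anything detected anywhere in this region").
#'
#' @param scan Scan data frame with `position` (or `center`) and `clr`.
#' @param window_bp Fixed window size in bp (study grid: 100, 1000, 10000);
#'   `NULL` for SNP-window scans that are already windowed.
#' @return Scalar score (`-Inf` for an empty scan of a region where nothing
#'   was polymorphic).
#' @export
replicate_score <- function(scan, window_bp = NULL) {
  if (nrow(scan) == 0L) return(-Inf)
  pos <- if (!is.null(scan$position)) scan$position else scan$center
  if (is.null(window_bp)) {
    return(max(scan$clr))
  }
  win <- floor((pos - 1) / window_bp)
  max(tapply(scan$clr, win, max))
}

#' ROC curve from selection and neutral replicate scores
#'
#' Sweeps a detection threshold over the pooled score set; at each
#' threshold, TPR is the fraction of selection replicates scoring at or
#' above it and FPR the fraction of neutral replicates doing so. The curve
#' is anchored at (0, 0) and (1, 1).
#'
#' @param selection_scores Numeric vector of scores from selection
#'   replicates.
#' @param neutral_scores Numeric vector of scores from matched neutral
#'   replicates.
#' @return Object of class `roc_curve`: data frame with columns `fpr`,
#'   `tpr`, ordered by increasing FPR, with attribute `auc`
#'   (Mann-Whitney).
#' @export
roc_curve <- function(selection_scores, neutral_scores) {
  stopifnot(length(selection_scores) > 0L, length(neutral_scores) > 0L)
  thr <- sort(unique(c(selection_scores, neutral_scores)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(selection_scores >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neutral_scores >= t), numeric(1))
  out <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  out <- out[order(out$fpr, out$tpr), ]
  rownames(out) <- NULL
  # Mann-Whitney AUC: P(sel > neut) + 0.5 P(tie)
  cmp <- outer(selection_scores, neutral_scores, "-")
  auc <- mean((cmp > 0) + 0.5 * (cmp == 0))
  structure(out, class = c("roc_curve", "data.frame"), auc = auc)
}

#' Area under a ROC curve
#' @param roc A [roc_curve()].
#' @return The Mann-Whitney AUC.
#' @export
roc_auc <- function(roc) attr(roc, "auc")

#' True-positive rate of a ROC curve at a given false-positive rate
#'
#' @param roc A [roc_curve()].
#' @param fpr Target FPR (default 0.05).
#' @return Highest TPR attained at FPR `<=` the target.
#' @export
power_at_fpr <- function(roc, fpr = 0.05) {
  ok <- roc$fpr <= fpr + 1e-12
  if (!any(ok)) return(0)
  max(roc$tpr[ok])
}

#' Power analysis over a grid of selection scenarios
#'
#' For each scenario, runs `n_reps` forward selection replicates and scores
#' them against `n_reps` neutral comparator replicates sharing the
#' demography, architecture, DFE (purifying selection on) and rate-map
#' settings but lacking the introduced mutation. Sweep scenarios are scanned
#' per SNP with the sweep CLR and scored at each fixed-bp window scheme;
#' balancing scenarios are scanned with the window CLR (`W`/`S` SNPs). The
#' background spectrum is estimated from the pooled neutral replicates.
#' Neutral comparator replicates are shared across scenarios with the same
#' run length.
#'
#' @param scenarios List of [selection_scenario()] objects.
#' @param model,arch,dfe,Q As in [run_forward()].
#' @param n_reps Replicates per scenario (and per neutral comparator set).
#' @param seed Integer base seed.
#' @param window_bp Fixed-bp window schemes for sweep scoring (default
#'   `c(100, 1000, 10000)`).
#' @param balance_W,balance_S SNP-window scheme for balancing scoring
#'   (default 10/5).
#' @param rate_mode `"fixed"` uses the constant rates 1.52e-8 and 1e-8;
#'   `"heterogeneous"` draws fresh mean-matched per-kb maps per replicate
#'   within the study bounds (mutation 0.61e-8 to 3.8e-8; recombination
#'   0.01 to 10 cM/Mb).
#' @param max_restarts Passed to [run_forward()]; a scenario whose
#'   replicates exceed the cap is recorded as absent (`NULL` curves), as
#'   when a weak sweep cannot fix before sampling.
#' @return List of class `power_grid`: per scenario, a list of
#'   [roc_curve()]s (one per window scheme) plus the replicate scores.
#' @export
power_grid <- function(scenarios, model, arch, dfe, n_reps = 50L, Q = 100,
                       seed = 1L, window_bp = c(100, 1000, 10000),
                       balance_W = 10L, balance_S = 5L,
                       rate_mode = c("fixed", "heterogeneous"),
                       max_restarts = 1000L) {
  rate_mode <- match.arg(rate_mode)
  L <- architecture_length(arch)
  nb <- ceiling(L / 1000)
  draw_maps <- function() {
    if (rate_mode == "fixed") {
      list(mu = rep(1.52e-8, nb), rec = rep(1e-8, nb))
    } else {
      list(mu = assign_rate_map(L, 1000, 1.52e-8, 0.61e-8, 3.8e-8),
           rec = assign_rate_map(L, 1000, 1e-8, 1e-10, 1e-7))
    }
  }
  run_set <- function(scenario, seeds) {
    lapply(seeds, function(s) {
      set.seed(s)
      maps <- draw_maps()
      tryCatch(
        run_forward(model, arch, dfe, scenario, maps$mu, maps$rec, Q = Q,
                    seed = s + 1L, max_restarts = max_restarts),
        error = function(e) {
          if (grepl("restart cap", conditionMessage(e))) NULL else stop(e)
        })
    })
  }

  # neutral comparator sets, shared per run length
  run_lengths <- unique(vapply(scenarios, `[[`, numeric(1), "run_N"))
  neutral_sets <- list()
  for (rn in run_lengths) {
    sc <- selection_scenario("neutral", run_N = rn)
    seeds <- seed * 10000L + round(rn) * 100L + seq_len(n_reps)
    neutral_sets[[as.character(rn)]] <- run_set(sc, seeds)
  }

  out <- list()
  for (si in seq_along(scenarios)) {
    scenario <- scenarios[[si]]
    neut <- neutral_sets[[as.character(scenario$run_N)]]
    seeds <- seed * 10000L + 50000L + si * 1000L + seq_len(n_reps)
    sel <- if (scenario$mode == "neutral") neut else run_set(scenario, seeds)
    feasible <- !vapply(sel, is.null, logical(1))
    entry <- list(scenario = scenario, n_feasible = sum(feasible))
    if (!any(feasible)) {
      entry$curves <- NULL  # absent panel: mutation could not fix in time
      out[[si]] <- entry
      next
    }
    sel <- sel[feasible]
    pooled <- do.call(rbind, lapply(neut, function(r) r$records))
    G <- background_spectrum(pooled, smooth = 0.5)
    if (scenario$mode == "balancing") {
      score <- function(r) {
        replicate_score(scan_balancing(r$records, balance_W, balance_S, G))
      }
      sel_scores <- vapply(sel, score, numeric(1))
      neut_scores <- vapply(neut, score, numeric(1))
      entry$curves <- list(snp_window = roc_curve(sel_scores, neut_scores))
      entry$scores <- list(selection = sel_scores, neutral = neut_scores)
    } else {
      spectra <- sweep_model_spectra(G)
      scans_sel <- lapply(sel, function(r) {
        scan_sweep(r$records, G, spectra = spectra)
      })
      scans_neut <- lapply(neut, function(r) {
        scan_sweep(r$records, G, spectra = spectra)
      })
      entry$curves <- lapply(setNames(window_bp, paste0("bp", window_bp)),
        function(wb) {
          roc_curve(vapply(scans_sel, replicate_score, numeric(1),
                           window_bp = wb),
                    vapply(scans_neut, replicate_score, numeric(1),
                           window_bp = wb))
        })
    }
    out[[si]] <- entry
  }
  structure(out, class = "power_grid")
}
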