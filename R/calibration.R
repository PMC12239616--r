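#' Genome-wide null threshold from neutral replicate scans
#'
#' The threshold for a scan scheme is the single highest CLR observed across
#' all neutral baseline replicates and chromosomes: by construction the
#' largest value the baseline model can produce in the simulated set, giving
#' a conservative scan.
#'
#' @param clr_values Numeric vector (or list of vectors, pooled) of CLR
#'   values from neutral replicate scans of one statistic/scheme.
#' @return The maximum CLR.
#' @export
null_threshold <- function(clr_values) {
  v <- unlist(clr_values, use.names = FALSE)
  if (length(v) == 0L) stop("no CLR values supplied")
  max(v)
}

#' Null thresholds for several schemes at once
#'
#' @param scheme_scans Named list; each element is a vector or list of CLR
#'   vectors for one scheme (e.g. `sweep_snp`, `b0maf_10`, `b0maf_100`).
#' @return Named numeric vector of thresholds.
#' @export
null_thresholds <- function(scheme_scans) {
  if (length(scheme_scans) == 0L) stop("no schemes supplied")
  vapply(scheme_scans, null_threshold, numeric(1))
}

#' Call candidates exceeding a null threshold
#'
#' Strictly-greater-than filter, preserving input order.
#'
#' @param scan Scan data frame with a `clr` column.
#' @param threshold Finite threshold value.
#' @return The rows of `scan` with `clr > threshold`.
#' @export
call_candidates <- function(scan, threshold) {
  stopifnot(is.finite(threshold))
  scan[scan$clr > threshold, , drop = FALSE]
}

candidate_ranges <- function(candidates) {
  if (!is.null(candidates$start) && !is.null(candidates$end)) {
    IRanges::IRanges(start = as.integer(candidates$start),
                     end = as.integer(candidates$end))
  } else {
    p <- as.integer(round(candidates$position))
    IRanges::IRanges(start = p, end = p)
  }
}

overlap_intervals <- function(candidates, intervals, id_col) {
  if (nrow(candidates) == 0L || nrow(intervals) == 0L) {
    return(data.frame(candidate = integer(), hit = character()))
  }
  q <- candidate_ranges(candidates)
  s <- IRanges::IRanges(start = as.integer(intervals$start),
                        end = as.integer(intervals$end))
  ov <- IRanges::findOverlaps(q, s)
  data.frame(candidate = S4Vectors::queryHits(ov),
             hit = intervals[[id_col]][S4Vectors::subjectHits(ov)])
}

#' Map candidates to overlapping genes
#'
#' Point candidates (per-SNP scans, `position` column) hit genes containing
#' the position; window candidates (`start`/`end` columns) hit genes
#' intersecting the window span. All intervals are 1-based closed.
#'
#' @param candidates Candidate data frame from [call_candidates()].
#' @param genes Gene intervals from [read_gene_annotations()] (or any data
#'   frame with `start`, `end`, `gene_id`).
#' @return Data frame with columns `candidate` (row index into
#'   `candidates`) and `hit` (gene identifier).
#' @export
overlap_genes <- function(candidates, genes) {
  overlap_intervals(candidates, genes, "gene_id")
}

#' Map candidates to overlapping structural variants
#'
#' @param candidates Candidate data frame.
#' @param svs Structural-variant intervals from [read_sv_intervals()].
#' @return Data frame with columns `candidate` and `hit` (SV class label).
#' @export
overlap_svs <- function(candidates, svs) {
  overlap_intervals(candidates, svs, "sv_class")
}

#' Empirical-tail outlier comparator
#'
#' The conventional outlier approach: interpret the upper `q` tail of the
#' empirical CLR distribution as candidates. Provided as a contrast to the
#' simulation-calibrated threshold: any model, including pure neutrality,
#' has a 5% tail.
#'
#' @param scan Scan data frame with a `clr` column (or a numeric vector).
#' @param q Tail fraction in (0, 1), e.g. 0.05.
#' @return List with `cutoff` (the `1 - q` linear-interpolation empirical
#'   quantile) and `n_candidates` (values strictly above it).
#' @export
empirical_tail_quantile <- function(scan, q) {
  stopifnot(q > 0, q < 1)
  v <- if (is.data.frame(scan)) scan$clr else scan
  cutoff <- unname(quantile(v, 1 - q, type = 7))
  list(cutoff = cutoff, n_candidates = sum(v > cutoff))
}
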