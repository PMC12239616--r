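#' Read an allele-frequency file ("FreqFile")
#'
#' Whitespace-delimited text with a header line naming the columns
#' `position x n folded`, one polymorphic site per row: physical position
#' (1-based bp), folded minor-allele count `x`, sample size `n` in
#' chromosomes, and a 0/1 folded flag. This single dialect feeds both the
#' sweep and the balancing scan.
#'
#' @param path File path.
#' @return Data frame with integer columns `position`, `x`, `n` and logical
#'   `folded`, rows in file order.
#' @export
read_freq_file <- function(path) {
  if (!file.exists(path)) stop("freq file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) stop("freq file is empty (missing header): ", path)
  header <- strsplit(trimws(lines[1L]), "[ \t]+")[[1L]]
  if (!identical(header, c("position", "x", "n", "folded"))) {
    stop("line 1: expected header 'position x n folded', got: ", lines[1L])
  }
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) {
    return(data.frame(position = integer(), x = integer(), n = integer(),
                      folded = logical()))
  }
  fields <- strsplit(trimws(body), "[ \t]+")
  prev_pos <- -Inf
  out <- matrix(NA_integer_, nrow = length(body), ncol = 4L)
  for (i in seq_along(fields)) {
    ln <- i + 1L
    f <- fields[[i]]
    if (length(f) != 4L) stop("line ", ln, ": expected 4 fields, got ", length(f))
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v) || any(v != floor(v))) {
      stop("line ", ln, ": non-integer field in '", body[i], "'")
    }
    if (v[1L] <= prev_pos) {
      stop("line ", ln, ": positions not strictly increasing (", v[1L], ")")
    }
    if (v[2L] < 1 || v[2L] > v[3L] %/% 2) {
      stop("line ", ln, ": folded count x = ", v[2L],
           " outside [1, ", v[3L] %/% 2, "]")
    }
    if (!v[4L] %in% c(0, 1)) stop("line ", ln, ": folded flag must be 0 or 1")
    prev_pos <- v[1L]
    out[i, ] <- as.integer(v)
  }
  data.frame(position = out[, 1L], x = out[, 2L], n = out[, 3L],
             folded = out[, 4L] == 1L)
}

#' Write an allele-frequency file
#'
#' Inverse of [read_freq_file()]; output is bit-stable for fixed input.
#'
#' @param records Data frame with columns `position`, `x`, `n`, `folded`.
#' @param path Output file path.
#' @export
write_freq_file <- function(records, path) {
  if (nrow(records) > 0L) {
    if (anyDuplicated(records$position) ||
        is.unsorted(records$position, strictly = TRUE)) {
      stop("record positions must be strictly increasing and unique")
    }
    if (any(records$x < 1L | records$x > records$n %/% 2L)) {
      stop("folded counts must lie in [1, n/2]")
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("position\tx\tn\tfolded", con)
  if (nrow(records) > 0L) {
    writeLines(sprintf("%d\t%d\t%d\t%d", records$position, records$x,
                       records$n, as.integer(records$folded)), con)
  }
  invisible(path)
}

#' Convert a biallelic SNP table (VCF) to folded allele-frequency records
#'
#' Applies the hard filters used throughout the pipeline: sites must be
#' biallelic SNPs genotyped in all individuals (allele number `2 *
#' n_diploid`), and monomorphic sites are removed. Remaining sites are
#' folded: `x = min(c, n - c)` for alternate-allele count `c`.
#'
#' @param vcf Path to a VCF file, or a `vcfR::vcfR` object.
#' @param n_diploid Expected number of diploid samples (default 5, i.e.
#'   10 chromosomes).
#' @return Data frame of allele-frequency records (see [read_freq_file()]),
#'   sorted by position. Only the first chromosome/scaffold present is
#'   accepted; pass per-chromosome VCFs.
#' @export
variant_table_to_freq <- function(vcf, n_diploid = 5L) {
  if (is.character(vcf)) {
    vcf <- vcfR::read.vcfR(vcf, verbose = FALSE)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (ncol(gt) != n_diploid) {
    stop("expected ", n_diploid, " diploid samples, found ", ncol(gt))
  }
  n <- 2L * n_diploid
  fix <- vcfR::getFIX(vcf)
  chrom <- unique(fix[, "CHROM"])
  if (length(chrom) > 1L) {
    stop("multiple chromosomes in VCF; supply per-chromosome files")
  }
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  biallelic <- !is.na(alt) & !grepl(",", alt) &
    nchar(ref) == 1L & nchar(alt) == 1L
  # count alternate alleles per site; any missing genotype voids the site
  count_site <- function(g) {
    if (anyNA(g)) return(NA_integer_)
    alleles <- unlist(strsplit(g, "[/|]"))
    if (length(alleles) != n || any(alleles == ".")) return(NA_integer_)
    sum(alleles == "1")
  }
  cnt <- apply(gt, 1L, count_site)
  keep <- biallelic & !is.na(cnt) & cnt > 0L & cnt < n
  pos <- as.integer(fix[keep, "POS"])
  x <- pmin(cnt[keep], n - cnt[keep])
  ord <- order(pos)
  data.frame(position = pos[ord], x = as.integer(x[ord]), n = n,
             folded = TRUE, row.names = NULL)
}

#' Read gene intervals from a GFF3 annotation
#'
#' Keeps features of type `gene` only; GFF3 coordinates are already 1-based
#' closed and are preserved.
#'
#' @param path GFF3 file path.
#' @return Data frame with columns `chrom`, `start`, `end`, `gene_id`.
#' @export
read_gene_annotations <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  id <- if ("ID" %in% names(S4Vectors::mcols(gr))) gr$ID else gr$Name
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             gene_id = as.character(id),
             row.names = NULL)
}

#' Read structural-variant intervals from a BED file
#'
#' BED is 0-based half-open; intervals are converted to 1-based closed
#' coordinates on read, so a BED row `chr 315972758 316062009` becomes
#' `315972759..316062009`.
#'
#' @param path BED file path (columns: chrom, start, end, name).
#' @return Data frame with columns `chrom`, `start`, `end`, `sv_class`.
#' @export
read_sv_intervals <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), sv_class = character()))
  }
  gr <- rtracklayer::import(path, format = "bed")
  if (any(GenomicRanges::start(gr) < 1L)) {
    stop("negative BED coordinates")
  }
  if (any(GenomicRanges::width(gr) < 1L)) {
    stop("BED interval with end <= start")
  }
  nm <- if ("name" %in% names(S4Vectors::mcols(gr))) gr$name else NA_character_
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             sv_class = as.character(nm),
             row.names = NULL)
}
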