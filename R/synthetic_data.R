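#' Write a minimal VCF from a haplotype matrix
#'
#' Emits biallelic SNPs (REF A, ALT C) with diploid unphased genotypes
#' formed by pairing consecutive haplotypes (rows 1+2 = sample 1, ...).
#'
#' @param genotypes 0/1 matrix, haplotypes x sites.
#' @param positions Site positions (bp), strictly increasing.
#' @param chrom Chromosome label.
#' @param path Output path.
#' @param contig_length Declared contig length (default `max(positions)`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, positions, chrom, path,
                      contig_length = NULL) {
  nh <- nrow(genotypes)
  if (nh %% 2L != 0L) stop("need an even number of haplotypes")
  ns <- nh %/% 2L
  if (is.null(contig_length)) {
    contig_length <- if (length(positions)) max(positions) else 1L
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", chrom,
                       as.integer(contig_length)),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT",
                       paste0("sample", seq_len(ns))), collapse = "\t")),
             con)
  for (j in seq_along(positions)) {
    gt <- vapply(seq_len(ns), function(i) {
      paste0(genotypes[2L * i - 1L, j], "/", genotypes[2L * i, j])
    }, character(1))
    writeLines(paste(c(chrom, positions[j], ".", "A", "C", ".", "PASS",
                       ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write gene intervals as GFF3
#'
#' @param genes Data frame with `chrom`, `start`, `end`, `gene_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes) > 0L) {
    writeLines(sprintf("%s\tayescan\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                       genes$chrom, as.integer(genes$start),
                       as.integer(genes$end), genes$gene_id), con)
  }
  invisible(path)
}

#' Write structural-variant intervals as BED
#'
#' Converts 1-based closed intervals back to BED's 0-based half-open
#' convention.
#'
#' @param svs Data frame with `chrom`, `start`, `end`, `sv_class`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(svs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(svs) > 0L) {
    writeLines(sprintf("%s\t%d\t%d\t%s", svs$chrom,
                       as.integer(svs$start) - 1L, as.integer(svs$end),
                       svs$sv_class), con)
  }
  invisible(path)
}

#' Gene spans of a simulated architecture
#'
#' One interval per functional region, from its first to its last exon.
#'
#' @param arch A [build_architecture()] object.
#' @param chrom Chromosome label.
#' @return Data frame with `chrom`, `start`, `end`, `gene_id`.
#' @export
architecture_genes <- function(arch, chrom) {
  # group exon rows into genes: a gene starts at the first exon after an
  # intergenic block
  gene_idx <- integer(nrow(arch))
  gid <- 0L
  prev <- "intergenic"
  for (i in seq_len(nrow(arch))) {
    if (arch$class[i] == "exon" && prev %in% c("intergenic", "")) {
      gid <- gid + 1L
    }
    gene_idx[i] <- gid
    prev <- if (arch$class[i] == "intergenic") "intergenic" else "genic"
  }
  keep <- arch$class == "exon"
  spans <- split(arch[keep, ], gene_idx[keep])
  data.frame(chrom = chrom,
             start = vapply(spans, function(s) min(s$start), numeric(1)),
             end = vapply(spans, function(s) max(s$end), numeric(1)),
             gene_id = paste0("gene", seq_along(spans)),
             row.names = NULL)
}

#' Generate a fully self-contained miniature dataset
#'
#' Emits, per configured chromosome, a VCF of 5 diploid samples (haplotypes
#' randomly paired), a matching freq file, plus a GFF3 of genes, a BED of
#' structural variants, and a ground-truth manifest. Neutral chromosomes
#' come from the coalescent; sweep/balancing chromosomes from the forward
#' simulator with the selected site recorded. Identical configuration and
#' seed yield byte-identical output.
#'
#' @param config List with elements:
#'   * `seed`: integer;
#'   * `chromosomes`: list of per-chromosome configs, each a list with
#'     `name`, `type` (`"neutral"`, `"sweep"`, `"balancing"`), and for
#'     neutral chromosomes `L` (default 2e5), for selection chromosomes
#'     optional `twoNs`, `tau`, `Q` (default 100);
#'   * optional `model` ([piecewise_demography()], default
#'     [default_demography()]), `dfe`, `mu`, `r`;
#'   * optional `svs` data frame (`chrom`, `start`, `end`, `sv_class`).
#' @param out_dir Output directory (created if needed).
#' @return The manifest data frame, invisibly; files are written under
#'   `out_dir`.
#' @export
make_fixture <- function(config, out_dir) {
  stopifnot(length(config$chromosomes) >= 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  model <- config$model
  if (is.null(model)) model <- default_demography()
  dfe <- config$dfe
  if (is.null(dfe)) dfe <- dfe_config()
  mu <- if (is.null(config$mu)) 1.52e-8 else config$mu
  r <- if (is.null(config$r)) 1e-8 else config$r
  arch <- build_architecture()
  genes_all <- list()
  manifest <- list()
  for (ci in seq_along(config$chromosomes)) {
    cc <- config$chromosomes[[ci]]
    seed_c <- config$seed + 17L * ci
    if (cc$type == "neutral") {
      L <- if (is.null(cc$L)) 2e5 else cc$L
      rep <- neutral_chromosome_replicate(model, L, mu, r, 10L, seed_c,
                                          genotypes = TRUE)
      gt <- rep$genotypes
      records <- rep$records
      sel_pos <- NA_integer_
      # toy gene annotations tiling part of the chromosome
      genes <- data.frame(chrom = cc$name,
                          start = c(round(L * 0.1), round(L * 0.6)),
                          end = c(round(L * 0.2), round(L * 0.7)),
                          gene_id = paste0(cc$name, "_gene", 1:2))
      Q <- NA_real_
    } else {
      Q <- if (is.null(cc$Q)) 100 else cc$Q
      scenario <- selection_scenario(
        cc$type,
        twoNs = if (is.null(cc$twoNs)) 10000 else cc$twoNs,
        tau = if (is.null(cc$tau)) {
          if (cc$type == "sweep") 0.1 else 75
        } else {
          cc$tau
        })
      res <- run_forward(model, arch, dfe, scenario, mu, r, Q = Q,
                         seed = seed_c)
      L <- res$L
      gt <- res$genotypes
      records <- res$records
      sel_pos <- res$sel_pos
      genes <- architecture_genes(arch, cc$name)
      genes$gene_id <- paste0(cc$name, "_", genes$gene_id)
    }
    if (!is.null(sel_pos) && !is.na(sel_pos) && sel_pos > L) {
      stop("selected site outside chromosome")
    }
    # random pairing of the sampled haplotypes into diploid calls
    set.seed(seed_c + 1L)
    perm <- sample.int(nrow(gt))
    gt <- gt[perm, , drop = FALSE]
    write_vcf(gt, records$position, cc$name,
              file.path(out_dir, paste0(cc$name, ".vcf")),
              contig_length = L)
    write_freq_file(records, file.path(out_dir, paste0(cc$name, ".freq")))
    genes_all[[ci]] <- genes
    manifest[[ci]] <- data.frame(chrom = cc$name, type = cc$type, L = L,
                                 selected_pos = sel_pos, seed = seed_c,
                                 Q = Q)
  }
  write_gff3(do.call(rbind, genes_all), file.path(out_dir, "genes.gff3"))
  svs <- config$svs
  if (is.null(svs)) {
    svs <- data.frame(chrom = character(), start = integer(),
                      end = integer(), sv_class = character())
  }
  write_bed(svs, file.path(out_dir, "svs.bed"))
  mf <- do.call(rbind, manifest)
  write.table(mf, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(mf)
}
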