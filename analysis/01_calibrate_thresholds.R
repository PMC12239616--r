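#!/usr/bin/env Rscript
# Step 1: neutral baseline and genome-wide null thresholds.
#
# Simulates neutral chromosome replicates under the bottleneck demography
# (SMC' coalescent; mu = 1.52e-8 /bp/gen, r = 1 cM/Mb, n = 10 chromosomes),
# estimates the genome-wide background folded SFS from the pooled
# replicates, scans every replicate with the sweep CLR (at each SNP) and
# the balancing CLR (10/5- and 100/50-SNP windows), and records the
# maximum CLR per scheme as the conservative null threshold.
#
# Desk scale: 20 replicates of 1 Mb (the study used 100 replicates of each
# of 14 full autosomes on a cluster).

suppressPackageStartupMessages(library(ayescan))

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

n_reps <- 20L
L <- 1e6
model <- default_demography()

message("simulating ", n_reps, " neutral replicates of ", L / 1e6, " Mb...")
reps <- lapply(seq_len(n_reps), function(i) {
  neutral_chromosome_replicate(model, L, seed = 1000L + i)$records
})
message("segregating sites per replicate: ",
        paste(range(vapply(reps, nrow, integer(1))), collapse = "-"))

G <- background_spectrum(do.call(rbind, reps), smooth = 0.5)
write_spect_file(G, file.path(out_dir, "background_spectrum.tsv"))
message("background folded SFS: ",
        paste(sprintf("%.3f", G$G), collapse = " "))

spectra <- ayescan:::sweep_model_spectra(G)
scans <- lapply(seq_along(reps), function(i) {
  rec <- reps[[i]]
  list(sweep = scan_sweep(rec, G, spectra = spectra),
       b10 = scan_balancing(rec, 10L, 5L, G),
       b100 = scan_balancing(rec, 100L, 50L, G))
})

th <- null_thresholds(list(
  sweep_snp = lapply(scans, function(s) s$sweep$clr),
  b0maf_10 = lapply(scans, function(s) s$b10$clr),
  b0maf_100 = lapply(scans, function(s) s$b100$clr)
))
message("null thresholds (max CLR over all neutral replicates):")
print(round(th, 3))

write.table(data.frame(scheme = names(th), threshold = unname(th)),
            file.path(out_dir, "thresholds.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# keep the per-replicate scan maxima for the outlier comparison in step 2
maxima <- data.frame(
  replicate = seq_len(n_reps),
  sweep_max = vapply(scans, function(s) max(s$sweep$clr), numeric(1)),
  b10_max = vapply(scans, function(s) max(s$b10$clr), numeric(1)),
  b100_max = vapply(scans, function(s) {
    if (nrow(s$b100)) max(s$b100$clr) else NA_real_
  }, numeric(1))
)
write.table(maxima, file.path(out_dir, "neutral_scan_maxima.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote results/thresholds.tsv, results/background_spectrum.tsv, ",
        "results/neutral_scan_maxima.tsv")
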