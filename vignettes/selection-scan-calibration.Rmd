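---
title: "Simulation-calibrated scans for episodic selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation-calibrated scans for episodic selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ayescan)
```

## The problem

Genome scans for recent positive selection (selective sweeps) and for
long-term balancing selection both work by asking whether the local site
frequency spectrum (SFS) deviates from a genome-wide background in a
characteristic direction: sweeps drag linked variation to fixation,
depressing diversity and skewing the SFS toward rare (and, for unfolded
data, high-frequency derived) alleles; balancing selection maintains
polymorphism and accumulates linked variants at intermediate frequencies.
Both signatures are, however, routinely mimicked by demography — a severe
bottleneck produces sweep-like troughs and intermediate-frequency excess
genome-wide. Outlier approaches that call the top 1–5% of a scan statistic
"candidates" are therefore inherently misleading: any model, including
strict neutrality, has a 5% tail.

`ayescan` implements the alternative workflow used for population-level
scans of the aye-aye (*Daubentonia madagascariensis*), an endangered lemur
whose history involves an ancient human-associated population reduction and
a recent collapse: simulate a realistic neutral baseline (demography fit to
non-functional regions), run the identical scan statistics on the simulated
baseline, and take the **maximum** statistic value observed across all
neutral replicates as the genome-wide detection threshold. Only empirical
values exceeding that maximum are treated as candidates. The package also
quantifies, by forward simulation with purifying selection and rate
heterogeneity, how much power such a conservative scan retains.

The sample size mirrors the study design throughout: 5 diploid individuals,
i.e. `n = 10` chromosomes, with allele frequencies folded (no ancestral
state information) and only polymorphic, fully genotyped biallelic sites
retained.

## The two statistics

Both statistics are composite likelihood ratios (CLR) against the same
null: each site's folded minor-allele count `x_i` is an independent draw
from the genome-wide background spectrum `G` (a `folded_sfs` object,
estimated by `background_spectrum()`; smoothing pseudo-counts are available
because the likelihood requires `G(k) > 0` for observed classes).

**Sweep CLR** (`scan_sweep()`, at every SNP). The alternative at test
position `t` perturbs `G` by a completed hard sweep: a lineage at distance
`d` escapes the sweep with probability `p_e = 1 - exp(-alpha d)`
(`escape_probability()`), where `alpha` absorbs selection strength,
duration and recombination. Of `n` sampled lineages, `e ~ Binomial(n,
p_e)` escape; the rest coalesce into the single swept ancestor, so the
ancestral configuration is a size-`(e+1)` draw from the (symmetrized,
hypergeometrically projected) background, and the swept ancestor's allele
is inherited by all non-escaped lineages (`sweep_spectrum()`). The CLR is
`2 [max_alpha sum_i log P_{alpha,d_i}(x_i) - sum_i log G(x_i)]`, maximized
over a log-spaced `alpha` grid (default 48 points over `1e-8`–`1e-1` per
bp) that includes the neutral limit, so the CLR is non-negative. Because
the data are folded, the derived-allele model is bridged by symmetrizing
`G`, perturbing, and re-folding.

**Balancing CLR** (`scan_balancing()`, over SNP-count windows — the study's
schemes are 10 SNPs/step 5 and 100 SNPs/step 50). The alternative mixes,
at each member site, the background with a balanced-class spectrum
`f_B` — a folded binomial around the equilibrium minor-allele frequency
`x_eq` (`balanced_class_spectrum()`) — with mixture weight
`exp(-A r d_i)` decaying with distance from the window center
(`r = 1e-8`/bp converts physical distance to map distance; physical
positions, no substitutions, minor-allele frequencies only). Maximization
is over `x_eq in {0.05, ..., 0.5}` and a log-spaced `A` grid whose
infinite endpoint collapses the alternative onto the null, again
guaranteeing CLR ≥ 0.

Neither implementation claims bit-level parity with the released
SweepFinder2/BalLeRMix binaries (whose internal grids are not published);
the model structure, data conventions and invocation-level options are
matched instead, and the statistics are validated against exhaustive
enumeration oracles at small `n` and against their analytic limits.

## The neutral baseline

`neutral_chromosome_replicate()` draws folded polymorphic sites for a
chromosome under a piecewise-constant demography using an SMC' (sequentially
Markov coalescent) generator written for this package: marginal genealogies
follow the exact time-inhomogeneous coalescent, and linkage along the
chromosome follows the standard SMC' prune-and-regraft approximation.
Replicates are seed-stable; mutations fall on integer positions
(infinite-sites approximation, duplicate positions rejected).

The default demography (`default_demography()`) is a three-epoch bottleneck:
ancestral diploid size 23,706, a ~5-fold reduction around 4,000 years ago,
and a recent collapse over the last decades, with a 5-year generation time.
**Only the ancestral size is a published inferred value**; the remaining
epoch parameters and the generation time are stand-ins chosen to reproduce
the qualitative shape (the source model's epochs are not published in the
material this package builds on) and are exposed as arguments. Default
rates are the study's: mutation `1.52e-8`/bp/generation, recombination
1 cM/Mb.

Calibration (`null_threshold()`) pools all replicate scans per scheme and
takes the maximum; `call_candidates()` applies a strictly-greater filter.
By construction the threshold yields zero candidates on its own training
set, and on fresh neutral replicates the per-replicate false-positive
probability is ~`1/(R+1)` for `R` training replicates. The
`empirical_tail_quantile()` comparator implements the conventional outlier
approach (linear-interpolation quantile) purely for contrast.

## The forward simulator and power analysis

`run_forward()` is a diploid Wright–Fisher simulator with multiplicative
fitness across sites and dominance `h = 0.5`, written for this package:

* **Architecture** (`build_architecture()`): 3 functional regions, each 9
  exons of 130 bp separated by 1,591-bp introns, with one 16,489-bp
  intergenic block per region — 91,161 bp total. The arithmetic forces one
  intergenic block per gene (two separators per gene would give 74,672 bp).
* **DFE** (`dfe_config()`): exonic mutations draw `2Ns` uniformly within
  one of four classes `[0,1)`, `[1,10)`, `[10,100)`, `[100, 2N)` with
  class probabilities `f0..f3`; intronic/intergenic mutations are neutral.
  The default proportions `(0.25, 0.49, 0.04, 0.22)` follow discrete-class
  DFE estimates published for humans and aye-ayes; they are external
  defaults, exposed as configuration.
* **Rate heterogeneity** (`assign_rate_map()`): each 1-kb block gets its
  own rate. The stated uniform bounds (0.01–10 cM/Mb; 0.61e-8–3.8e-8) do
  not average to the fixed genome-wide rates, while the study describes
  the chromosome-wide mean as matching them; both a `literal` mode (plain
  uniform) and the default `mean_matched` mode (uniform draws rescaled,
  with clamping, until the realized mean is within 1% of the target) are
  provided.
* **Scenarios** (`selection_scenario()`): a 10N-generation burn-in at the
  ancestral size precedes a post-burn-in phase of 10N (sweep/neutral) or
  85N (balancing) generations over which the bottleneck unfolds. Sweeps
  introduce one beneficial mutation (`2Ns` in {100, 1000, 10000}) at
  `tau` N-generations before sampling and are retained only if fixed at
  sampling; the balanced mutation (`tau` in {10N, 50N, 75N}) experiences
  negative frequency-dependent selection with coefficient
  `S_bp = F_eq - F_bp` recomputed every generation (genotype fitnesses
  `1 + S_bp`, `1 + h S_bp`, `1`), and must still segregate at sampling.
  Failures restart from a saved introduction-time population state; a
  restart cap (default 1000) flags infeasible corners such as
  `2Ns = 100, tau = 0.1`, mirroring the study's absent panels.
* **Rescaling**: sizes and durations are divided by `Q`, rates and
  selection coefficients multiplied by `Q` (default `Q = 100` for desk
  scale; `Q = 1` reproduces the full-scale setting). Scaled selection
  coefficients are floored at −0.95 so genotype fitnesses stay positive;
  at `Q = 100` this makes the strongest DFE class effectively
  recessive-lethal, a known limitation of rescaling strongly deleterious
  mutations. Demographic epochs shorter than `Q` generations (the final
  recent-collapse epoch at `Q = 100`) round away; they matter only at
  small `Q`.

`power_grid()` runs each scenario against matched neutral comparators
(same demography, architecture, DFE and rate settings, no introduced
mutation; comparator sets are shared across scenarios with the same run
length), scores every replicate by its region-wide maximum windowed CLR,
and assembles ROC curves (`roc_curve()`, Mann–Whitney AUC). The
per-replicate max-score convention answers "was anything detected in this
region"; note that with max-aggregation the score is invariant to the
fixed-bp window size, so the 100 bp/1 kb/10 kb schemes are reported as a
robustness convention rather than as distinct analyses.

## What the synthetic data do and do not emulate

`make_fixture()` emits complete miniature datasets in the empirical
formats (per-chromosome VCF with 5 diploid samples assembled by random
haplotype pairing, GFF3 genes, BED structural variants, freq files, and a
ground-truth manifest), built from the coalescent and forward simulators.
These fixtures exercise every pipeline stage — format round-trips,
filtering, scanning, thresholding, annotation — with known truth. They do
not emulate sequencing error, mapping artifacts, genotype-likelihood
uncertainty, reference bias, or polymorphism-blind invariant-site
filtering; passing tests therefore demonstrate the statistical machinery,
not robustness to data-production noise.

## Numerical choices

* The sweep scan discretizes the compound parameter `u = alpha * d` onto a
  256-point log grid of precomputed perturbed spectra (`p_e` clamped to
  `[1e-12, 1]`); sites with `u > 20` contribute exactly their background
  term and cancel. The exact unbinned evaluation (`sweep_clr_at()`) agrees
  to within a few percent and is used as the reference in tests.
* Spectrum folding/unfolding splits each folded class's mass equally
  between `k` and `n - k` (self-symmetric class kept whole); re-folding
  conditions on polymorphism and errors if the polymorphic mass underflows
  (`p_e` effectively zero with a degenerate background).
* Window positions are the physical midpoint of the first and last member
  SNP; trailing partial windows are dropped so all windows share `W`.
* Ties at a threshold are excluded by the strict inequality; the outlier
  comparator uses the conventional linear-interpolation quantile.
* Monte-Carlo assertions in the test suite use analytic oracles
  (Watterson's estimator, the standard folded neutral SFS, exhaustive
  subset enumeration at `n <= 6`) with 3-standard-error bands; problem
  sizes are 1-Mb chromosomes for calibration (20 training + 100 test
  replicates) and 50 replicates per scenario at `Q = 100` for power
  orderings — deliberately modest sizes that keep the whole suite
  desk-runnable while leaving the Monte-Carlo bands meaningful.

## Design choices where the design was open

* **One shared freq-file dialect** (`position x n folded`) feeds both
  statistics; import shims for the two published tool dialects were judged
  unnecessary since both scans consume identical folded records.
* **One genome-wide background spectrum** is estimated from all pooled
  replicates (rather than per-chromosome spectra); the baseline model is
  homogeneous across chromosomes, so pooling only reduces noise.
* **Balancing fitness scheme**: only `S_bp` is specified by the study;
  genotype fitnesses `1, 1 + h S_bp, 1 + S_bp` with `h = 0.5` recomputed
  each generation are the natural completion, and the single-locus
  equilibrium check (`simulate_balanced_locus()`) confirms the time-average
  sits at `F_eq`.
* **Selected-site placement** defaults to the center of the middle gene's
  middle exon (configurable).
* **Sweep dominance** is additive (`h = 0.5`), the usual convention where
  unstated.

## Known limitations

* At the study's selection strengths the sweep footprint
  (`~ s / (r ln 2N)`) exceeds the 91-kb simulated region many-fold, so
  within-region localization of the selected site is not achievable — the
  region-wide signature (diversity loss, SFS skew) is what the power
  analysis measures. This matches the study-scale finding that detectable
  sweeps must be strong and recent, and that power is modest overall.
* The SMC' generator approximates linkage (exact marginals, Markovian
  correlation along the sequence); thresholds calibrated from it inherit
  that approximation.
* Rescaling at `Q = 100` compresses the recent bottleneck epochs and
  saturates strongly deleterious fitness effects, as noted above.
* The balancing statistic's published refinements involving substitutions
  or unfolded spectra (B1/B2-type variants) are out of scope; only the
  polymorphism-only folded variant is implemented.
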