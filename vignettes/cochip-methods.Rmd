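---
title: "Methods: co-localization and dynamics statistics in cochip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-localization and dynamics statistics in cochip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cochip)
```

# The analysis model

`cochip` treats a ChIP-seq experiment as a set of peaks — intervals with
an enrichment value — and reduces each peak to a single interaction
site, its midpoint `floor((start + end)/2)`. Everything downstream is
built on three primitives:

1. **TSS-window assignment.** A peak belongs to a gene when its
   strand-oriented offset from the TSS lies in the half-open window
   `[-w, w)` with `w = 20` kb. Offsets are negated for minus-strand
   genes, so "upstream" is always negative. The same rule feeds the
   200-bin signal profile (`bin_peaks()`, `signal_intensity()`) and the
   association strength (`tfas_matrix()`).
2. **The midpoint overlap predicate.** Peaks with centers `S_1, S_2`
   and widths `L_1, L_2` co-localize iff `|S_1 - S_2| < (L_1 + L_2)/2`.
3. **Quartile expression classes.** Genes are ranked by FPKM; the top
   and bottom quarters become the `high`/`low` classes for the SVM, the
   middle half is excluded.

The assumptions this encodes: peak midpoints are an adequate proxy for
the protein–DNA contact point (summits are parsed and can be switched
on via `use_summit`, but midpoints are the default so narrow and broad
peaks are treated uniformly); binding relevant to a gene is confined to
±20 kb of its TSS; and peak counts need no library-size normalization
because peak calling has already thresholded enrichment.

Genes whose ±20 kb windows overlap another gene's window are removed
before any statistic is computed (`filter_nonoverlapping_genes()`), so
a peak near a TSS is almost always attributable to one gene. A peak
that still falls in several windows counts toward each.

# Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `half_window` | 20000 | bp | TSS window half-width for binning, TFAS, and the gene filter |
| `bin_size` | 200 | bp | bin width; 40 kb / 200 bp = 200 bins |
| `d0` | 2000 | bp | TFAS exponential decay length |
| `alpha` | 0.001 | — | guard in `I_RV` against `R_G + R_K = 0` |
| `threshold` | 0.6 | — | minimum overlap ratio for network edges / clique mining |
| `cost`, `gamma` | 1, `1/n_features` | — | libSVM soft margin and RBF width |
| `folds` | 5 | — | stratified cross-validation folds |

The distance constants are the pipeline's standard configuration; the
0.6 co-binding threshold is the magnitude used for the triple-mining
step, and the SVM settings are libSVM's defaults.

# Conventions and numerical choices

* **Coordinates** are 0-based half-open (BED convention). The TSS of a
  minus-strand BED record is `end - 1`. Chromosome names match by exact
  string comparison; `rename_chromosomes()` reconciles schemes.
* **The overlap predicate is strict** and evaluated in integer
  arithmetic: internally each peak maps to the doubled-coordinate range
  `[2c - L + 1, 2c + L]`, whose integer intersection is exactly
  `2|c_1 - c_2| < L_1 + L_2`. There are no floating-point ties: peaks
  whose half-widths exactly touch do not overlap.
* **Matched-peak counting.** The `n` of `R_o = 2n/(N_1 + N_2)` is
  ambiguous between "overlapping pairs" and "participating peaks". The
  default counts participating peaks, `n = (|A hit| + |B hit|)/2`, which
  guarantees `R_o` is in `[0, 1]`, symmetric, and 1 for a track against
  itself. Pair-event counting (which can exceed 1 when one peak covers
  several) is available as `count_mode = "pairs"` for sensitivity
  analysis only.
* **Bin indexing.** Bin `j = floor((offset + w)/bin_size) + 1`; offset
  0 (a peak centered exactly on the TSS) falls in bin 101, the first
  downstream bin, and offset `-w` in bin 1. The window is half-open at
  `+w`. A strand-naive profile is available via `strand_flip = FALSE`.
* **Classification boxes.** Because `D_signal = (f-1)/(f+1)` exactly,
  the `f` bounds (1.5, 0.6) and the `D_signal` bounds (0.2, −0.25) are
  the same boxes; values on a boundary belong to no class and are
  labelled `unclassified` rather than snapped to the nearest box. A
  factor with signal in one cell line only gets `f = +Inf`,
  `D_signal = 1`; no signal in either cell line is an error.
* **Degenerate inputs.** Empty peak files parse to empty tracks; two
  empty tracks have no defined overlap ratio (error); a region
  restriction that removes every peak raises a typed
  `cochip_empty_restriction` error; constant TFAS columns yield `NA`
  correlations (flagged, not errors); all-equal FPKM is a degenerate
  quartile split and errors.
* **Determinism.** All randomness (fold assignment, simulation) is
  driven by explicit seeds through an internal save/restore wrapper, so
  package calls never perturb the caller's RNG state, and identical
  configs produce byte-identical outputs.
* **Quartile ties** are broken by gene id in a single total order, so
  labelling is deterministic; both classes have exactly
  `ceiling(n/4)` genes.
* **SVM features** are transformed `log(1 + A)` and z-scored using
  training-fold statistics only. TFAS is heavy-tailed (a sum of
  exponentially decayed lognormal intensities), and the log transform
  keeps the RBF kernel's length scale meaningful; raw features remain
  available (`transform = FALSE`). Folds are stratified by class so no
  fold is single-class.
* **Network edges** use `weight >= threshold` (so a zero threshold
  keeps all pairs); clique mining uses the strict `r_o > threshold`
  stated for the triple-combination rule. Edge specificity comes from
  the pair's `I_RV` outlier status: positive outliers are
  GM12878-specific, negative K562-specific, everything else unbiased.
  Either `R_o` or TFAS-PCC can serve as the edge weight; `R_o` is the
  default because it is the only thresholded quantity with a stated
  magnitude.
* **Outlier band.** `outlier_pairs()` uses the population (divide by
  `n`) standard deviation, strict inequalities, and flags nothing when
  the dispersion is zero.

# What the synthetic generator emulates — and what it does not

`simulate_genome()` produces evenly spaced genes (default 120 kb apart,
so all ±20 kb windows are disjoint and the filter is the identity
unless spacing is reduced) and per-factor, per-cell-line tracks:

* a `tss_enrichment` fraction of each factor's peaks sits within ±2 kb
  of a uniformly chosen host gene's TSS — chosen independently per
  factor, so factors are statistically uncoupled unless planted — and
  the rest is uniform background;
* widths are lognormal, mean 300 bp for TFs and 1500 bp for HMs
  (narrowPeak/broadPeak-like scales; chosen once as realistic values);
  intensities are lognormal and continuous, so TFAS values are almost
  surely tie-free;
* a planted pair (A, B, `co_rate`) puts A on a fixed-width lattice and
  gives a Bernoulli(`co_rate`) subset of A's peaks a B partner jittered
  strictly inside the overlap bound, with the remaining B peaks on
  lattice midpoints, provably out of reach — so the recovered `R_o` is
  exactly a binomial proportion with success probability `co_rate`;
* a planted enrichment `f_true` splits a factor's TSS-proximal peak
  budget between the cell lines in ratio `f_true : 1`. Background peaks
  that land inside gene windows dilute the recovered `f` toward 1
  (e.g. planted 4 recovers ≈ 3.2 at the default geometry), which the
  classification-band tests account for by construction, not by
  loosened thresholds;
* `simulate_expression()` sets
  `FPKM_i = exp(beta * mean(driver TFAS_i) + eps)`,
  `eps ~ N(0, noise_sd)` — a noisy monotone function with an
  exponential link so FPKM is strictly positive and quartile thresholds
  behave like real FPKM.

Passing parameter-recovery tests on this generator shows the statistics
measure what they claim under known ground truth. It does **not** show
robustness to what real ENCODE data contains and the generator omits:
mappability artifacts and blacklisted regions, chromatin-domain-scale
autocorrelation of peak placement, correlated factor binding beyond the
planted structure, multi-transcript genes sharing promoters, or
FPKM estimation noise structure. Real-data tables from two-cell-line
ENCODE analyses are therefore not reproduced here.

# Problem sizes

The test suite and the acceptance script run entirely on synthetic
data sized for tight feedback: oracle-equivalence checks use 200 random
track pairs of 5–25 peaks against an `O(N^2)` brute force; co-rate
recovery uses 2000-peak tracks over 20 seeds; enrichment-band recovery
uses 8000-peak tracks (≈ 5600 TSS-proximal) over 20 seeds per
`f_true ∈ {0.25, 1, 4}`; the SVM checks use 300 genes (150 labelled)
with 1200-peak tracks, plus 10 label permutations. These sizes make the
binomial/Gaussian sampling error of each recovery statistic small
relative to its acceptance band.

# Known limitations

* Two cell lines are assumed by the dynamics indices; the container
  functions work per pair, and N-cell-line analyses must iterate pairs.
* `R_av` treats all other factors equally; no weighting by peak count.
* The SVM scan reports balanced accuracy only — no ROC/AUC, and no
  uncertainty on per-factor accuracies beyond fold averaging.
* The pipeline caches outputs with a content-hash manifest but does not
  implement partial-stage resume; a re-run recomputes (identically).
* Peak parsing validates structure (column counts, coordinate sanity)
  but not chromosome existence against an assembly.
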