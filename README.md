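# cochip

Integrative analysis of matched ChIP-seq and RNA-seq data: where do
transcription factors (TFs) and histone modifications (HMs) bind around
gene starts, which factors co-localize, how does all of that change
between cell lines, and how much of gene expression can binding strength
predict?

`cochip` is aimed at regulatory genomicists who have per-factor peak
calls (ENCODE narrowPeak / broadPeak) for two cell lines, a gene
annotation, and per-cell-line FPKM tables, and who want a reproducible,
tested implementation of the standard battery of co-localization and
dynamics statistics rather than one-off scripts.

## The statistics

With a 40 kb window around each TSS cut into 200 bins of 200 bp, and
`N_ij` the number of peak midpoints of a factor in bin *j* of gene *i*:

* **Signal intensity** per bin: `S_j = (10^3 / n) * sum_i N_ij` over the
  `n` analysis genes (genes whose ±20 kb windows overlap another gene's
  are excluded first).
* **Cross-cell-line dynamics** of a factor: the signal ratio
  `f = sum_j S_j^G / sum_j S_j^K` and the total difference index
  `D_signal = (sum S^G − sum S^K) / (sum S^G + sum S^K)`, which satisfy
  `D_signal = (f−1)/(f+1)` identically. Factors are classified
  GM12878-rich (`f > 1.5`), K562-rich (`f < 0.6`), or unbiased
  (`0.6 < f < 1.5`).
* **Peak overlap**: two peaks with centers `S_1, S_2` and widths
  `L_1, L_2` co-localize iff `|S_1 − S_2| < (L_1 + L_2)/2` (strict,
  exact integer arithmetic). The **overlap ratio** of two factors is
  `R_o = 2n / (N_1 + N_2)` with `n` the matched-peak count; the
  **average overlap ratio** of one factor against a panel of `N` others
  is `R_av = (1/m) sum_i x_i / N`, where `x_i` counts the other factors
  touching its *i*-th peak.
* **Pair dynamics**: `I_RV = (R_G − R_K)/(R_G + R_K + α)`, `α = 0.001`;
  pairs outside the mean ± 2 sd band of `I_RV` are flagged as
  cell-line-specific.
* **TFAS** (association strength) of factor *j* on gene *i*:
  `A_ij = sum_k g_k exp(−d_k / d_0)` over the factor's peaks within
  ±20 kb of the TSS (`g_k` = signalValue, `d_k` = center–TSS distance,
  `d_0` = 2 kb). Pairwise Pearson correlation of TFAS columns and the
  thresholded `R_o`/PCC graph give the co-binding network.
* **Expression prediction**: genes are labelled high/low by FPKM
  quartiles (top and bottom 25%), and a radial-kernel SVM (libSVM via
  e1071) is scored per factor with 5-fold stratified cross-validation:
  `Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)`, `Acc = (Sn+Sp)/2`, plus the
  prediction difference `D_Acc = (Acc^G − Acc^K)/(Acc^G + Acc^K)`, which
  is correlated against `D_signal`.

A synthetic-data generator (`simulation_config()`, `simulate_genome()`,
`simulate_expression()`) plants known co-localization rates, cell-line
enrichment ratios, and TFAS-driven expression so that every statistic
above can be checked by parameter recovery.

## Worked example

```r
library(cochip)

cfg <- simulation_config(
  n_genes = 120, n_factors = 4, peaks_per_factor = 1500,
  planted_pairs = list(list(factor_a = "TF03", factor_b = "TF04",
                            co_rate = 0.8)),
  planted_enrichment = c(TF02 = 3), driver_factors = "TF01",
  tss_enrichment = 0.8, seed = 20)
sim   <- simulate_genome(cfg)
genes <- filter_nonoverlapping_genes(sim$genes)

factor_dynamics_table(sim$tracks$GM12878, sim$tracks$K562, genes)
#>   factor_name     f d_signal               label peak_count_diff ...
#> 1        TF01 0.995 -0.00270     unbiased_factor             0.0
#> 2        TF02 2.692  0.45824 GM12878_rich_factor             0.4
#> 3        TF03 1.000  0.00000     unbiased_factor             0.0
#> 4        TF04 0.994 -0.00298     unbiased_factor             0.0
```

TF02 was planted with three times more TSS-proximal signal in GM12878
than in K562; its recovered ratio `f = 2.69` (diluted toward 1 by
background peaks inside gene windows) puts it in the GM12878-rich band,
while the unplanted factors sit at `f ≈ 1`.

```r
pair_dynamics_table(sim$tracks$GM12878, sim$tracks$K562)
#>   factor_a factor_b   r_g   r_k    i_rv is_outlier
#> 1     TF01     TF02 0.672 0.462  0.1851      FALSE
#> ...
#> 6     TF03     TF04 0.793 0.808 -0.0096      FALSE
```

The planted TF03:TF04 pair recovers its co-binding rate (`R_o ≈ 0.8` in
both cell lines); the TF01:TF02 overlap is promoter crowding — both
factors are TSS-enriched, so their peaks collide near gene starts.

```r
a    <- tfas_matrix(sim$tracks$GM12878, genes)
expr <- simulate_expression(genes, a, "TF01", noise_sd = 0.4, seed = 20)
svm_scan(a, quartile_labels(expr), seed = 20)
#>   feature_set n_features    sn    sp   acc
#> 1        TF01          1 1.000 1.000 1.000
#> 2        TF02          1 0.567 0.200 0.383
#> 3        TF03          1 0.233 0.833 0.533
#> 4        TF04          1 0.233 0.833 0.533
```

The factor that drives expression classifies high/low genes perfectly;
the unrelated factors hover around the 0.5 chance floor (the two classes
are equal-sized by construction).

`run_pipeline(pipeline_config(...))` chains all stages from files on
disk to result TSVs; `inst/scripts/cochip.R` is a command-line wrapper
(`simulate`, `run`) over the same functions.

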