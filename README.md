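# sfimpute

Missing values are endemic to bottom-up label-free proteomics: in
data-dependent acquisition, 5–50% of protein intensities per replicate can
be absent, through a mixture of value-independent mechanisms (MCAR/MAR —
instrument stochasticity, misassigned peptides) and *left-censored*
missing-not-at-random loss (MNAR — low-abundance species falling below the
detection limit, or true presence/absence between conditions). Choosing an
imputation strategy that ignores this mixture distorts downstream
differential-expression statistics.

`sfimpute` implements a Selection-Filter-Imputation (SFI) workflow for
protein quantification matrices, built around a per-group MAR/MNAR hybrid
inside a multiple-imputation loop, for proteomics analysts comparing two
treatment groups of replicated label-free runs.

## What it provides

**Imputers.** Three MAR methods — *k*-nearest neighbours (inverse-distance
weighted donor averaging), iterative SVD (eigenprotein regression to a
relative change below 0.01), and multivariate-normal maximum likelihood
(EM, with conditional draws) — and three left-censored MNAR methods —
MinDet (per-sample low-quantile replacement), MinProb (Gaussian draws
centred on the MinDet value), and QRILC (quantile regression of the
observed order statistics against normal quantiles, then draws from the
estimated left-truncated tail).

**The model selector and the SFI-hybrid.** Each protein row is flagged MAR
or MNAR by an intensity rule: with an overall missing fraction π, rows
whose mean observed log2 intensity falls below the π-quantile of all row
means are treated as left-censored. The hybrid applies this selector
*within each treatment group separately* and imputes MAR-flagged rows with
kNN and MNAR-flagged rows with QRILC — so a protein entirely absent from
one group is drawn from that group's censored tail instead of being
dragged toward donors.

**The multiple-imputation engine.** The matrix is imputed, quantile
normalized, and tested *m* = 25 times (seed `base_seed + i` per
iteration; for kNN/SVD the neighbour/component count follows the iteration
index). Per-protein statistics are the empirical-Bayes moderated *t*
(variance shrinkage toward a scaled inverse-chi-square prior):

  s̃²ᵍ = (d₀·s₀² + d·s²ᵍ) / (d₀ + d),  t_g = logFC_g / (s̃ᵍ·√(1/n₁ + 1/n₂))

with two-sided p-values on d₀ + d degrees of freedom, Benjamini–Hochberg
adjustment, and Storey q-values (smoother π̂₀). Iterations are combined by
across-iteration means and SDs of logFC and −log10 q; proteins are ranked
by q-value mean and called significant at q-mean < 0.05 (strict).

**Benchmarking.** A self-contained ground-truth generator (log2 baselines
~ N(20, 2), planted effects, replicate noise), mechanism-controlled
amputation (calibrated logistic selection: MAR on a weighted sum of the
remaining columns, MNAR on the value being masked), and evaluation
metrics: capture rate, missingness bins (0/1/2/3/B2/B3), merged
top-protein lists, spread statistics, and cross-method rank ratings.

## Worked example

```r
library(sfimpute)

gt <- generate_ground_truth(n_proteins = 300, seed = 7)
gt
#> <ground_truth> 300 proteins, 6 samples, 75 true DE, 11.6% missing after amputation

cfg  <- mi_config(m = 25, params = impute_params("hybrid"), base_seed = 7)
tabs <- run_mi(gt$amputed, gt$groups, cfg)
combined <- combine_mi(tabs, mask = missing_mask(gt$amputed), g = gt$groups)
head(combined[, c("accession", "logfc_mean", "logfc_sd", "qmean",
                  "rank", "significant", "missing_bin")], 5)
#>   accession logfc_mean  logfc_sd        qmean rank significant missing_bin
#> 1    P00175   8.568517 0.3334686 2.798327e-09    1        TRUE           3
#> 2    P00001   9.228067 0.3031862 3.022902e-09    2        TRUE           3
#> 3    P00065   6.859110 0.2840314 3.302855e-09    3        TRUE           3
#> 4    P00165   7.010919 0.2848226 7.031512e-09    4        TRUE           3
#> 5    P00231  -6.950290 0.2667280 7.611445e-09    5        TRUE           3

truth <- moderated_ttest(quantile_normalize(gt$complete), gt$groups)
sum(combined$significant)
#> [1] 97
capture_rate(truth$accession[truth$significant],
             combined$accession[combined$significant])
#> [1] 96
```

The top-ranked proteins here are presence/absence cases (`missing_bin`
"3": one whole group missing) with large, stable log fold changes — the
regime in which the hybrid recovers signal that single-mechanism methods
miss. The hybrid run recaptures 96% of the proteins that the complete
(pre-amputation) data declare significant.

Real matrices enter through `read_matrix()` (wide TSV/CSV, accessions in
column 1), `filter_contaminants()` (cRAP / MaxQuant-style accession
lists), `filter_sparse()` (removes rows with abundance < 2^15 in half the
samples or fewer than 3 observations), and `log2_transform()`; a whole run
is reproducible from one YAML config via `sfi_run()` or the
`inst/cli/sfi.R` script (`run` / `simulate` / `benchmark` subcommands).

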