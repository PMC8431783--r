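---
title: "Imputation of missing values in label-free proteomics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imputation of missing values in label-free proteomics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfimpute)
```

# The missing-value problem this package models

A label-free quantification matrix holds one intensity per protein and
sample; cells are missing for two qualitatively different reasons.
Value-independent loss (MCAR/MAR) arises from acquisition stochasticity
and identification errors and is spread across the intensity range.
Left-censored loss (MNAR) arises because low-abundance species fall below
an effective detection limit — including the extreme case of a protein
genuinely absent from one condition, as in immunoprecipitation against an
IgG control. Any real dataset mixes both, and the mixture varies between
treatment groups, so a single-mechanism imputer is systematically wrong
for part of every matrix.

All imputation in this package operates on log2 intensities, where
replicate variation is approximately Gaussian; sparsity filtering operates
on the raw scale, where the 2^15 abundance cutoff is defined. The package
separates the two with an explicit `scale` flag, and represents
missingness as an explicit mask rather than sentinel zeros, because a zero
in an LFQ export may mean either "absent" or "not quantified".

# The workflow

A run is Selection → Filter → (m ×) Imputation → quantile normalization →
moderated t → q-values → combination:

1. **Selection** (`select_groups()`): columns of the two contrast groups,
   treatment block first; logFC = treatment − reference throughout.
2. **Filter** (`filter_contaminants()`, `filter_sparse()`): contaminant
   accessions, then rows with raw abundance below 2^15 (missing counts as
   below: a missing cell cannot certify abundance above the limit) in at
   least half the samples, or with fewer than 3 observed values. The two
   sparsity phrasings are both implemented and both applied by default —
   the union is the conservative reading — and each is individually
   switchable via the `rules` argument.
3. **Imputation** with one of seven strategies (below).
4. **Quantile normalization** after imputation (the matrix must be
   complete); ties share the average of the tied quantile means.
5. **Moderated t / BH / q-values** per iteration.
6. **Combination** across iterations by plain means and SDs.

## The model selector

Left-censoring implies that the missing mass sits in the low-intensity
tail. The selector therefore computes each row's mean observed log2
intensity and flags as MNAR (0) the rows whose mean lies below the
quantile of all row means at probability equal to the overall missing
fraction: if 10% of cells are missing, the lowest-abundance 10% of
proteins are modelled as censored. The quantile rule is a documented
reconstruction — the original software lineage does not print its
threshold definition — and is exposed as configuration, including forced
all-MAR and all-MNAR modes (the forced-MAR mode is what a "pure MAR"
method uses so that no left-censored draws occur). A row with no observed
value at all inside a group block is necessarily flagged MNAR there: a
whole-group absence is the archetypal censored case.

## The imputers and their parameters

| Method | Key parameters (defaults) | Character |
|---|---|---|
| kNN | `k_neighbors` 15, inverse-distance weights, `eps` 1e-10 | deterministic |
| SVD | `n_components` 6, `svd_tol` 0.01, `max_iter` 100 | deterministic |
| MLE | EM tolerance 1e-4 on the log-likelihood, `draw` TRUE | stochastic (draws) |
| MinDet | `mindet_quantile` 0.01, per-sample mode | deterministic |
| MinProb | MinDet centre, `minprob_sigma_scale` 1 | stochastic |
| QRILC | grid (π + 0.001, 0.999), 100 points, `qrilc_sigma_scale` 1 | stochastic |
| hybrid | selector + kNN (MAR) + QRILC (MNAR), per group | stochastic |

Defaults of 15 neighbours and 6 eigenproteins reflect the stability
analysis of the multiple-imputation loop: with very few donors or
components, imputed values for rows with several missing cells are highly
variable and the logFC can even change sign across iterations, so a
mid-teens neighbourhood (and as many components as small designs allow)
is the recommended single-run operating point.

Distances for kNN are Euclidean over mutually observed columns, scaled by
√(total columns / overlap) so rows with different overlap sizes compete
fairly; exact-zero distances get weight 1/ε. SVD imputation initializes
missing cells at row means and iterates rank-`n_components` eigenprotein
regression until the root-sum-of-squares change of the imputed cells,
relative to the whole matrix, drops below `svd_tol` (an absolute variant
is available). MLE treats rows as i.i.d. multivariate normal over
samples, requires more rows than columns, and ridge-regularizes a
near-singular covariance with a warning. MinProb's spread is the median
of per-row observed SDs — a global, robust choice that survives n = 3
columns, in preference to per-sample SDs. QRILC regresses the observed
order statistics on standard-normal quantiles by ordinary least squares
over 100 probabilities in (π + 0.001, 0.999) — the canonical reading of
"quantile regression" on normal Q-Q points — and draws from the fitted
normal truncated above at its π-quantile, i.e. strictly from the censored
tail.

The hybrid imputes each group's column block independently: selector on
the block, kNN across the MAR-flagged subset, QRILC on the MNAR-flagged
subset. Non-hybrid methods impute the selected matrix jointly. When a
QRILC column inside the MNAR subset has fewer than four observations, the
censored normal is fitted from the full block column instead (with a
warning); standalone QRILC keeps the hard error, since there the user can
and should filter.

## Multiple imputation and combination

Iteration *i* runs with seed `base_seed + i`, so any single iteration can
be replayed in isolation. For kNN and SVD the loop additionally sets
k/components to the iteration index (capped at the matrix limits), making
the 25 iterations a sweep of the method's own tuning parameter rather
than repeated draws of the same noise. Combination uses across-iteration
means and sample SDs of logFC and −log10 q and ranks by q-value mean
(ties broken lexicographically by accession); significance after
combination is q-mean < 0.05, strict. This is a deliberate fidelity
choice: Rubin's pooling rules are the textbook alternative but are
out of scope here, and the mean-q ranking is what the evaluation metrics
(top lists, rank ratings) are defined on. Deterministic imputers make
every iteration identical, so all SD columns are exactly zero and the
combined table is invariant to *m* — a property the test suite asserts
bitwise for MinDet.

## Differential expression statistics

Per protein, the pooled two-group residual variance s² (d = n₁ + n₂ − 2
df) is shrunk toward an empirical-Bayes prior fitted across proteins
(scaled inverse-chi-square; estimation delegated to
`limma::squeezeVar()`), giving s̃² = (d₀s₀² + ds²)/(d₀ + d) and
t = logFC / (s̃√(1/n₁ + 1/n₂)) on d₀ + d df (capped at the pooled df of
the dataset when the prior is estimated). Supplying `eb_prior(0, ·)`
recovers the classical pooled t exactly; `eb_prior(Inf, s0sq)` fixes
every posterior variance at s0sq — both limits are tested. P-values are
two-sided. q-values scale the BH step-up quantity by a π̂₀ estimated with
the cubic-smoother convention over λ ∈ {0.05, …, 0.95}, clipped to
(0, 1]; with fewer than 10 p-values π̂₀ is 1 with a warning, and π̂₀ = 1
reproduces BH exactly. No variance-intensity trend is fitted: the
original analysis does not state one, and none is implemented.

# The synthetic ground truth: what it emulates and what it does not

`generate_ground_truth()` emulates the processed form of a two-group
label-free experiment: log2 baselines ~ N(20, 2) (typical LFQ intensity
magnitudes), a fraction `frac_de` = 0.25 of proteins with effects ~
N(0, 2) added to the treatment group, replicate noise ~ N(0, 0.3), and
n = 3 replicates per group. Amputation then introduces missingness with
controlled mechanisms via calibrated logistic selection: the MAR score is
a weighted sum of the columns that remain observed, the MNAR score is the
value that would be lost (left-shaped, so low intensities go missing
preferentially); scores are standardized, the link steepness is fixed at
1, and the shift is solved numerically so the expected masked fraction
equals the requested proportion. A random allocation vector then assigns
each candidate row to one mechanism, mechanisms with proportion zero
receiving no allocation — which keeps the identity (0:0) and
single-mechanism (0:1) limits exact and, at the benchmark grid
(0.2:0.2, 0.5:0.5, 0.8:0.2, 0.2:0.8), adds missingness in the single-digit
percent range on top of the baseline, as in the study designs this
emulates.

The generator's default amputation patterns are the six single-column
masks **plus the two whole-group blocks**. `ampute()` itself defaults to
single-column patterns only; the fixture adds the block patterns because
real label-free data — and the simulated baseline this fixture stands in
for — prominently contains proteins missing an entire treatment group,
and it is exactly this presence/absence regime that separates per-group
hybrid imputation from single-mechanism methods. Under single-cell-only
missingness all reasonable imputers recover nearly the same information
and a method comparison is uninformative.

What the fixture does **not** emulate: peptide-level structure and
roll-up, correlated protein families (rows are independent given the
design), batch effects, intensity-dependent variance, or the
contaminant/shared-peptide artefacts of real searches. Passing the
benchmark therefore demonstrates correct mechanism handling and honest
statistics, not end-to-end performance on any particular instrument
dataset.

# Numerical choices and degenerate inputs

* Quantile normalization requires a complete matrix (imputation comes
  first by construction) and breaks ties by average rank.
* The sparsity rule counts a row out when the below-threshold fraction
  **reaches** `sparse_fraction` (≥, so exactly half the samples below
  2^15 removes the row); the alternative strict reading is obtainable by
  lowering the fraction.
* MinDet at quantile q uses R's type-7 empirical quantile; per-sample
  mode falls back to the global quantile for an empty column, with a
  warning.
* A QRILC slope estimate ≤ 0 (pathological input) falls back to the
  observed SD with a warning; truncated draws use inverse-CDF sampling
  with underflow guards.
* kNN cells with no eligible donor fall back to the row mean; donor
  pools smaller than k are used whole. Both warn once per call with
  counts.
* EM non-convergence and SVD non-convergence return the last iterate
  with a warning (`max_iter` 100).
* Iteration seeds are `base_seed + i`; all stochastic imputers also
  accept an explicit `seed` for standalone use.

# Problem sizes used by the checks

The test suite and the acceptance script run entirely from generated
data: oracle comparisons on 20×6 matrices (50 replicates), QRILC recovery
on 1000-value columns (50 seeds), amputation calibration on 2000×6,
false-positive control on 1000×6 null fixtures (10 seeds, all seven
methods), and the method benchmark on 400–500-protein fixtures with
m = 5 multiple-imputation iterations (10 seeds). These sizes were chosen
so the whole suite exercises every code path at statistically meaningful
scale while remaining quick to run; all scale linearly if users wish to
rerun larger.

# Known limitations

* Two-group contrasts only; factorial designs and multi-group F-tests
  are out of scope.
* Combination is by across-iteration means, not Rubin's rules, by
  design (see above); between-imputation variance is reported (SD
  columns) but not folded into the test statistic.
* The model-selector threshold is a reconstruction; datasets whose
  censoring is not aligned with row-mean abundance (e.g. strong
  sample-specific dropout) may need the forced modes or a custom
  selector.
* MLE imputation requires more proteins than samples — always true in
  practice, but it excludes toy inputs.
* Peptide-to-protein inference, vendor formats, and raw spectra are not
  handled; the package starts from a quantification matrix.
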