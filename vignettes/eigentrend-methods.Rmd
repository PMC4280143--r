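---
title: "Treatment-preserving SVD normalization: model and methods"
author: "eigenTrend authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Treatment-preserving SVD normalization: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eigenTrend)
```

## The problem

Feature tables from LC-MS metabolomics and proteomics experiments (thousands
of peak intensities across tens of samples) carry systematic variation that
has nothing to do with the biology under study: progressive signal loss as
contaminants accumulate in the ion source over a day's injections, step
changes between instrument days, and slower, harder-to-name drifts in LC
column and MS performance. Left in place, these biases widen within-group
variances, distort quantitative group comparisons, and attenuate
correlations between peak intensities and clinical measurements collected
alongside the samples. Because their shape is not known in advance, fitting
a named bias model (a linear run-order term, a batch factor) is not enough;
but removing "everything systematic" risks removing the treatment signal
itself.

eigenTrend separates the two by construction. The variation attributable to
the experimental design is captured first, per feature, with a fixed-effects
ANOVA; whatever systematic structure remains in the *residuals* is, by
definition, bias, and is discovered and removed there.

## Model and procedure

Write the log-intensity of feature $i$ in sample $j$ as

$$x_{ij} = \mu_{c(j)}^{(i)} + \sum_{k=1}^{h} \beta_{ik} v_{kj} + \varepsilon_{ij},$$

where $c(j)$ is the design cell of sample $j$ (the combination of the
treatment factor and any further fixed-effect factors), $v_k$ are unknown
unit-norm sample-indexed *bias trends* shared by all features,
$\beta_{ik}$ are per-feature loadings, and $\varepsilon$ is noise. The
pipeline is:

1. **Cell-means ANOVA** (`fitANOVA`). Each feature is fit with one mean per
   occupied design cell, using only its observed values. Residuals
   $r_{ij} = x_{ij} - \hat\mu_{c(j)}^{(i)}$ are defined only at observed
   positions and sum to zero within every cell. The cell-means
   parameterization gives exactly the residuals of any full-rank coding of
   the crossed fixed-effects model, with no contrast-coding ambiguity and
   graceful behaviour when some cells are unobserved. Features with zero
   residual degrees of freedom are excluded from trend discovery (their
   residual rows are identically zero and would only dilute the
   decomposition) and reported.
2. **SVD of the residual matrix** (`decomposeResiduals`). $R = UDV'$ on the
   rows with no missing entries. Columns of $V$ are the candidate trends;
   $d_k^2/\sum_j d_j^2$ is the fraction of residual variation each one
   carries. Restricting to complete rows avoids imputation bias in $V$;
   incomplete rows are normalized afterwards by regression on their
   observed positions. Because singular vectors are defined only up to
   sign, each column of $V$ is deterministically flipped so its
   largest-magnitude entry is positive.
3. **How many trends?** Two selectors are provided.
   `permutationTrendTest` tests trends in variance order with the
   statistic $f_k = d_k^2/\sum_{j\ge k} d_j^2$, computed on the residual
   matrix with previously accepted trends projected out. The null is
   built by permuting entries within each feature's row — destroying all
   across-sample structure while preserving each feature's residual
   distribution — and re-residualizing the permuted matrix onto the same
   subspace (orthocomplement of the design cells and accepted trends)
   before re-decomposing. Without that re-residualization the null
   spectrum is spread over more dimensions than the observed one and the
   later tests become sharply anticonservative. The step-down rule stops
   at the first non-significant trend: trends are variance-ordered, and
   accepting a later trend after rejecting an earlier one would be
   uninterpretable. `heuristicTrendCount` instead removes a fixed
   fraction of the number of samples — about 20%, rounded half-up,
   floored at 1 and capped at $n-2$ — which in metabolomics practice
   tends to normalize better than the automatically selected number (the
   permutation count works well for proteomics). Both are reported; the
   pipeline default is the heuristic.
4. **Trend removal** (`removeTrends`). For each feature the observed
   residuals are regressed *jointly* on the $h$ selected trend columns,
   restricted to the observed positions — the unique variance-minimizing
   choice, well defined under missingness — and the fitted trend part is
   subtracted. The normalized value is the ANOVA fitted treatment value
   plus the cleaned residual; adding back per-feature *fitted values*
   rather than a grand mean is what preserves the group differences by
   construction. Features with fewer than $h+1$ observations (or a
   rank-deficient restricted trend matrix) pass through unchanged and are
   flagged, never dropped; the missing-value mask is never altered.

A consequence worth knowing: estimated trends lie in the orthocomplement of
the design space (residual rows do, hence so do the right singular
vectors), so removal never changes the fitted group means of
complete-data features. Normalization improves group comparisons by
shrinking within-group variance, not by moving the means. It also means a
bias component that is *confounded* with the design (a trend whose group
means differ) is invisible to any residual-based method — the reason
run-order randomization and treatment-matched blocks matter at acquisition
time.

No residual-variance rescaling is applied after removal; whether and how
the original method rescaled is not something we assert, and
`summarizeVarianceShift` makes the variance reduction explicit instead.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `trends` | `"heuristic"` | trend-count selector (`"permutation"`, or an integer for manual) |
| `fraction` | 0.2 | samples fraction for the heuristic (dimensionless) |
| `B` | 500 | permutation replicates; p-value resolution is $1/(B+1)$ |
| `alpha` | 0.05 | step-down significance level |
| `hMax` | $n-2$ | largest trend count the permutation test will consider |
| `base`, `offset` | 2, 0 | log transform of raw tables (log2 makes loadings fold-change-like) |
| `missingCodes` | `""`, `"NA"`, `"NaN"` | cells read as unobserved; zeros only with `zeroAsMissing = TRUE`, since XCMS-style tables may contain true low intensities |

Whether the input should be log-transformed at all is exposed as a flag
rather than asserted: the scale travels with the table and downstream
stages refuse raw-scale input unless overridden.

## The synthetic-data generator

`simulateIntensities` draws tables from the additive model above with known
truth, emulating a two-group serum study run over five instrument days.
Defaults: $m = 1000$ peaks, $n = 80$ samples in two balanced groups with
randomized run order; per-feature baselines $\mathcal N(18, 1.5^2)$ on the
log2 scale (Orbitrap-like intensities around $2^{18}$); true group
log2-fold-changes $\mathcal N(0, 0.5^2)$ on 10% of features; residual noise
SD 1; and three bias trends — a within-day sawtooth (signal declining over
each day's injections), a between-day step, and a smooth sine —
orthonormalized and injected on the log scale (multiplicative signal loss
on the raw scale) with heterogeneous per-feature loadings, calibrated to
carry about 20%, 10% and 5% of the residual variance. A clinical covariate
correlated with group membership ($\rho = 0.6$) is generated alongside,
standing in for measurements such as blood glucose that track the disease
groups. The trend amplitude calibration is
$\sigma_\beta^2 = \frac{f}{1-\sum f}\, n\, \sigma_\varepsilon^2 /(1 - z)$
for a target residual-variance fraction $f$ and zero-loading fraction $z$.

Injected trends are centred within each treatment group before
orthonormalization. This emulates the matched-block design of a careful
acquisition protocol (each block containing both groups, run order
randomized within block), under which run-order bias is balanced across
treatment groups rather than confounded with them. It also makes the
validation honest: as noted above, a design-confounded bias component
cannot be removed by any residual-based method, so leaving it in would
test the acquisition design, not the normalization.

Missingness is off by default and opt-in: `missingRate` sets the overall
probability, and `mnarStrength` makes it intensity-dependent through a
logistic model on the value rank (low-abundance signals preferentially
missing, as in real LC-MS data where signal loss increases missingness).
The seed fully determines the output.

What the generator does *not* emulate: retention-time drift and peak
misalignment (upstream of a feature table), heavy-tailed or correlated
noise, QC-sample structure, and bias trends confounded with the design.
Passing the simulation-based checks therefore says the machinery works
under the stated model, not that any particular real dataset is free of
artifacts the model lacks.

With only tens of samples, per-cell missingness quickly leaves few
*complete* feature rows (at 10% missing and $n = 80$, almost none), and
trend estimation will stop with an instructive error. Real tables at such
missingness levels should be filtered to well-observed features for trend
*estimation*; removal then still applies to every estimable feature. The
validation scenarios accordingly simulate complete tables and exercise
missingness in the unit-level contracts (loadings regression, masks,
round-trips) rather than end to end.

## Downstream evaluation

`differentialTest` runs per-feature *Welch* (unequal-variance) unpaired
t-tests — the safer default when a normalization has just changed
variances and the original analysis did not state an equal-variance
assumption — with Benjamini–Hochberg step-up adjustment across features
(`bhAdjust`; `NA` p-values pass through without counting toward the number
of tests). `spearmanToCovariates` correlates features to clinical
covariates with ranks recomputed on pairwise-complete pairs (average-rank
ties); pairwise deletion is the least committal rule under missingness.
`compareRawVsNormalized` assembles the before/after report: significant
counts at a cutoff, paired correlation lists on the features with
BH-adjusted $p < 0.001$ in the normalized table (a generalization of
selecting strongly discriminatory peaks before correlating), and
per-sample medians in run order.

## Numerical choices and degenerate inputs

* Exactness targets asserted in the test suite: SVD reconstruction and $V$
  orthonormality to $10^{-8}$; BH and Welch against literal definitional
  oracles to $10^{-12}$; missing-data loadings against the restricted
  normal equations to $10^{-10}$; $h = 0$ is an identity map.
* All-zero residual matrices select $h = 0$ with a note rather than
  erroring; features that cannot be fit or normalized are flagged and
  passed through; untestable features keep `NA` p-values.
* Fewer complete residual rows than $\max(10, n)$ is an error that asks
  for stricter feature filtering rather than silently imputing.
* Ties in the sign convention (two entries of equal magnitude) resolve to
  the first index; permutation p-values use the add-one estimator
  $(1 + \#\{f^* \ge f\})/(B + 1)$, so they are never zero.
* Delimiters are auto-detected between tab and comma; files whose header
  contains both are rejected rather than guessed.

## Validation problem sizes

The packaged checks simulate $m = 1000 \times n = 80$ tables over 20 seeds
for trend recovery, type-I behaviour, effect preservation, power and
correlation improvement (with $B = 500$ permutations), and smaller
matrices ($200 \times 20$, $500 \times 60$) for the distributional and
calibration properties — sizes chosen to mirror a realistic single-study
feature table while keeping a full validation run on a laptop in minutes.

## Known limitations

* Bias confounded with the treatment design is structurally unremovable
  here (and would be silently preserved); only acquisition design guards
  against it.
* Trend estimation requires complete residual rows; datasets with
  widespread missingness need feature filtering before estimation.
* Only crossed fixed-effects designs are supported (no additive-only or
  mixed models); continuous covariates cannot be adjusted for inside the
  ANOVA stage.
* The heuristic trend count is a rule of thumb; on data whose bias
  structure is simple, it can remove more trends than the permutation
  test would, trading a little extra variance for robustness.
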