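# eigenTrend

Treatment-preserving SVD normalization of LC-MS feature tables.

LC-MS metabolomics and proteomics intensity tables (features in rows,
samples in columns) accumulate systematic biases of unknown shape:
within-day signal loss as contaminants build up in the ion source,
step changes between instrument days, and slower drifts in LC/MS
performance. These biases inflate within-group variance, blunt
differential analysis, and attenuate correlations between peaks and
clinical covariates. eigenTrend removes them while preserving the
variation attributable to the experimental design, for analysts working
with feature tables produced upstream by tools such as XCMS.

## Method

For log-intensity `x_ij` of feature *i* in sample *j*:

```
x_ij = mu_{c(j)}^(i)  +  sum_k beta_ik v_kj  +  eps_ij
```

1. A per-feature fixed-effects **cell-means ANOVA** over the design cells
   `c(j)` captures (and later preserves) the treatment variation; its
   residual matrix `R` is the substrate for bias discovery.
2. **SVD** `R = U D V'` on the complete residual rows exposes
   sample-indexed bias trends (columns of `V`), each carrying a fraction
   `d_k^2 / sum d_j^2` of the residual variation.
3. The **number of trends** `h` is chosen either by a step-down
   **permutation test** on `f_k = d_k^2 / sum_{j>=k} d_j^2` (null: entries
   permuted within each feature's row, re-residualized, re-decomposed) or
   by the metabolomics **heuristic** of about 20% of the number of samples.
4. Each feature's observed residuals are regressed jointly on the selected
   trends (**missing-value-aware least squares**) and the trend part is
   subtracted; normalized values are the fitted treatment values plus the
   cleaned residuals, so group differences survive by construction.

Downstream evaluation mirrors standard practice: per-feature Welch
t-tests with Benjamini–Hochberg adjustment, Spearman correlation of
peaks to clinical covariates, and before/after comparison reports. A
synthetic-data generator with known group effects, drift/batch trends and
(optionally intensity-dependent) missingness makes the whole pipeline
testable without external data.

## Worked example

```r
library(eigenTrend)

sim <- simulateIntensities(simulationConfig(seed = 11))
sim$table
#> IntensityExperiment: 1000 features x 80 samples
#>   scale: log  | missing: 0.0%
#>   factors: group (primary: group)
#>   covariates: covariate

res <- eigenNormalize(sim$table, trends = "permutation", seed = 11)
res@selection
#> TrendSelection: h = 3 ( permutation )
#>   p-values: 0.001996 0.001996 0.001996 0.3912  [alpha = 0.05, B = 500]

summarizeVarianceShift(sim$table, normalizedTable(res))
#>        trendVar1 trendVar2 trendVar3 primaryFactorFraction
#> before    0.1885    0.1197    0.0608                0.0129
#> after     0.0213    0.0205    0.0200                0.0203

cmp <- compareRawVsNormalized(sim$table, normalizedTable(res))
cmp$nSignificantRaw; cmp$nSignificantNorm
#> [1] 5
#> [1] 18
```

The simulation injected three bias trends carrying about 20%, 10% and 5%
of the residual variance; the permutation test finds exactly three
significant trends (p ≈ 0.002 each, the fourth clearly null). After
removal the leading residual trends drop to the noise floor (~2% each)
while the treatment fraction is intact, and the number of BH-significant
features at 0.05 rises from 5 to 18 — the sensitivity gain that motivates
normalizing before differential analysis.

A thin command-line front end wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/eigentrend.R", package="eigenTrend"))') \
    normalize --table table.tsv --design design.tsv --trends heuristic --out-dir run/
```

with `simulate` and `evaluate` subcommands alongside; every run writes a
JSON manifest (parameters, seeds, input digests) for reproducibility.

## Documentation

See the methods vignette (`vignettes/eigentrend-methods.Rmd`) for the
model, the selection test, the generator's assumptions, numerical
choices, and known limitations.
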