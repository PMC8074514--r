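# harmindex

Temporally harmonized household asset indices from multi-wave panel
surveys.

## What this is for

In low- and middle-income-country surveys, household wealth is usually
proxied by an *asset index*: the first principal component of a set of
durable-asset ownership indicators (radio, television, automobile, ...)
and housing characteristics (floor material, electricity, sanitation,
rooms per member). A separate index per survey wave ranks households
*within* a wave but cannot say whether a household got wealthier *between*
waves — each fit has its own arbitrary scale.

`harmindex` implements the harmonized construction for longitudinal
cohorts: pool all waves into one dataset, reconcile instruments that
changed over time (items absent from a wave's questionnaire are
zero-imputed where ownership was negligible, e.g. automobiles in a 1967
village census), fit **one** set of loadings to the pooled correlation
matrix, and score every household-wave record on that single scale, so
wealth trajectories across decades are meaningful. The intended users are
epidemiologists and economists working with birth cohorts or long-running
panels who need a life-course wealth exposure.

## The model

For pooled standardized indicators \(z\) with correlation matrix \(R\),
the harmonized index is the first principal component: leading eigenpair
\((\lambda_1, v)\) of \(R\), reported loadings \(v\sqrt{\lambda_1}\)
(item–component correlations), household scores \(z^\top v\) (mean 0, SD
\(\sqrt{\lambda_1}\) on the fitting sample), variance share
\(\lambda_1/p\), sign fixed so electricity loads positive. Around the
benchmark the package provides:

* two-kind missingness (not-asked vs nonresponse) with rule-checked,
  wave-aware zero-imputation;
* tetrachoric/polychoric correlation matrices by two-step maximum
  likelihood (own bivariate-normal CDF, Drezner–Wesolowsky/Genz
  quadrature), with PSD smoothing and continuity corrections, all flagged;
* one-factor minres EFA (regression scores) and MCA (correspondence
  analysis of the indicator matrix) as alternative extraction backends;
* diagnostics: standardized Cronbach's alpha, KMO, per-wave clumping and
  truncation proxies, wave summaries, external-validity correlations
  against household-linked schooling measures;
* the full S1–S5 robustness protocol (cross-sectional and urban/rural
  stratified refits, newer-asset extension, leave-out sweeps over items
  and waves, alternate correlation x extraction grids, three-level
  ordinal housing recodes), each variant compared to the benchmark by
  Spearman rank correlation on a stated household set;
* a seeded synthetic cohort generator calibrated to the published per-wave
  ownership marginals of a six-wave Guatemalan birth-cohort study
  (households 547–1145 per wave, pooled n = 4959), with a single latent
  wealth factor, within-household persistence, urban strata with the
  published sizes, and schooling measures with target latent correlations
  — the study's raw data are restricted, so this generator is what makes
  the pipeline testable end to end.

## Worked example

```r
library(harmindex)

spec  <- default_cohort_spec()          # calibrated six-wave design
panel <- simulate_panel(spec)           # household x wave x item records
cb    <- default_codebook(extended = TRUE)

bench <- harmonized_index(panel, cb)    # impute -> pool -> PCA -> score
bench
#> <harmonized_index> pca/pearson, pooled n = 4959, 19 items, PC1 share = 0.367

wave_summaries(bench$scores, codebook_waves(cb))
#> # A tibble: 6 × 9
#>   wave        n   mean    sd median    q25    q75   min    max
#> 1 1967      547 -3.79  0.933  -3.84 -4.45  -3.12  -5.51 -0.234
#> 2 1975      755 -3.04  1.40   -3.18 -4.00  -2.21  -5.50  3.07
#> 3 1987      617 -1.29  1.80   -1.17 -2.67   0.128 -5.52  2.51
#> 4 2002      820  0.922 1.37    1.15  0.205  1.82  -4.41  3.97
#> 5 2015-16  1075  1.98  1.31    2.15  1.36   2.86  -4.40  4.42
#> 6 2017-18  1145  2.00  1.30    2.19  1.31   2.90  -4.40  4.53
```

The pooled scores are centred (mean 0, SD \(\sqrt{\lambda_1} = 2.64\))
while per-wave means rise monotonically from −3.79 to 2.00: households
accumulate assets as the economy grows, and because every wave is scored
with the same loadings the increase is interpretable as wealth gain, not a
scale artifact. Loadings behave like their real-data counterparts — large
for television (0.85), sanitation (0.85), electricity (0.84) and floor
quality (0.83) on the item-correlation scale, near zero for record player,
and *negative* for radio (−0.12), whose ownership rose then fell against
the secular trend:

```r
head(tidy(bench), 5)
#>   item           loading  weight
#> 1 radio          -0.117  -0.0442
#> 2 record_player  -0.0433 -0.0164
#> 3 sewing_machine  0.303   0.115
#> 4 refrigerator    0.706   0.267
#> 5 television      0.850   0.322

diagnostics(bench$model, bench$design, bench$scores)
#> <index_diagnostics> alpha = 0.866, KMO = 0.951, PC1 variance share = 0.367
```

Internal consistency (alpha 0.87) and sampling adequacy (KMO 0.95) are in
the range expected for a one-factor asset battery; the per-wave shape
table shows higher modal shares and lower-tail truncation in the early
waves — the clumping pattern that limited early instruments produce.

The robustness protocol and plots:

```r
report <- sensitivity_report(panel, cb, bench,
                             extended_panel = panel, extended_codebook = cb)
sensitivity_summary(report)   # min Spearman r per block; all >= 0.93 here
autoplot(bench)               # per-wave score histograms
```

Shell interface over the same functions:

```sh
Rscript inst/cli/harmindex simulate --out data --seed 7
Rscript inst/cli/harmindex build --panel data/panel.csv \
    --codebook data/codebook.json --out fit
Rscript inst/cli/harmindex sensitivity --panel data/panel.csv \
    --codebook data/codebook.json --out fit --grid s1,s3,s4
```

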