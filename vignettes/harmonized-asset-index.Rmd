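---
title: "Building temporally harmonized asset indices: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building temporally harmonized asset indices: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(harmindex)
```

## The problem

Asset indices are the standard proxy for household wealth in low- and
middle-income-country surveys: a household reports ownership of durable
goods (radio, television, automobile, ...) and housing characteristics
(floor material, electricity, sanitation, crowding), and a scalar index is
extracted from the correlation structure of those indicators. A
*cross-sectional* index ranks households within one survey; it says nothing
about whether a household became wealthier between surveys, because each
wave's index has its own arbitrary scale.

`harmindex` implements the *temporally harmonized* construction: all survey
waves are pooled into one dataset, one set of loadings is estimated from
the pooled correlation matrix, and every household-wave record is scored on
that single scale. Scores are then comparable across decades — a household's
trajectory through the index is meaningful — at the cost of having to
reconcile survey instruments that changed over time.

## The harmonization model

### Items, recoding and crowding

A **codebook** declares each item's kind (`asset`, `housing`, `crowding`),
the recoding of raw response levels to binary quality codes (e.g. dirt
floor → 0, tile → 1), an optional three-level ordinal recode
(low/medium/high) for the housing-material items, and the set of waves in
which the item was actually on the instrument. The benchmark set is 19
items: 8 durable assets and 11 housing characteristics, one of which is
**crowding** — rooms per household member, kept continuous, with higher
values indicating greater wealth. Crowding is binarized at 0.75
rooms/member (strictly greater than) only where a method requires
categorical input: MCA, and — as this package's uniform convention — all
polychoric variants. The cut is a standard convention for MCA; extending it
to the polychoric fits avoids introducing a polyserial estimator for a
single column and keeps the categorical code path uniform.

### Two kinds of missingness

The data model distinguishes **not-asked** (an item absent from a wave's
instrument; all-or-none across households within a wave) from
**nonresponse** (a household-level gap in an asked item). The distinction
drives everything downstream:

* Not-asked ownership items are **zero-imputed** where the harmonization
  rules say ownership was negligible: land, record player, sewing machine,
  television, motorcycle and automobile for the 1967 wave; record player
  from 2002 onwards; and, in the extended set, the newer assets (video
  player, sound system, computer, telephone, washing machine, improved
  sewage) for the waves before their introduction. The imputation operator
  refuses to touch an (item, wave) that was actually asked, so observed
  data can never be silently overwritten.
* Nonresponse is never imputed. Records with any remaining missing value on
  the pooled item set are excluded listwise from fitting — the
  package's default, with no partial scoring unless the caller opts in by
  scoring a design they construct themselves.

### Pooling and extraction

Pooled columns are standardized with **pooled** means and SDs — one scale
across all waves. Per-wave standardization would remove exactly the
between-wave mean shifts the harmonized index is meant to measure, so it is
deliberately not available. Zero-variance columns (e.g. an item that is
imputed zero everywhere in a single-wave fit) are flagged, dropped and
reported.

The benchmark index is the **first principal component** of the pooled
Pearson correlation matrix. With unit-norm eigenvector \(v\) and leading
eigenvalue \(\lambda_1\):

* reported loadings are \(v\sqrt{\lambda_1}\) (item-component correlations,
  the "standardized loadings" scale); the raw eigenvector is stored
  alongside;
* household scores are \(z^\top v\) on the pooled z-scores, so the fitting
  sample has mean 0 and SD \(\sqrt{\lambda_1}\) exactly. This reproduces
  the characteristic pooled pattern (mean 0, SD well above 1, strongly
  negative early-wave means rising to positive late-wave means) rather
  than unit-variance scores;
* the share of variance explained is \(\lambda_1/p\);
* the sign is fixed by an orientation reference — electricity by default,
  chosen because it loads large and positive in every specification
  examined; if the reference is absent or loads exactly zero, the
  majority-of-loadings rule decides. Orientation never forces all loadings
  positive: a weakly relevant item whose ownership pattern runs against
  the secular trend (radio is the canonical example) can legitimately load
  negative.

Higher-order components are out of scope by design.

### Alternative extraction backends

For the robustness protocol the package also implements, from first
principles:

* **Tetrachoric/polychoric correlations** by two-step maximum likelihood:
  thresholds from the normal quantiles of the marginal proportions, then a
  1-D likelihood maximization (tolerance 1e-6) over bivariate-normal
  rectangle probabilities. The bivariate normal CDF uses the
  Drezner–Wesolowsky/Genz quadrature (absolute error below 1e-7, verified
  against the closed form \(\Phi_2(0,0,\rho) = 1/4 + \arcsin(\rho)/2\pi\)
  and independent quadrature). Estimates are capped at \(|\rho| \le 0.999\)
  for eigen-stability; zero cells get a +0.5 continuity correction,
  flagged per pair; an indefinite pairwise matrix is eigenvalue-smoothed
  (negatives clipped to 1e-8, diagonal renormalized) and flagged.
* **One-factor minres EFA**: loadings minimize the squared off-diagonal
  residuals \(\sum_{i<j}(r_{ij} - l_i l_j)^2\) (BFGS with analytic
  gradient; Heywood communalities clipped to 0.995 with a warning). With a
  single factor the varimax rotation is the identity, so none is applied.
  Scores use the regression method \(z R^{-1} l\). The \(R\) in that
  projection is the correlation matrix of the *observed* scored columns:
  for Pearson fits this is the fitting matrix itself, while for polychoric
  fits the latent \(R\) overstates the near-collinearity of the observed
  0/1 columns — after PSD smoothing it is numerically singular, and
  inverting it puts explosive, sign-flipping weights on smoothing-created
  null directions. Projecting with the observed Pearson matrix keeps the
  weights on the scale of the data actually being scored; the spectral
  inverse additionally truncates eigenvalues below 1e-3.
* **MCA** as correspondence analysis of the complete disjunctive coding:
  two indicator columns per item, standardized residuals
  \(S = D_r^{-1/2}(P - rc^\top)D_c^{-1/2}\), SVD. Household scores are
  first-dimension row principal coordinates (any affine rescaling leaves
  every rank-correlation comparison unchanged, which is the quantity the
  protocol reports); item loadings are the principal coordinates of the
  ownership categories; out-of-sample scoring uses the CA transition
  formula on the indicator profile.

### Diagnostics

* **Cronbach's alpha** in its standardized form
  \(k\bar r/(1+(k-1)\bar r)\) — the raw alpha of z-scored items.
* **KMO** from anti-image partial correlations of the inverse correlation
  matrix (ridge 1e-8 if singular, flagged).
* **Clumping** and **truncation** are traditionally assessed visually
  from histograms; this package operationalizes them as labelled
  quantitative proxies: the modal share and distinct-value ratio of a
  wave's scores (rounded at 1e-9 so algebraically equal scores coincide),
  and the share of a wave's households within 1% of the pooled range of
  the pooled minimum/maximum.
* **Wave summaries** use type-7 (linear interpolation) quantiles —
  documented because printed IQRs depend on the convention.
* **External validity** is the Pearson correlation between a
  household-linked external measure (parental or attained schooling) and
  the index score at the earliest (or latest) wave the household is
  observed. Index-vs-index comparisons everywhere else are Spearman
  mid-rank correlations; for external measures Pearson is the package's
  choice, flagged in the output.

### The S1–S5 robustness protocol

Every variant is refit end-to-end and compared to the benchmark by
Spearman rank correlation on a stated household set:

| Block | Variant | Comparison population |
|---|---|---|
| S1 | per-wave cross-sectional fits, optionally urban/rural-stratified in the final two waves | that wave's (stratum's) households |
| S2 | 25-item index adding the six newer assets, zero-imputed pre-2002 | per wave, 2002 onwards |
| S3 | leave-out refits: all indicator pairs, 1–2 waves, joint item x wave | households of the remaining waves |
| S4 | {Pearson, polychoric} x {PCA, EFA}, and MCA | all pooled households |
| S5 | three-level ordinal housing materials, polychoric, PCA and EFA | all pooled households |

Cross-sectional fits drop items not asked in that wave (and any
zero-variance column) rather than carrying imputed constants. After a wave
omission the comparison population is the remaining waves' households;
this convention is recorded in the output metadata.
Leave-out refits reuse the benchmark's pooled complete-case design matrix
(row/column subsetting plus restandardization), which is identical to
re-pooling whenever there is no nonresponse and makes the 306-variant
sweep run in seconds. Stratum labels are data, never inferred.

## The synthetic cohort generator

The restricted study data cannot be redistributed, so the package ships a
seeded generator that emulates the study conditions and makes every module
testable end-to-end.

**Item responses.** A single dominant latent wealth factor
\(w_{ht} = \mu_t + \delta_{ht} + \sigma_t(\sqrt{\rho}\,a_h +
\sqrt{1-\rho}\,e_{ht})\) with a persistent household effect (intraclass
correlation \(\rho = 0.6\), a stipulation — the real persistence is
unobservable) and rising wave means. Ownership follows the probit rule
\(x_{hj} = 1\{\lambda_j w_{ht} + u_{hj} > \tau_{jt}\}\), with thresholds
calibrated in closed form so each (item, wave) marginal hits its printed
target:
\[
\tau_{jt} = \lambda_j\mu_t + \sqrt{\lambda_j^2\sigma_t^2 + 1}\;
\Phi^{-1}(1 - p_{jt}).
\]
The calibration is verified both in closed form and by Monte Carlo
(tests allow 4 binomial SDs familywise across the ~120 calibrated cells,
with 95% of cells inside the pointwise 3-SD band).

**Design fidelity.** Six waves with household counts 547, 755, 617, 820,
1075, 1145; the not-asked pattern of the real instruments (record player
asked only in 1975/1987, washing machine only in the final two waves,
etc.); urban strata in the final two waves with exactly 302/1075 and
329/1145 urban households and a mean-centred urban latent shift (+0.8
between-stratum separation that leaves the wave mean, hence the calibrated
marginals, unchanged). Target marginals of 0.00 or 1.00 are taken as
0.005/0.995: near-degenerate but not constant, so the pooled fit keeps
the item while single-wave refits treat it as (almost) constant — the
behaviour such items show in real cross-sectional fits.

**Item discriminations** \(\lambda_j\) are stipulations, not estimates:
large for television, electricity, floor quality and sanitation (the items
that dominate asset indices in this setting), small for radio, record
player and house ownership (items that typically load near zero). Radio's target
marginals rise then fall, so with a small discrimination its pooled
loading can emerge negative — the tests deliberately do not assert its
sign, because it is data-dependent in the real study too.

**Crowding** is a truncated linear function of standardized latent wealth
with per-wave intercepts at the printed rooms-per-member means (slope
0.18, noise SD 0.20, floor 0.05). The three housing materials additionally
carry an ordinal level: a second threshold 0.8 below the binary one splits
the "low" band, so ordinal 2 coincides with binary 1 and a genuine middle
category exists for the S5 variant.

**External schooling** measures are generated by a Gaussian copula against
standardized latent wealth at the household's earliest (parental) or
latest (attained) wave, with target correlations 0.16, 0.10 and 0.35, then
discretized to right-skewed grade distributions via a Poisson quantile map
(mean 1.8 grades for parents, 4.5 for attained). Note the targets are
correlations with *latent* wealth: the index measures within-wave wealth
with reliability ≈ 0.85 on the default design, so the recovered
index-schooling correlation is the target shrunk by that factor — the
tests assert exactly that attenuated identity rather than pretending the
index is error-free.

**What the generator does not emulate.** Attrition and mortality,
migration, intervention effects, item-specific response biases, and any
dependence structure beyond the single factor. Passing tests therefore
show that the pipeline recovers the structure *it assumes*; they cannot
show robustness to multidimensional wealth or informative missingness in
real data.

## Problem sizes and reproducibility

The default study conditions (pooled n = 4959, 19–25 items) run the full
pipeline in under a second and the complete 306-variant S3 sweep in a few
seconds on one CPU, so tests and the acceptance script use the full design
rather than a scaled-down one. All randomness flows through the spec's
single integer seed; `simulate_panel()` and `simulate_external()` are
byte-reproducible given it, and every CLI output file carries the seed in
its metadata header.

## Worked example

```{r example, eval = FALSE}
spec <- default_cohort_spec(seed = 1L)
panel <- simulate_panel(spec)
cb <- default_codebook(extended = TRUE)

bench <- harmonized_index(panel, cb)
glance(bench)                         # method, lambda1, variance share, n
tidy(bench)                           # per-item loadings and weights
wave_summaries(bench$scores, codebook_waves(cb))
diagnostics(bench$model, bench$design, bench$scores)

report <- sensitivity_report(panel, cb, bench,
                             extended_panel = panel, extended_codebook = cb)
sensitivity_summary(report)
autoplot(bench)                       # per-wave score histograms
```

## Known limitations

* Polychoric estimation is pairwise; a jointly estimated matrix could
  differ where smoothing is needed. Smoothing and continuity corrections
  are flagged but change the matrix.
* No survey weights, no model-based imputation, no polyserial
  correlations, no bootstrap intervals on the comparison correlations —
  all outside the scope of the procedure implemented.
* Different software normalizes index scores differently; the convention
  here (unit-norm
  eigenvector on pooled z-scores) reproduces the qualitative scale
  pattern, and all robustness comparisons are rank-based, hence invariant
  to it.
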