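# ziqsir

Semiparametric association testing for **zero-inflated non-negative
outcomes** — microbiome abundances, biomarker concentrations,
health-care costs — against covariates of interest, adjusting for
nuisance covariates, without parametric assumptions on the positive
part.

## The model

For a response $Y \ge 0$ with tested covariates $Z$ (dimension $p$) and
adjustment covariates $C$ (dimension $q$), the two parts are

$$\mathrm{logit}\,P(Y > 0 \mid X) = Z^\top \eta + C^\top \gamma,$$

$$Q_Y(\tau \mid X, Y > 0) = G_\tau(Z^\top \alpha_\tau + C^\top \beta_\tau),$$

with an unspecified link $G_\tau$, and the null hypothesis is
$\eta = 0,\ \alpha_\tau = 0$ for all $\tau$.  The presence part is
tested by a logistic likelihood-ratio test.  For the positive part,
$G_\tau$ is approximated on a normalised cubic B-spline basis,
$\beta_\tau$ is estimated on the unit sphere by profile check-loss
minimisation, and a rank-score statistic

$$T_\tau = \frac{n}{\tau(1-\tau)}\, \hat s^\top
  \left(\Omega_{zz} - \Omega_{zc}\Omega_{cc}^{+}\Omega_{cz}\right)^{+} \hat s$$

is formed from the empirical score
$\hat s = n^{-1}\sum_i \{\tau - I(Y_i - \hat G_\tau(u_i) < 0)\}
\hat G^{(1)}_\tau(u_i) \hat Z_i I(Y_i>0)$, where $\hat Z_i$ removes the
spline projection of $Z_i$ onto the fitted index $u_i$.  Under the null
$T_\tau \to \chi^2_p$.  The logistic p-value $p^L$ and the per-level
p-values $p^Q_{\tau_s}$ ($\tau_s \in \{0.1, 0.25, 0.5, 0.75, 0.9\}$) are
merged by a weighted Cauchy combination

$$T_C = \hat r_n \tan\{(0.5 - p^L)\pi\}
  + (1 - \hat r_n) \sum_s w_s \tan\{(0.5 - p^Q_{\tau_s})\pi\},$$

with $\hat r_n$ the observed zero fraction and centre-heavy weights
$w_s$.  For small samples (fewer than 1000 positive responses by
default) the per-level p-values are calibrated by a fast permutation
scheme that fits the null model once and re-draws only the tested
covariates.  See the methods vignette
(`vignettes/ziqsir-methods.Rmd`) for every numerical decision.

## Worked example

Simulate a zero-inflated abundance against five covariates (Setting 1
of the built-in generator: independent sex/BMI/waist/blood-pressure
lookalikes) and test the third covariate, adjusting for the rest:

```r
library(ziqsir)
sim <- simulateZiqData(500, setting = 1, seed = 42)
d   <- simToZiqData(sim, testCoords = 3)
ziqsirTest(d, B = 199, seed = 1)
```

```
ZIQ-SIR test (permutation mode, B = 199)
  zero proportion: 0.322
  presence (logistic LRT) p = 0.004387
  tau = 0.1   T =  0.04435  p = 0.915
  tau = 0.25  T =   0.9249  p = 0.355
  tau = 0.5   T = 0.004712  p = 0.96
  tau = 0.75  T =   0.4007  p = 0.58
  tau = 0.9   T = 0.0002069  p = 1
  combined p-value: 0.02286
```

Reading this: 32% of the responses are exact zeros; the covariate
shifts the *presence* of the outcome strongly (logistic LRT
p = 0.0044) while the positive-part quantiles show no detectable shift
at any level (permutation p-values 0.36–1).  The Cauchy combination
weighs the two parts by the zero fraction and rejects at the 5% level
(p = 0.023) — the association lives in the zero pattern, a signal a
positive-part-only analysis would miss.

For a count table (features × samples) the per-feature pipeline
filters features with ≥ 80% zeros, jitters positive counts, adjusts
for library size and reports Benjamini–Hochberg q-values:

```r
res <- runFeatureTests(counts, covariates,
                       testCols = c("bmi", "waist"),
                       adjustCols = c("sex", "age"), seed = 1)
```

A command-line front end over the same functions lives at
`inst/scripts/ziqsir-cli.R` (subcommands `simulate`, `test`,
`experiment`).

## Monte Carlo studies

`typeIErrorExperiment()` and `powerExperiment()` reproduce the
simulation design the package is built around: presence coefficients
mimicking a moderately prevalent gut taxon, quantile-coefficient
curves and a quartic link (`dgpGamma()`, `dgpBeta()`, `dgpLink()`),
two covariate settings (independent / correlated), nulls obtained by
zeroing a coordinate's presence and quantile effects.

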