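# allocluster

Quantifying the consequences of ignoring clustered sampling designs in
log-log biomass allometric models.

## The problem

Biomass allometric models — power laws predicting tree biomass from
root collar diameter or height, fitted as linear models after
natural-log transformation — are usually built from *clustered* data:
several trees sampled from each of several forest stands. Trees within
a stand are more alike than trees from different stands, so ordinary
least squares (OLS), which assumes independence, understates the
uncertainty. With cluster size *n* and intraclass correlation
coefficient ICC = τ²/(τ² + σ²) (the fraction of residual variance due
to stands), the design effect

> D<sub>eff</sub> = 1 + (n − 1) · ICC

inflates sampling variances relative to an independent sample of the
same size. Ignoring it underestimates log-scale standard errors by
(√D<sub>eff</sub> − 1)/√D<sub>eff</sub> × 100 %, overestimates
t-scores by (√D<sub>eff</sub> − 1) × 100 %, narrows confidence
intervals, and inflates type-I error for near-critical tests. The
package is aimed at forest biometricians and methodologists who build
or audit allometric models: it fits both the OLS model and the
random-intercept multilevel model (REML), computes the observed and
theoretical consequence metrics, implements the Durbin–Watson bounds
test (including the ICC range it cannot detect), and validates the
whole framework by Monte-Carlo simulation on synthetic clustered
tree-biomass data.

## Worked example

Simulate a 22-stand, 10-trees-per-stand campaign with ICC 0.6, then
compare the OLS and multilevel fits of ln(TB) on ln(D):

```r
library(allocluster)

cfg   <- sim_config(J = 22, n = 10, tau2 = tau2_for_icc(0.6), seed = 42)
trees <- generate_dataset(cfg)

compare_models(trees, response = "TB", predictor = "D")
#> Model comparison: ln(TB) ~ ln(D), N = 220 trees, J = 22 stands
#>   slope: OLS 2.4159 (SE 0.0218), MLM 2.4089 (SE 0.0581)
#>   fitted ICC = 0.6365; Durbin-Watson d = 0.8246
#>   SE underestimation: intercept 62.43%, slope 62.43%
#>   t-score overestimation (slope): 166.95%
```

Both models recover the generating exponent (β = 2.4), but the OLS
standard error is 62 % too small: the 220 trees carry the information
of far fewer independent ones. The Durbin–Watson bounds test flags the
clustering, and the naive mapping ICC ≈ 1 − 0.5·d roughly recovers the
fitted ICC:

```r
dw_test(fit_ols(log(trees$D_mm), log(trees$TB_g))$residuals)
#> Durbin-Watson bounds test (N = 220, k = 1, alpha = 0.05)
#>   d = 0.8246; bounds dL = 1.770, dU = 1.788
#>   decision: positive_autocorrelation; naive ICC approximation: 0.5877

design_effect_report(n = 10, icc = 0.6365, N = 220)
#> Design-effect report
#>   cluster size n = 10, ICC = 0.637
#>   Deff = 6.729; effective N = 32.7 of 220
#>   SE underestimation (theory): 61.45%
#>   t-score overestimation (theory): 159.40%
#>   efficacy loss: 85.14%
```

The observed underestimation (62.4 %) sits on the theoretical curve
(61.5 % at the fitted ICC). `run_validation_study()` repeats this
comparison over an (ICC, n) grid with hundreds of replicates,
`type1_error_experiment()` measures type-I-error inflation for a
true-null covariate, and `render_report()` writes the study tables and
curve data. See the vignette in `vignettes/clustered-allometry.Rmd`
for the model, the estimation algorithm and all design choices.

A thin command-line wrapper ships in `inst/scripts/allocluster`:

```sh
Rscript inst/scripts/allocluster simulate --J 22 --n 10 --icc 0.5 \
    --seed 1 --out trees.csv
Rscript inst/scripts/allocluster dw --data trees.csv --response TB \
    --predictor D --alpha 0.05
```

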