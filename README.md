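# metamr

Two-sample Mendelian randomization (MR) screening of many exposures —
typically blood metabolites — against one disease outcome, from GWAS
summary statistics.

MR uses genetic variants as instrumental variables: because alleles are
randomized at conception, a variant that alters a metabolite level gives a
confounding-resistant handle on that metabolite's causal effect on
disease. For each exposure with per-SNP effects `b_x ± s_x` and outcome
effects `b_y ± s_y` on a common effect allele, the core estimator is
inverse-variance weighting over per-SNP Wald ratios:

    beta_IVW = sum(w_j * b_yj/b_xj) / sum(w_j),   w_j = b_xj^2 / s_yj^2
    se_fixed = (sum w_j)^(-1/2);  random-effects: se * sqrt(max(1, Q/(k-1)))

with MR-Egger regression (free intercept = directional pleiotropy) and the
weighted median (consistent while >= 50% of weight is valid) as
pleiotropy-robust companions, and `exp(beta)` reported as an odds ratio.
Instrument selection follows standard screening practice: exposure
`p < 1e-5`, greedy LD clumping (`r² < 0.001` within 10,000 kb), a
user-supplied confounder exclusion list, removal of palindromic (A/T, G/C)
variants during harmonization, and exclusion of weak instruments via
`F = R²(n−k−1)/((1−R²)k)` with the F > 10 rule. The sensitivity battery
covers Cochran's Q (IVW and Egger forms), the Egger intercept test,
MR-PRESSO (global / outlier / distortion), leave-one-out, and the Steiger
directionality test. A summary-level GWAS simulator with known ground
truth (causal effect, pleiotropy regime, outliers, LD blocks, palindromic
alleles) makes the whole pipeline testable without external data.

See `vignettes/mr-screening-methods.Rmd` for the full model description,
parameter conventions, and known limitations (in particular
weak-instrument attenuation).

## Worked example

Simulate one metabolite with a true causal log-OR of 0.25 on a
biobank-scale outcome, then run the full pipeline:

```r
library(metamr)

scenario <- sim_scenario(J = 50, beta_causal = 0.25, r2_exposure = 0.05,
                         n_x = 7824, n_y = 213683, seed = 42)
sim <- simulate_gwas_pair(scenario)

fit <- mr_pipeline(sim$exposure, sim$outcome, ld = sim$ld,
                   label = "metabolite_X")
fit
#> <mr_fit> metabolite_X (k = 3 instruments)
#>   ivw_fi  OR = 1.237 (95% CI 1.201-1.274), p = 1.97e-45
#>   ivw_ra  OR = 1.237 (95% CI 1.185-1.290), p = 7.6e-23
#>   egger   OR = 1.463 (95% CI 1.234-1.735), p = 0.143
#>   wme     OR = 1.244 (95% CI 1.184-1.307), p = 4.19e-18
fit$instrument_set
#> <instrument_set> metabolite_X: k = 3, R2 = 0.02057, F_overall = 54.75
```

Three SNPs survive selection (p < 1e-5, clumping, palindrome removal,
F > 10); their joint F of 54.7 indicates strong instruments. All
estimators agree in direction: the IVW odds ratio 1.237 (95% CI
1.201–1.274) recovers `exp(0.25) = 1.28` up to sampling noise and mild
weak-instrument attenuation; MR-PRESSO is not computable at k = 3 (it
needs 4) and is reported as missing rather than silently dropped.
`glance(fit)` returns the one-row diagnostic summary (Q p-values 0.13 and
0.59: no heterogeneity; Egger intercept p = 0.30: no detected directional
pleiotropy; Steiger direction exposure → outcome), `tidy(fit)` the
estimates table, and `ggplot2::autoplot(fit)` the scatter plot with one
fitted line per method.

Screening many exposures against one outcome and writing all report files:

```r
scr <- mr_screen(exposures, outcome)   # named list of tibbles, or file paths
tidy(scr)                              # one row per exposure, sorted by IVW p
render_report(scr, "results/")         # screen.tsv, significant.tsv, loo.tsv, ...
```

`run_screen_config("config.yaml")` drives the same screen from a YAML file
(paths, column maps, thresholds, seeds).

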