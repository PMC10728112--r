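---
title: "Methods: two-sample MR screening of metabolites against a disease outcome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR screening of metabolites against a disease outcome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metamr)
```

# The problem

Observational associations between circulating metabolites and autoimmune
disease are confounded by diet, medication, and reverse causation.
Two-sample Mendelian randomization (MR) sidesteps this by using genetic
variants as instrumental variables: alleles are randomized at conception,
so a variant that raises a metabolite level provides a natural experiment
for that metabolite's effect on disease risk. `metamr` implements the full
screening workflow used to test hundreds of metabolite exposures (each
measured in a metabolomics GWAS of several thousand individuals) against a
single binary outcome from a biobank-scale case-control GWAS, entirely
from summary statistics — per-SNP effect estimates `b`, standard errors
`s`, alleles, frequencies, p-values and sample sizes.

A variant is a valid instrument if it (1) associates with the exposure,
(2) shares no confounder with the exposure–outcome relationship, and
(3) affects the outcome only through the exposure. The pipeline enforces
(1) statistically, supports (2) through a user-supplied exclusion list of
known confounder-associated variants, and probes (3) with the sensitivity
battery described below.

# Instrument selection

For each exposure, candidate SNPs pass through, in order:

1. **Relevance filter** — keep SNPs with exposure `p < 1e-5` (strict
   inequality). This suggestive threshold is the screening convention when
   metabolite GWAS yield too few genome-wide-significant hits; it is
   configurable.
2. **Confounder exclusion** — set-difference against a user list
   (replaces an online phenome-scan with a reproducible input).
3. **LD clumping** — greedy reduction to independent index SNPs: rank by
   p-value (ties: smaller position, then lexicographic id), take the best
   remaining SNP, drop all others on the same chromosome within 10,000 kb
   with pairwise `r² >= 0.001` against it, repeat. Pairs absent from the
   LD table count as independent. The tie-breaks make the output fully
   deterministic; the thresholds are the standard strict settings.
4. **Harmonization** — outcome effects are re-oriented onto the exposure's
   effect allele (sign flips, strand complements); irreconcilable allele
   sets are dropped and counted. A/T and G/C (palindromic) variants cannot
   be strand-resolved from alleles alone and are removed under the default
   policy rather than rescued from allele frequencies: removal is the
   conservative screening practice, and the `keep` policy is available when
   both studies are known to report the same strand.
5. **Weak-instrument filter** — per-SNP strength is the squared
   association t-statistic `F_j = (b_x/s_x)²`; SNPs with `F_j <= 10` are
   excluded, variance explained is recomputed on the survivors as
   `R² = Σ t²/(t² + n − 2)`, and the set is retained only if the overall
   `F = R²(n − k − 1) / ((1 − R²) k)` also exceeds 10. Per-SNP r² comes
   from the t-statistic rather than allele frequencies because frequencies
   are often missing in distributed summary files.

# Estimators

With harmonized pairs `(b_xj, b_yj)` and outcome SEs `s_yj`:

- **Wald ratio** (single SNP): `b_y/b_x`, SE `s_y/|b_x|` (first-order
  delta method).
- **IVW**: weighted mean of Wald ratios with weights `w_j = b_x²/s_y²`,
  algebraically the weighted least-squares slope through the origin.
  Fixed-effects SE is `(Σw)^{-1/2}`; the multiplicative random-effects
  model inflates it by `sqrt(max(1, Q/(k−1)))`, so heterogeneity widens
  intervals but can never narrow them below the fixed-effects ones. The
  random-effects model is the screen's default significance model, as is
  conventional when heterogeneity cannot be ruled out a priori. P-values
  are normal.
- **MR-Egger**: weighted regression of `b_y` on `b_x` with a free
  intercept (weights `1/s_y²`), each SNP oriented so `b_x >= 0` — Egger
  regression is not orientation-invariant, so a deterministic convention
  is required. The intercept estimates average directional pleiotropy; the
  slope is a pleiotropy-adjusted causal estimate. SEs carry a
  multiplicative overdispersion factor floored at 1 and p-values use
  `t(k−2)`, the convention of the method's literature. The normal
  equations are solved explicitly so that exact-fit data (zero residuals)
  yield zero SEs rather than 0/0 artifacts.
- **Weighted median**: ratios sorted, cumulative midpoint weights
  `q_j = Σ_{i<=j} w_i − w_j/2` formed from normalized weights, estimate
  interpolated at `q = 0.5`. Consistent while at least half the weight
  comes from valid instruments. Its SE is a parametric bootstrap
  (default 1000 replicates, seeded): effects are resampled from their
  reported sampling distributions and the estimate recomputed.
- All estimates are reported with 95% CIs using the fixed normal
  multiplier 1.959963985 and on the odds-ratio scale (`exp`), since the
  outcome is modelled on log-odds.

# Sensitivity battery

- **Cochran's Q** for the IVW fit (`df = k−1`) and the Egger fit
  (weighted RSS, `df = k−2`); `p > 0.05` is read as no material
  heterogeneity.
- **Egger intercept test**: directional pleiotropy declared absent when
  the intercept p-value exceeds 0.05.
- **MR-PRESSO**: observed residual of each SNP against its leave-one-out
  IVW prediction; the global test compares the weighted RSS with a
  parametric null (defaults: 1000 simulations, so the smallest attainable
  p is 1/1001, the +1-corrected empirical convention); per-SNP outlier
  p-values are Bonferroni-multiplied by k and called at 0.05; when
  outliers exist, the distortion test compares the outlier-corrected
  estimate against random same-size removals. A significant global test
  does not auto-drop an exposure: the value is reported and the retention
  rule left to the analyst, since screening practice varies.
- **Leave-one-out**: random-effects IVW with each SNP omitted, flagging
  omissions that flip the sign or cross `p = 0.05`.
- **Steiger directionality**: instruments must explain more variance in
  the exposure than in the outcome. Variance explained per trait is again
  `Σ t²/(t² + n − 2)` (sums clipped below 1); the z-statistic compares
  Fisher-transformed correlations with the independent-samples variance
  `1/(n_x−3) + 1/(n_y−3)`, appropriate because the two GWAS are
  non-overlapping cohorts in two-sample MR.

Stages that need more instruments than survive (Egger and the weighted
median need 3, MR-PRESSO 4) return explicit not-computable markers, never
silent omissions; IVW with one SNP falls back to the Wald ratio with a
note.

# The screen

`mr_screen()` runs the pipeline independently per exposure and reports one
row per analyzable exposure, sorted by IVW p-value. Significance is called
at nominal `alpha = 0.05` on the selected IVW model with **no**
multiple-testing correction — the convention of hypothesis-generating
metabolome-wide screens, where every reported p-value is nominal —
but Bonferroni- and FDR-adjusted columns are emitted alongside so stricter
rules cost one `dplyr::filter()`. A consistency flag records whether IVW,
Egger and the weighted median agree in sign. Each exposure's stochastic
steps (weighted-median bootstrap, MR-PRESSO) are seeded from the base seed
and the exposure label alone, so results are identical whatever the
processing order or parallelization. `render_report()` writes
`screen.tsv`, `significant.tsv`, `estimates.tsv`, `sensitivity.tsv`,
`loo.tsv`, per-hit scatter data and a run manifest (thresholds, seeds,
input hashes); re-running an identical configuration reproduces every TSV
byte for byte.

# The synthetic-GWAS generator

`simulate_gwas_pair()` emulates the statistical structure of a real
exposure/outcome pair at the summary level — the only level the pipeline
ever observes, and the standard design for MR method evaluation:

- MAFs uniform on (0.05, 0.5); true exposure effects `γ_j` proportional to
  `|N(0,1)|` draws, scaled so the instruments jointly explain exactly
  `r2_exposure` of the exposure (the normalization is exact to 1e-12).
- A `pi_pleio` fraction of SNPs receive pleiotropic effects
  `α_j ~ N(mu_alpha, sigma_alpha²)`; `mu_alpha = 0` is balanced
  pleiotropy, nonzero is directional. The optional `inside_violation`
  adds `γ_j/2` to each pleiotropic effect, correlating strength with
  direct effects (the coefficient 1/2 makes the violation material
  without dwarfing the random component).
- True outcome effects are `β·γ_j + α_j`, plus `outlier_shift` on
  designated outliers; sampling noise uses the standard per-allele SEs
  `1/sqrt(2p(1−p)n)`.
- Alleles include a `palindrome_frac` share of A/T-or-G/C pairs (default
  1/6, their share among the six unordered biallelic SNV pairs); LD is
  encoded as exchangeable within-block `r²` in a pairwise table, because
  clumping consumes only pairwise `r²` and positions.

Defaults mirror the motivating study design: exposure n = 7824
(metabolomics-scale European GWAS), outcome n = 213,683 (538 cases +
213,145 controls, total-n convention), and `r2_exposure = 0.05` as the
per-metabolite variance-explained testing convention (real metabolite
panels vary widely and the source GWAS do not report it). Everything is
deterministic given the scenario seed; no global RNG state is touched.

What the generator does **not** emulate: individual-level genotypes,
realistic allele-frequency spectra, case-control ascertainment effects on
the log-odds scale (an OR-scale noise model is used directly), sample
overlap between the two GWAS, or LD with external reference panels.
Passing tests therefore demonstrate correctness of the estimators and the
pipeline logic under the stated model, not robustness to those real-data
features.

# Validation protocol and known limitations

The test suite validates every estimator against an independently coded
oracle (least-squares fits via `lm`, a grid-scan for the weighted median's
crossing point, hand-derived closed forms) and the whole pipeline against
its statistical guarantees, using Monte-Carlo designs with replicate seeds
drawn from fixed master seeds via `sample.int` (consecutive integer seeds
give correlated Mersenne-Twister streams and are avoided). Problem sizes:
2000 replicates for the null calibration of IVW and Cochran's Q, 500 for
parameter recovery and the pleiotropy-robustness contrast, 200–500 for
MR-PRESSO and Steiger.

Two behaviors deserve emphasis because they are properties of the methods,
not bugs:

- **Weak-instrument attenuation.** With `r2_exposure = 0.05` spread over
  50 SNPs in an exposure GWAS of 7824, the mean per-instrument F is ~8 and
  the overall F by the closed form is 8.18 — below the F > 10 comfort
  bound. In this regime IVW is attenuated toward the null by roughly a
  factor `F̄/(F̄+1)`, compounded by winner's curse when instruments are
  selected in the same sample: a true log-OR of 0.2 is estimated around
  0.178 on average, and 95% CI coverage drops to ~0.88. Selecting at
  `p < 1e-5` and filtering per-SNP F does not remove this; it is the
  documented cost of weak instruments, and the reason the F statistic is
  reported for every exposure.
- **The weighted median's guarantee is about weight, not count.** With
  40% of SNPs invalid and strongly skewed instrument strengths, the
  *realized* invalid weight share exceeds one half in a sizable minority
  of replicates, where the estimator is correctly no longer consistent.
  The robustness tests therefore evaluate replicates satisfying the
  estimator's hypothesis (invalid weight share below 0.5, established
  from the simulation's truth labels) and report how many qualify.

Other numerical choices: malformed input rows are dropped with counted
reasons, never coerced; multi-character (indel) alleles are rejected
because palindrome logic is defined only for single-nucleotide variants;
p-values are floored at the smallest positive double so extreme signals
survive the `(0, 1]` validity check; missing LD pairs mean `r² = 0`;
empty instrument sets mark an exposure skipped rather than erroring the
screen.
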