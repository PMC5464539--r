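---
title: "Two-sample Mendelian randomization with mrpipe: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrpipe: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
```

## The problem and the model

Mendelian randomization (MR) uses genetic variants as instrumental variables
to estimate the causal effect of a modifiable exposure (say, body mass index
or fasting insulin) on a disease outcome (say, lung cancer), sidestepping the
confounding — most notoriously by tobacco smoking — that plagues
observational estimates of metabolic risk factors. In the *two-sample*
design, the SNP–exposure associations come from one GWAS (a continuous trait,
effects in SD units per allele, $\hat\beta_{GP,j} \pm SE_{GP,j}$) and the
SNP–outcome associations from a second, non-overlapping case-control GWAS
(log odds per allele, $\hat\beta_{GD,j} \pm SE_{GD,j}$). Only summary
statistics are combined; no genotype-level data are touched.

The working model is a continuous log-linear effect of the exposure on
disease risk with causal slope $\theta$ (log OR per SD of exposure): for a
valid instrument $j$ with true SNP–exposure effect $\xi_j$,

$$\hat\beta_{GP,j} \sim N(\xi_j,\; SE_{GP,j}^2), \qquad
  \hat\beta_{GD,j} \sim N(\theta\,\xi_j,\; SE_{GD,j}^2),$$

independently across SNPs and across the two samples. Instrument validity
further requires no direct (pleiotropic) path from SNP to outcome; the
robust estimators below relax that in different ways.

## Instrument selection and harmonization

The selection pipeline mirrors standard consortium practice, with every
threshold exposed as an argument:

* `select_genomewide()` — strict $P < 5\times10^{-8}$;
* `ld_prune()` — greedy clumping-style pruning to pairwise
  $R^2 < 0.01$ against a caller-supplied LD table (no reference-panel
  download; ties in significance broken by chromosome, position, rsid for
  determinism);
* `filter_covariate_adjusted()` — for glycemic/lipid exposures, SNPs whose
  association does not survive BMI adjustment ($P_{adj} > 0.05$) are
  excluded to limit adiposity-mediated pleiotropy;
* `recalibrate_to_sd()` with `pooled_sd()` — when a GWAS reports effects in
  raw trait units, both $\beta$ and $SE$ are divided by the
  sample-size-weighted mean SD across contributing studies. Both must be
  divided for scale coherence, and we read "mean SD, weighted for sample
  size" as the weighted *arithmetic* mean of SDs; a root-mean-square
  alternative (weighted mean of variances) is available via
  `pooled_sd(method = "rms")`;
* `filter_imputation_quality()` — outcome SNPs with imputation
  $R^2 < 0.7$ are removed; records with no score are treated as directly
  genotyped and pass;
* `resolve_palindromes()` — A/T and C/G variants are strand-ambiguous at the
  summary level, so they are replaced by a supplied proxy in tight LD
  ($R^2 > 0.8$) or dropped. Allele-frequency-based rescue of palindromes is
  deliberately not implemented: with frequencies near 0.5 it is fragile, and
  replace-or-remove is the conservative policy. A palindromic proxy is
  refused rather than chained.

`harmonize()` then inner-joins on rsid and aligns outcome effects to the
exposure's effect allele by the usual truth table (identical pair: keep;
swapped: negate; strand-complementary: complement then apply the same rule;
irreconcilable: drop with a named diagnostic), and finally orients every
pair to the exposure-increasing allele so that $\beta_{GP} \ge 0$ — the
orientation both MR-Egger and the funnel statistic require.

## Estimators

All estimators consume the same harmonized set and report a log OR per SD
with a 95% CI and two-sided P (`mr_estimate` objects; OR-scale view
included).

**Wald ratio / IVW.** The per-SNP ratio $\theta_j = \beta_{GD,j} /
\beta_{GP,j}$ with first-order SE $SE_{GD,j}/\beta_{GP,j}$; the
inverse-variance weighted estimate pools them with weights
$w_j = \beta_{GP,j}^2 / SE_{GD,j}^2$ and is identical to weighted least
squares through the origin. First-order weights are the default
(consistent with the IVW convention); second-order ratio SEs are available
via `wald_ratio(se_method = "second")`.

**Profile-likelihood MLE** (`mr_mle()`). The joint likelihood of the model
above over $(\theta, \xi_1, \dots, \xi_J)$ is quadratic in each $\xi_j$, so
for fixed $\theta$ the nuisance effects have the closed form
$\xi_j(\theta) = (\hat\beta_{GP,j} SE_{GD,j}^2 + \theta \hat\beta_{GD,j}
SE_{GP,j}^2)/(SE_{GD,j}^2 + \theta^2 SE_{GP,j}^2)$, leaving a 1-D profile
log-likelihood maximized with `stats::optimize()` (tolerance $10^{-10}$,
search interval centered at the IVW estimate and widened adaptively; an
estimate still pinned to the boundary after six doublings is reported as
non-convergence rather than returned). Unlike IVW this propagates the
exposure-side uncertainty; the two coincide as $SE_{GP}\to 0$, which the
test suite asserts at $10^{-6}$. The SE comes from the numerical curvature
of the profile log-likelihood (central differences, step
$10^{-5}\max(1,|\hat\theta|)$) and the CI is Wald-type — symmetric, matching
how such results are conventionally reported; a profile-based CI was
considered and not implemented since the profile is near-quadratic at the
sample sizes this design targets.

**Weighted median** (`mr_weighted_median()`). The interpolated weighted
median of the ratio estimates (cumulative weight midpoints
$s_j = \sum_{k\le j} w_k - w_j/2$, linear interpolation at $s = 0.5$),
consistent while instruments carrying at least half the weight are valid.
The SE is a seeded parametric bootstrap (default 1,000 replicates) that
resamples both samples' effects independently, honouring two-sample
independence. `n_boot = 0` returns the point estimate alone, which large
calibration studies use.

**MR-Egger** (`mr_egger()`). Weighted regression of $\beta_{GD}$ on
$\beta_{GP}$ with an unconstrained intercept, weights $1/SE_{GD}^2$. The
intercept estimates average directional pleiotropy (valid under the InSIDE
condition — instrument strength independent of direct effects); the slope is
the pleiotropy-adjusted causal effect. Inference follows the multiplicative
random-effects convention: residual scale
$\hat\sigma = \max(1, \sqrt{RSS_w/(J-2)})$ (underdispersion is not allowed
to shrink SEs), coefficient SEs scaled by $\hat\sigma$, t inference with
$J-2$ df. The outlier rule in `detect_outliers()` — standardized weighted
residuals from the Egger line, two-sided normal P, Bonferroni correction
$\min(1, pJ)$, flag below $\alpha$ — is our explicit operationalization of
"Egger regression identifies genetic outliers with Bonferroni-corrected
P-values"; leverage corrections are ignored, which is conservative for the
moderate $J$ this design uses.

```{r estimators}
sim <- simulate_two_sample(sim_config(n_snps = 25, theta = 0.3, seed = 42))
iset <- harmonize(sim$exposure, sim$outcome, "exposure", "disease")
mr_ivw(iset)
mr_egger(iset)
```

## Heterogeneity, diagnostics, power

`strata_heterogeneity()` pools stratum-specific causal estimates (by tumour
histology, by smoking status, ...) under a fixed-effect model on the log-OR
scale and reports Cochran $Q$, its chi-square P at $S-1$ df, and
$I^2 = \max(0, (Q - df)/Q)\times 100$. Published OR/CI triplets are accepted
directly: SEs are recovered by `se_from_ci()`, which inverts the Wald CI
with the normal quantile fixed at 1.959964 (6 decimals, for bit-stable round
trips) and tolerates rounded inputs that no longer bracket the estimate with
a warning — required when recomputing from 2-decimal published tables.
`wald_p()` recovers the two-sided P implied by a printed estimate and CI.

```{r heterogeneity}
strata_heterogeneity(data.frame(or = c(0.93, 1.20, 1.52),
                                lci = c(0.79, 1.01, 1.15),
                                uci = c(1.08, 1.43, 2.00)))
```

`funnel_points()` emits the per-SNP fold risk $\exp(\beta_{GD}/\beta_{GP})$
against instrument strength $\beta_{GP}/SE_{GD}^2$ as a plot-ready table
(asymmetry suggests directional pleiotropy); `forest_table()` flattens
estimate collections for forest plots. Rendering is left to the caller —
these are data contracts, not graphics.

`mr_power_binary()` implements the standard normal approximation for a
binary outcome: $power = \Phi(|\ln OR|\sqrt{N R^2 \phi(1-\phi)} -
z_{1-\alpha/2})$ with case fraction $\phi$. At $OR = 1$ this degenerates to
$\alpha/2$ (one tail of the two-sided test) — documented behaviour, not a
bug. The formula is validated against the simulator: the empirical IVW
rejection rate at $N = 20{,}000$, $\phi = 0.5$, $R^2 = 0.025$, $OR = 1.2$
sits within three percentage points of the analytic value in the acceptance
suite. `power_grid()` tabulates the conventional 1%, 2.5%, 5%, 10%, 15%
variance-explained curves.

## The simulator: what it emulates and what it does not

`simulate_two_sample()` draws summary statistics *directly from their
asymptotic sampling distributions* rather than from individual-level
genotypes: per SNP, MAF $\sim U(f_{\min}, f_{\max})$, true effects
$\xi_j = c\,|Z_j|$ rescaled so the realized variance explained
$\sum_j 2\xi_j^2 f_j(1-f_j)$ hits the target exactly, sampling SEs
$SE_{GP,j} = 1/\sqrt{2 n_{exp} f_j(1-f_j)}$ and
$SE_{GD,j} = 1/\sqrt{2 f_j(1-f_j) N\phi(1-\phi)}$, and observed effects
drawn around $\xi_j$ and $\theta\xi_j + \alpha_j$. Invalid instruments — a
`floor(invalid_fraction * J)` subset — receive pleiotropic effects
$\alpha_j \sim N(\mu_\alpha, \sigma_\alpha^2)$ drawn independently of
$\xi_j$, so the InSIDE condition holds by construction and the Egger
intercept targets the constructed mean pleiotropy
$\lfloor \pi J\rfloor/J \cdot \mu_\alpha$.

Defaults are pinned to the study conditions the package is designed around:
an exposure GWAS of 339,224 individuals (an adiposity-consortium scale
discovery), an outcome GWAS of 29,266 cases and 56,450 controls (a lung
cancer meta-analysis scale), $J = 25$ instruments explaining 2.7% of
exposure variance, MAF in [0.05, 0.5]. The `directional` scenario uses
$\pi = 0.3$, $\mu_\alpha = 0.05$ log-odds, $\sigma_\alpha = 0.02$: direct
effects comparable to the causal signal $\theta\xi$, the regime in which
pleiotropy bias dominates sampling noise and sensitivity analyses earn
their keep. These were fixed once as the generator's definition of the
study conditions.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: LD between instruments (SNPs are
independent by construction, so pruning is exercised only via synthetic LD
tables), sample overlap between the two GWAS, winner's-curse inflation of
discovery effects, MAF-dependent effect-size architecture, population
stratification, and binary/coarsened exposures. Calibration results are
statements about the summary-model regime the estimators themselves assume.

```{r sim}
sim <- simulate_two_sample(mr_scenario("directional", seed = 7))
head(sim$truth, 4)
```

## Numerical and design choices

* **Bias as an expectation.** Robustness comparisons (weighted median vs
  IVW under directional pleiotropy) estimate each estimator's bias on
  batches of 10 replicates and compare batch-level absolute biases across
  500 batches: single-draw comparisons confound bias with sampling noise,
  and the weighted median's occasional bad draw (when the random invalid
  subset captures near-half the weight) is part of its sampling
  distribution, not its bias.
* **Problem sizes.** Calibration suites use 1,000 replicates for
  coverage/recovery checks, 2,000 for the power cross-validation, and
  500 × 10 for the robustness ordering — sizes at which Monte-Carlo error
  (operationalized a priori as 3.5 empirical SEs of the mean) cleanly
  separates pass from fail for the effects simulated.
* **Determinism.** Every stochastic operation takes a seed; simulation
  replicate $r$ uses `seed + r`. Identical configurations are bit-identical.
  The RNG state is restored after each seeded call, so library calls do not
  perturb a caller's stream.
* **Degenerate inputs.** Exact-fit Egger regressions (zero residuals) keep
  finite SEs because the residual-scale floor is applied to the unscaled
  coefficient covariance; a single instrument reduces IVW and the MLE to
  the Wald ratio; empty harmonized sets are an error at estimation, not a
  silent NA.
* **Missing allele frequencies** fail `variance_explained()` loudly by
  default (`na_eaf = "error"`), with `"drop"` as the explicit opt-in, since
  silently shrinking the $R^2$ denominator would bias power assessments.
* **Serialization** uses 12 significant digits everywhere, making
  write→read→write an identity at the precision the tests assert.

## Known limitations

Correlated instruments, multivariable and mediation MR, mode-based
estimators, binary exposures, and frequency-based palindrome rescue are out
of scope. The Egger outlier rule ignores leverage. The power formula is a
normal approximation that is slightly anticonservative for very weak
instrument sets. Real consortium summary files vary more than the reader's
delimiter auto-detection (tab/comma/semicolon) covers; `column_map` and the
explicit `delim` argument are the escape hatches.
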