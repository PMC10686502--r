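---
title: "Two-sample Mendelian randomization with mrkit: models, diagnostics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrkit)
```

## The causal model

Mendelian randomization (MR) treats genetic variants as instrumental
variables for a modifiable exposure. Because alleles are assigned at
conception, a variant that (1) is robustly associated with the exposure,
(2) shares no common cause with the outcome, and (3) affects the outcome
only through the exposure, identifies the causal effect of the exposure
free of the confounding and reverse causation that afflict observational
contrasts. In the two-sample setting the per-variant association estimates
come from two different GWAS: for variant $j$ we observe
$\hat\beta_{Xj}$ (effect on the exposure, with standard error
$\sigma_{Xj}$) and $\hat\beta_{Yj}$ (effect on the outcome, log-odds scale
for disease outcomes, with $\sigma_{Yj}$). Under the instrumental-variable
assumptions each Wald ratio $\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$
estimates the same causal effect $\theta$.

`mrkit` implements the standard analysis stack around this model:
instrument selection (genome-wide significance $p < 5\times10^{-8}$,
strict, plus greedy LD clumping at $r^2 < 0.001$ in a 10,000 kb window),
effect-allele harmonization, the estimator suite (`mr_fit()`), the
sensitivity workflow (`mr_sensitivity()`), multivariable MR
(`mvmr_ivw()`), and a synthetic summary-statistics generator with known
ground truth (`sim_truth()` / `simulate_pair()` / `simulate_mvmr()`).

## Estimators

**IVW.** The inverse-variance weighted estimate pools the Wald ratios with
weights $w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$ (the first-order
approximation that ignores exposure-side noise, the standard two-sample
simplification):
$$\hat\theta_{IVW} = \frac{\sum_j w_j \hat\theta_j}{\sum_j w_j},$$
which is algebraically the weighted regression of $\hat\beta_{Yj}$ on
$\hat\beta_{Xj}$ through the origin with weights $1/\sigma_{Yj}^2$ — an
identity the test suite asserts to $10^{-10}$ against `lm()`. The primary
report uses multiplicative random effects: the fixed-effect standard error
$(\sum_j w_j)^{-1/2}$ is inflated by $\sqrt{\max(1, Q/(J-1))}$, so
heterogeneity widens the interval but can never narrow it. Whether the
fixed- or random-effects flavour is primary is a configuration switch
(`ivw_mode`), since applied reports frequently leave the choice implicit;
multiplicative random effects is the default because it is the
conservative convention for the method when heterogeneity is plausible.

**MR-Egger.** Weighted regression *with* an intercept after re-signing
every pair so $\hat\beta_{Xj}\ge 0$. The slope is a causal estimate robust
to directional pleiotropy under the InSIDE assumption (instrument strength
independent of direct effects); the intercept estimates the average direct
effect. Standard errors carry the multiplicative overdispersion scale
$\max(1, \sqrt{RSS_w/(J-2)})$ and p-values use the t distribution with
$J-2$ degrees of freedom, reflecting the small $J$ at which Egger is
typically run. The fit is invariant to which subset of pairs is re-signed.

**Weighted median.** Order the ratios $\hat\theta_{(1)}\le\dots\le
\hat\theta_{(J)}$, give each half of its normalized weight at its own
position ($s_j = \sum_{i\le j} w'_i - w'_j/2$), and interpolate linearly to
$s = 0.5$. The estimate is consistent when instruments carrying at least
half the weight are valid. There is no closed-form standard error, so it
is estimated by a seeded parametric bootstrap (default 1000 resamples,
redrawing both effect vectors from normals with their reported standard
errors).

Estimates are reported as odds ratios with 95% confidence intervals,
$OR = e^{\hat\theta}$, $CI = e^{\hat\theta \mp 1.96\,se}$. Because the
exposure GWAS scale for continuous diet-style traits is whatever the
source GWAS used, ORs are interpreted *per unit of the exposure GWAS
scale*; the package deliberately does not rescale betas.

## Sensitivity workflow

`mr_sensitivity()` mirrors the reporting discipline of applied two-sample
MR:

1. **Cochran's Q** ($Q = \sum_j w_j(\hat\theta_j - \hat\theta_{IVW})^2$,
   $\chi^2_{J-1}$ under homogeneity) always runs.
2. The **Egger intercept test** (two-sided t, flag at $p<0.05$) always
   runs.
3. When the intercept flags pleiotropy, the simulation-based outlier
   procedure `mr_presso()` runs: a global test comparing the observed
   leave-one-out weighted residual sum of squares with its parametric null
   distribution; a per-variant outlier test with Bonferroni correction
   across variants; and a distortion test comparing the post-removal shift
   in the estimate against random same-size removals. Outlier removal
   triggers exactly one IVW re-estimation — the procedure is not iterated.

Simulation budgets default to 1000 draws for the global/outlier tests and
1000 random subsets for the distortion test, with the add-one rule
$p = (1 + \#\{RSS^\ast \ge RSS\})/(n_{sim}+1)$ so reported p-values are
bounded away from zero at $1/(n_{sim}+1)$ and reproducible under a seed.
Whether the null simulations also redraw exposure-side effects is a flag
(`exposure_noise`, default `TRUE`); both variants are legitimate readings
of the procedure and differ negligibly at biobank-scale precision.

## Multivariable MR

`mvmr_ivw()` regresses outcome effects on all exposure-effect columns
jointly, without intercept, weights $1/\sigma_{Yj}^2$, giving each
exposure's *direct* effect conditional on the others. Standard errors use
the same overdispersion floor as univariable IVW (scale
$\max(1,\sqrt{RSS_w/(J-m)})$, never below the homoscedastic weighted-fit
standard error), with t p-values on $J-m$ degrees of freedom. A
rank-deficient design aborts with the names of the collinear exposures.

The joint instrument set is assembled by `mvmr_instrument_union()`: the
union of each exposure's significant variants, jointly clumped with each
variant ranked by its smallest p-value across exposures. Published
analyses rarely state their assembly rule; the union is the common
convention, and a configuration switch (`mvmr_snp_set = "primary"`) offers
the main-exposure-only alternative.

The mediation signature this machinery exists to expose: when exposure A
affects the outcome only through exposure B, univariable MR of A shows a
non-null effect ($d_B \times$ the A-to-B cross effect) while the
multivariable direct effect of A collapses toward zero. The test suite
asserts at least 50% attenuation in the generator's mediation scenario.

## The synthetic-data generator

`simulate_pair()` draws, per variant,
$\hat\beta_{Xj}\sim N(\gamma_j, \sigma_{Xj})$ and
$\hat\beta_{Yj}\sim N(\theta\gamma_j + \alpha_j, \sigma_{Yj})$ with the
analytic standard errors $\sigma = 1/\sqrt{2Np(1-p)}$ implied by sample
size $N$ and allele frequency $p$ for a standardized trait. Binary-outcome
statistics are approximated as Gaussian log-odds effects with those
standard errors rather than simulating individual-level case-control data:
two-sample MR consumes only summary statistics, and this keeps every
replicate study desk-fast. Defaults are chosen once to mimic the scale of
large biobank dietary-exposure analyses and are not tuning knobs:

* `n_exp = 450000`, `n_out = 300000` — typical sizes of a UK-biobank-scale
  exposure GWAS and a national-registry disease GWAS.
* `gamma ~ U(0.015, 0.04)` on the standardized exposure: per-variant
  variance explained $2\gamma^2 p(1-p)$ of roughly 0.005–0.05%, matching
  the per-instrument $R^2$ implied by published dietary instrument tables
  (tens of instruments jointly explaining 0.1–1% of variance), with
  per-variant F statistics comfortably above the weak-instrument
  threshold of 10.
* `maf ~ U(0.05, 0.5)` — common variants, the ones that survive GWAS QC.
* Balanced pleiotropy `alpha ~ N(0, 0.002)`: direct effects comparable to
  the per-variant outcome sampling error, so pleiotropy is material
  without dominating.
* `n_snp = 50`, in the middle of the 8–106 instrument counts typical of
  dietary exposures.

Two-sided normal p-values are floored at the smallest positive double so
extreme associations stay within the record model's $(0,1]$ range.

What the generator does *not* emulate — and therefore what passing tests
do not certify about real data: LD between instruments (LD matrices are
supplied as explicit fixtures, not simulated), allele-frequency
mismatches and strand ambiguity between cohorts (exercised separately by
the harmonization unit tests), sample overlap between exposure and
outcome GWAS, winner's-curse in instrument selection, and the
non-Gaussianity of log-odds estimates when cases are very rare.

## Numerical and procedural choices

* Selection threshold is a strict inequality, $p < 5\times10^{-8}$.
* Clumping ties in p-value break by (chromosome, position) order —
  determinism over elegance. Variants missing from the LD matrix are
  treated as independent, with a warning; no reference panel ships with
  the package.
* Palindromic variants (A/T, C/G) are dropped when either allele
  frequency is missing or falls in (0.42, 0.58) — a common community
  default, configurable via `palindrome_eaf_window` — and otherwise
  aligned by frequency concordance. Strand complementing is attempted
  only after direct and swapped matching both fail, minimizing spurious
  flips.
* Instruments genome-wide significant on the *outcome* are discarded
  (exclusion-restriction hygiene); the threshold mirrors the selection
  threshold and is configurable, since applied reports rarely state it.
* Instrument strength: $r^2_j = 2\hat\beta_j^2 p_j(1-p_j)$ and
  $F = \frac{N-k-1}{k}\frac{R^2}{1-R^2}$; published instrument tables are
  numerically consistent with these forms. Both the overall F and the
  mean per-variant F are reported, as both conventions appear in print.
* A single instrument degrades `mr_fit()` to the Wald ratio; two
  instruments to IVW only; Egger and the weighted median require three,
  the outlier search four. Skipped methods carry a reason code rather
  than silently vanishing.
* The grid applies no multiplicity correction by default — each
  exposure-outcome test is reported at bilateral $\alpha = 0.05$, the
  convention of the analyses this package reproduces — with Bonferroni
  and FDR available behind `p_adjust`. A "suggestive" band (default
  $0.05 \le p < 0.10$) marks near-threshold results.

## Verification scale

The distributional checks in the test suite and acceptance script run at
fixed, stated sizes chosen to make Monte-Carlo error small relative to
the asserted margins: 500 replicates for IVW coverage of a true effect
$\theta = 0.3$ at $J = 50$; 2000 replicates for the size of the Egger
intercept test under the balanced-pleiotropy null; 500 replicates (1000
simulations each) for uniformity of the global outlier-test p-value under
the null; 100 runs for detection of a single $10\sigma_Y$ outlier among
30 instruments; 20 replicates for the mediation attenuation signature.

## Known limitations

Proxy-variant lookup for instruments missing from the outcome GWAS is not
implemented (missing variants are dropped and counted). LD is consumed,
never estimated. Mode-based estimators, MR-RAPS, Steiger filtering and
radial MR are out of scope. The Gaussian approximation to case-control
log-odds statistics degrades when case counts are tiny; with hundreds of
cases the intervals this package reports are, like those of any
summary-statistics MR, only as good as the source GWAS's asymptotics.
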