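---
title: "Methods: newborn body composition, anthropometric indices and fractional-polynomial centile standards"
author: "nbcomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: newborn body composition and centile standards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters, the design choices
that were genuinely open, and the limits of what the synthetic-data tests
can show.

## 1. The two-compartment densitometric model

A newborn's body is treated as two compartments: fat mass (FM) with
constant density $d_{FM} = 0.9007$ g/ml, and fat-free mass (FFM) whose
density rises with postnatal age as tissue hydration falls, from
$d_{FFM}(0) = 1.063$ g/ml at birth to $1.067$ g/ml at six months
(182.5 days). Only the two endpoint densities are authoritative here; the
package interpolates **linearly** between them and clamps beyond six
months — the simplest monotone choice that reproduces both endpoints
exactly. Whole-body density $D = \text{mass}/\text{volume}$ (volume from
air-displacement plethysmography) determines the fat fraction $f$ through

$$\frac{1}{D} = \frac{f}{d_{FM}} + \frac{1-f}{d_{FFM}(a)}
\quad\Longleftrightarrow\quad
f = \frac{d_{FM}\,\bigl(d_{FFM}(a) - D\bigr)}{D\,\bigl(d_{FFM}(a) - d_{FM}\bigr)},$$

then $FM = f \cdot \text{weight}$ and $FFM = \text{weight} - FM$, so mass
closes exactly. Measurement noise can push $D$ outside the physical
interval $[d_{FM}, d_{FFM}]$; such values are **clamped to 0–100% body fat
and flagged**, not rejected — real neonatal measurements are noisy and a
hard failure would make the pipeline unusable on exactly the records a
clinician most wants to see. Thoracic-gas and garment corrections of the
commercial instrument are not modelled; volume is treated as already
corrected. The inverse map `volume_from_composition()` exists so that
simulated plethysmography readings are exactly consistent with the model;
the full roundtrip composition → volume → density → composition is the
identity to well below 0.5 g at any age in [0, 182.5] days (checked over
200 random records in the test suite).

## 2. The synthetic cohort generator

The generator exists so that every downstream stage is testable without
access to clinical data. Its defaults are the study conditions: the
published moments of a large single-site newborn cohort (n = 1,019).

**What it emulates.**

- Sex: Bernoulli with boys' fraction 0.492.
- Gestational age (GA): truncated normal, mean 39.4, SD 1.6 weeks, on
  28–43⁺⁶ weeks. The truncation bounds are obstetrically plausible and
  shift the mean by under 0.014 weeks. A single truncated normal yields
  about 6.7% preterm (< 37 weeks) against the published 8.9%; the default
  keeps the single component for simplicity, and a two-component mixture
  (93% N(39.5, 1.4²) + 7% N(36.0, 1.5²)) is available via
  `ga_model = "mixture"` for users who need the higher preterm rate.
- Exam age: log-normal truncated to (0, 96] hours with parameters solved
  (meanlog 2.737574, sdlog 0.7951537) so the truncated distribution has
  mean 20.0 and SD 15.8 h — the right skew matches clinical timing, most
  exams happening on day one with a tail to day four.
- Composition: within sex, FFM and FM are linear in GA with **independent
  Gaussian residuals**. Means at the mean GA are 2,965/2,739 g (FFM,
  boys/girls) and 332/343 g (FM); slopes 169/155 g per week (FFM) and
  33/36 g per week (FM). Residual SDs are back-computed so the *marginal*
  SDs match the published 422/390 g (FFM) and 172/167 g (FM):
  $\sigma_{res} = \sqrt{\sigma_{marg}^2 - \beta^2 \sigma_{GA}^2}$. FM is
  floored at 20 g (a newborn is never fat-free).
- Postnatal loss: newborns lose weight after birth; the generator uses a
  loss fraction linear in exam age reaching 9% of birth weight at 96 h,
  with 80% of the lost mass taken from FFM (water loss). Composition is
  parameterized **on the exam scale at the cohort-average loss**: each
  record's individual loss is applied around that reference, and birth
  weight is the inflation of exam weight. This choice keeps the configured
  means and slopes unbiased targets for sample moments and OLS *and*
  encodes the decline of exam weight and FFM across postnatal age bands
  with FM nearly flat — the qualitative postnatal pattern the cohort
  tables exercise. (Drawing exam-scale composition independent of exam age
  would lose the band structure; drawing birth-scale composition at the
  published exam-scale moments would bias every calibration target by the
  mean loss.)
- Length: allometric in FFM, $L = a + b\,FFM^{1/3} + \varepsilon$, with
  $a = 7.128$, $b = 2.942$ solved against the numerically corrected
  expectation of $FFM^{1/3}$ so the per-sex length means (49.3/48.2 cm)
  are hit without per-sex intercepts, and residual SD 1.0 cm. The cube
  root keeps length positive and realistically convex in mass, and makes
  length couple far more strongly to FFM than to FM — the structural fact
  behind weight/length being the best FFM predictor.
- Head circumference: linear in FFM with per-sex intercepts (26.725 /
  27.058 cm) and slope 0.00251 cm/g, chosen so the within-sex
  FFM–head-circumference correlation is a realistic ≈ 0.7 at the published
  per-sex means.
- Body volume: the exact densitometric inverse of the generated
  composition at the record's exam age; optional Gaussian measurement
  noise (`volume_noise_sd`, default 0 so the densitometry stage roundtrips
  exactly).
- Low-risk flag: Bernoulli 0.2424 (247/1,019), independent of everything
  else; antenatal ultrasound z-scores: three iid N(0, 1) draws per record.

**What it does not emulate.** FM skewness (the real FM distribution is
slightly right-skewed; an optional shifted-log-normal residual switch
`fm_lognormal` exists but is off by default), correlation between the FM
and FFM residuals, maternal covariates, twins, missing data, and
site/device effects. Two consequences matter for interpreting tests.
First, GA-mean recovery tests compare against 39.4 weeks although
truncation biases the generator's mean by −0.013 weeks; at the test sizes
used this is far inside the 3-standard-error bands. Second, with
independent FM/FFM residuals at the published marginal SDs, the
weight/length → FFM adjusted R² on synthetic cohorts is ≈ 0.79–0.85, not
the ≈ 0.92 of the real data: in real newborns FM and FFM residuals
correlate positively, which makes FFM more predictable from total size.
The *ordering* weight/length > BMI > ponderal index for FFM — the
headline qualitative claim — is robust to this (it is asserted across 20
seeds at n = 5,000), but absolute R² values on synthetic data understate
the real ones, and passing tests show the pipeline's correctness, not the
real-data effect sizes.

Reproducibility is structural: identical (config, n, seed) gives
bit-identical tables, and the generator restores the caller's RNG stream.

## 3. Exclusions, prescriptive selection and phenotypes

The exclusion rules mirror study bookkeeping: malformations first, then
exams after 96 h, then a within-sex 3-SD screen on FM and FFM. Two
readings were open:

- *Raw vs GA-adjusted z-scores.* The screen uses the raw within-sex mean
  and SD (the simplest reading of "a value > 3 SD"); a residual-based
  variant would require committing to a regression model inside a data-
  cleaning rule.
- *Single pass vs fixed point.* Removing an outlier shrinks the SD and can
  newly expose another record, so a single pass is not idempotent. The
  screen therefore **iterates to a fixed point**; applying the exclusions
  twice then provably equals applying them once. A consequence worth
  knowing: in tiny samples a lone outlier bounds its own z-score at
  $(n-1)/\sqrt{n}$ (2.85 at n = 10), so the screen is intentionally a
  large-cohort instrument.

The prescriptive subset keeps low-risk records without remarkable
antenatal biometry (no ultrasound |z| > 4, fewer than two |z| > 3).
Phenotypes use strict centile inequalities — SGA strictly below the 10th,
LGA strictly above the 90th, wasting/stunting strictly below the 3rd, ties
to the central class — and preterm is GA < 37.0 weeks. Classification
against a standard whose domain does not cover the record's GA is refused
for that axis and flagged rather than extrapolated. Exam-age bands are
[0, 12), [12, 24] and (24, 96]: the printed band labels "12–24" and "> 24"
imply the right edge 24 belongs to the middle band.

## 4. Regression conventions

All adjusted comparisons are ordinary least squares. Confidence intervals
are estimate ± 1.95996·SE throughout. The sex contrast "at the mean GA" is
implemented as GA-centring plus a sex × GA interaction, the standard
contrast-at-a-covariate-value construction; the returned difference is
female − male. Group-difference tables use classical SEs; only the
index-evaluation models use heteroscedasticity-consistent sandwich SEs, in
the **HC1** flavour (the small-sample degree-of-freedom scaling
$n/(n-k)$) — the default of the commercial package ubiquitously used for
such analyses, and the natural reading of an unqualified "robust SEs".
The HC1 computation (delegated to the `sandwich` package) is verified in
the test suite against a brute-force
$(X'X)^{-1} X' \mathrm{diag}(r_i^2\, n/(n-k)) X (X'X)^{-1}$ oracle to
1e−8. The adjusted R² reported for an index model is that of the **full
model** including covariates, not a partial R² for the index alone — the
narrowest reading of the published table; both interpretations rank the
indices identically on synthetic cohorts (the unadjusted-fit ranking is
asserted in the tests). Tissue decompositions report shares of the weight
difference (which sum to 100 whenever the deltas close), deltas relative
to comparator tissue, and — because the published comparisons mix both —
group means as a percentage of comparator means with the corresponding
reduction; exact values are kept and rounding happens only in printing.

## 5. The fractional-polynomial centile standard

The core model fits, separately by sex, fractional polynomials with two
powers for the mean and one for the SD of an outcome across GA, under a
normality assumption (no skewness/kurtosis modelling — body-composition
outcomes are approximately normal at fixed GA, and a four-moment family
would be unidentifiable at prescriptive-subset sizes).

- **Basis.** Powers from {−2, −1, −0.5, 0, 0.5, 1, 2, 3}; $x^0 \equiv \ln
  x$; a repeated pair $(p, p)$ contributes $x^p$ and $x^p \ln x$. GA is
  divided by 10 before powering so $x^3$ and $x^{-2}$ stay within a few
  orders of magnitude of each other; the scale is stored in the model, so
  all evaluation is convention-free.
- **Estimator.** Two-stage least squares: (1) best-RSS FP2 mean fit over
  all 36 candidates; (2) FP1 fit of absolute residuals, multiplied by
  $\sqrt{\pi/2}$ (for Gaussian residuals $E|r| = \sigma\sqrt{2/\pi}$);
  (3) one reweighting pass of the mean with weights $1/\sigma^2$; (4) a
  final SD fit. The estimator behind the published standards is not
  documented beyond the FP structure; two-stage least squares is the
  transparent choice, and a joint Gaussian ML refinement at the selected
  powers (`ml = TRUE`) is provided — on well-specified data it agrees with
  the two-stage curves to within a few percent of $\sigma$ (tested).
- **Selection and ties.** Model selection is by RSS (equivalent to
  Gaussian deviance at fixed n). Ties are broken toward the pair closest
  to (1, 2), then lexicographically, so a constant response
  deterministically yields powers (1, 2) with zero slopes. Power
  *identification* is honest only when the curve components stand clear of
  the noise: near-ties among FP bases over a narrow relative GA range are
  resolved by noise, which is why the selection-stability test uses a
  signal whose log component dominates its noise floor, and why the
  SD-power recovery test spans an order of magnitude in $x$. What matters
  for standards is the fitted *curves*, which are stable even when the
  chosen powers are not.
- **SD positivity.** An SD candidate is accepted only if the fitted
  $\sigma$ is strictly positive across the observed range (the fit is
  monotone in $x$, so checking the endpoints suffices); if no candidate
  qualifies the SD falls back to a constant with a warning. Degenerate
  inputs — under 31 records, a GA span below 2 weeks, singular candidates
  — are refused or skipped with log messages.
- **Evaluation.** $z = (y - \mu)/\sigma$; centile $= \mu + \sigma
  \Phi^{-1}(p/100)$; the two are mutual inverses and the 50th centile is
  the mean curve. Centiles below 33 weeks are labelled "reference" and
  below 28 weeks additionally "caution" — labels only, same mathematics,
  reflecting where such cohorts run out of data.

**Goodness of fit.** Diagnostics are grouped over G = 6 GA-quantile bins
by default (the source analyses are silent on grouping; six bins balance
resolution against per-bin stability, and bins under 2 observations are
merged with a neighbour). The Q statistics test mean-0 and SD-1 of the
z-scores: $Q_{mean} = \sum_g n_g \bar z_g^2$, and $Q_{sd} = \sum_g v_g^2$
with the Wilson–Hilferty cube-root normalisation $v_g = [(s_g^2)^{1/3} -
(1 - \tfrac{2}{9(n_g-1)})]\sqrt{9(n_g-1)/2}$, each referred to a
chi-square with $\max(G - df, 1)$ degrees of freedom. The df deductions
default to the 3 mean and 2 SD parameters estimated from the same data;
for externally supplied z-scores nothing is estimated and both deductions
are 0 — the configuration under which the null-calibration tests run
(1,000 simulations; both rejection rates within binomial bounds of 5%).
The exact Q-statistic convention of the original analyses lives in their
cited methodology, not in the published text; the forms adopted here are
documented as this package's convention, not asserted as the authors'
computation. Worm plots are de-trended within-group QQ plots: sorted
z-scores against $\Phi^{-1}((i - 0.5)/n_g)$, ordinate = empirical −
theoretical; a location shift moves the worm bodily, a scale error tilts
it with unit slope in the theoretical quantile (both tested).

## 6. Problem sizes and numerical tolerances

The test suite works at sizes chosen to make its statistical assertions
sharp without waste: moment calibration and slope recovery on cohorts of
5,000 (with 3-standard-error bands); acceptance-level slope recovery at
10,000 per sex; centile coverage on 5,000 simulated records against 99%
binomial bands; Q-statistic calibration over 1,000 null simulations of 600
z-scores; the index-ordering claim across 20 seeds at n = 5,000; FP
recovery on noiseless data to 1e−6; the sandwich-SE oracle to 1e−8 on a
50-row fixture; densitometric roundtrips to 0.5 g over 200 random records.
RSS comparisons in model selection use a relative guard of 1e−9 so
tie-breaking is deterministic across platforms.

## 7. Known limitations

- The generator's independence of FM and FFM residuals understates
  real-data index R² (Section 2); absolute R² values from synthetic runs
  should not be quoted as real-world performance.
- The two-compartment model inherits its density assumptions; FFM density
  in late gestation may deviate from the birth endpoint, and FM, FFM and
  BF% derived from one density are complementary, not independent.
- Standards fitted on a few hundred prescriptive records have unstable
  power selection (though stable curves) and widening uncertainty at the
  GA extremes — hence the reference/caution labelling.
- The pipeline fits its classification standards internally from the
  cohort at hand; published external standards, where available, are the
  better choice for clinical classification and can be supplied to
  `classify_cohort()` directly.
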