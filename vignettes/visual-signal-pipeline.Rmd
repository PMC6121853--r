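---
title: "Modeling honest visual signals: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling honest visual signals: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`stripesignal` implements a three-stage workflow for studying dynamic color
signals in fish: (1) a receptor-noise-limited (RNL) visual model quantifies
how conspicuous a facial color pattern is to conspecifics under the ambient
light of the natural habitat; (2) staged dyadic contests link a rapidly
reversible signal — the darkness of a black facial stripe — to dominance;
(3) an out-of-equilibrium manipulation experiment (mirror-image stimulation,
MIS) measures whether unreliable signal expression is socially punished.
This vignette explains the models, the tunable parameters, and the design
decisions taken where the design was genuinely open.

## Stage 1: the visual model

### Quantum catches and adaptation

A receptor class with spectral sensitivity $S_i(\lambda)$ viewing a patch
with reflectance $R(\lambda)$ under irradiance $I(\lambda)$ absorbs

$$Q_i = \int R(\lambda)\, I(\lambda)\, S_i(\lambda)\, T(\lambda)\, d\lambda,$$

with $T$ an optional ocular-media transmission. Integrals are trapezoidal on
a common working grid, 300–750 nm in 1 nm steps; all inputs are resampled
onto it (linear interpolation, no extrapolation) so integrands can never
silently misalign. Catches are von Kries adapted: $q_i = Q_i / Q_i^{white}$,
the catch for an ideal white ($R \equiv 1$) under the same illuminant. This
makes every downstream contrast invariant to the overall intensity of the
illuminant. The ideal white is the default adaptation reference; any patch
spectrum (for example a background substrate) can be supplied instead by
adapting to it manually, since the reference enters only through a ratio.

### Receptor noise and contrasts

Channel noise is summarized by Weber fractions
$\omega_i = \nu / \sqrt{\eta_i}$, with $\eta_i$ the relative receptor
density and $\nu$ a system noise parameter. Defaults: densities
$(1, 2, 2)$ for the short-, mid-, and long-wavelength cones and $\nu$ chosen
so the long-wavelength channel has $\omega = 0.05$ — standard working values
for teleosts; all are configuration-exposed because the species' true values
are not published. Signals are logarithmic, $f_i = \ln q_i$, the appropriate
coding for suprathreshold contrasts spanning the black-to-white intensity
range; catches are floored at $10^{-9}$ (and spectra at $10^{-6}$) so logs
stay finite for near-black patches.

The chromatic distance between two stimuli with log-signal differences
$\Delta f_i$ is, for a dichromat,

$$\Delta S = \frac{|\Delta f_1 - \Delta f_2|}{\sqrt{\omega_1^2 + \omega_2^2}},$$

for a trichromat the familiar three-channel quotient, and for any $n$ the
noise-weighted Mahalanobis distance in the subspace orthogonal to the
achromatic direction,

$$\Delta S^2 = \min_c \sum_i \left(\frac{\Delta f_i - c}{\omega_i}\right)^2 ,$$

which the closed forms specialize. The unit is the just-noticeable
difference (JND); contrasts above 1 are conventionally treated as
discriminable. The achromatic contrast uses a luminance channel,
$\Delta L = |\Delta f_L| / \omega_L$ with $\omega_L = 0.05$ by default. The
luminance sensitivity defaults to the sum of the two longest-wavelength cone
sensitivities (the double-cone convention for fish) and can be overridden
with an explicit receptor. Maxwell-triangle coordinates (barycentric
projection of the normalized trichromatic catches onto a unit equilateral
triangle) are provided for visualizing chromatic positions.

### Receptor sensitivities and ambient light

Measured sensitivities are rarely available, so `pigment_template()`
synthesizes them from a single $\lambda_{max}$ with the standard A1
visual-pigment nomogram (alpha plus beta band, summed and peak-normalized;
valid for $\lambda_{max}$ in 330–600 nm). Underwater ambient light follows
Beer–Lambert attenuation, $I_d(\lambda) = I_0(\lambda) e^{-K(\lambda) d}$,
from a surface irradiance $I_0$, a diffuse attenuation coefficient
$K(\lambda)$ (m$^{-1}$), and a depth $d$. The default synthetic habitat uses
a broadband surface spectrum and a U-shaped $K$ with its minimum near
490 nm, so light at depth peaks in the blue-green as in clear lake water at
a default depth of 10 m. The species' actual cone $\lambda_{max}$ values,
ocular transmission and habitat depth are not printed in accessible sources;
the defaults are explicit placeholders, not species claims.

## Stage 1/2: conspicuousness analysis

Contrasts are computed for every unordered pair of the five facial patches
(black horizontal stripe, black vertical stripe, white, blue, yellow). A
configurable adjacency map classifies pairs; the default encodes the facial
mask qualitatively (horizontal stripe bordering white, blue and yellow;
vertical stripe bordering white and blue; white bordering blue) since the
exact scored geometry is not published. Because several pairs per fish are
reused across comparisons, all adjacent and all nonadjacent contrasts are
averaged per individual before modeling.

The adjacency models are random-intercept (fish) linear mixed models fitted
by REML with `lme4`. Achromatic contrasts are square-root transformed before
fitting; residual normality is checked by a Shapiro–Wilk test and reported
with each fit. Design choices worth stating:

* **F-tests.** Fixed-effect terms are tested with Wald F statistics;
  denominator degrees of freedom use the containment method (within-group
  terms get $N - g - p_w$, between-group terms $g - p_b$), which reproduces
  the classical nested-ANOVA df for these balanced designs (denominator 9
  for 10 fish with a within-fish factor; 18 for 20 fish). Factors are coded
  with sum-to-zero contrasts so each term's test is a main-effect test, not
  a simple effect at a reference level.
* **Variance explained.** The percent of response variance attributable to
  each fixed term is a sequential (type-I) sum-of-squares decomposition of
  the fixed design on the transformed response, in the fixed order
  adjacency, stripe intensity, interaction. The decomposition method behind
  published variance-share figures is generally unstated; sequential SS was
  chosen for exact reproducibility, and the order matches the scientific
  priority of the terms.
* **Change tests.** Which pair types change with dominance is assessed by
  two-sided Mann–Whitney tests (dominant vs subordinate fish) per pair
  type, with Benjamini–Hochberg false-discovery-rate control applied within
  each contrast kind (chromatic and achromatic families separately),
  matching the per-panel flagging convention of figure-style summaries.

## Stage 2: contest analysis

Contests are same-sex dyads matched on standard length and mass. Matching is
verified with a paired Wilcoxon signed-rank test on within-pair differences
(reported with its conventional $V$ statistic; exact p for $\le 25$ pairs,
normal approximation with continuity correction otherwise). Dyads are
paired by design, which is why a paired procedure is used even where an
unpaired label is sometimes attached to the same $V$ statistic in reports.

A fighting-ability index is the count of aggressive minus submissive
behaviors, scored from a time-sorted ethogram event stream against a
declared code-to-valence table. Winner/loser labels are inputs (scored from
video in real studies; assigned from latent ability by the generator), never
computed by the package.

Mass and fighting ability are modeled with pair-random-intercept LMMs
(success, sex, interaction). The association between stripe state and
contest outcome is a binomial logit mixed model with pair as random
intercept, tested by a single-df likelihood-ratio test, at both timepoints:
the end-of-contest state reflects current dominance; the begin state should
not predict the coming outcome. If the outcome is completely separated by
stripe state the mixed likelihood is degenerate: the package flags it, and
reports the odds ratio from a bias-reduced (Firth-penalized) fixed-effects
logistic fit, implemented in-package with the hat-diagonal score
correction. The "aggression level vs end-stripe-state" question is modeled
as a fighting-ability response on the end state — an interpretation, since
the published specification of that model is incomplete.

## Stage 3: punishment analysis

Each fish is tested twice, with two of the three treatments (darkened,
paled, control sham) in randomized order. Aggressive bouts received are
modeled on the square-root scale (counts generated as Poisson-lognormal are
overdispersed, which is exactly why the transform helps); latency to attack
is left untransformed by default, with a log option, because only the bouts
transform is part of the canonical recipe. Individual and treatment order
enter as crossed random intercepts. Treatment contrasts use Tukey HSD via
`multcomp::glht` with single-step familywise adjustment of the three
pairwise z statistics.

Fold effects are ratios of raw-scale treatment means (bouts:
darkened/paled, darkened/control, paled/control; latency: control/darkened,
control/paled, i.e. "how many times shorter"), with percentile bootstrap
confidence intervals resampling fish (both trials together; 2000 resamples,
seeded). Latencies censored at the trial duration (600 s by default — the
handling convention is the package's own, since none is published) are
excluded from latency means but counted and reported; censoring can never
affect bout outputs.

## The synthetic-data generator

The generator produces data with the statistical structure the analyses
assume, so the whole pipeline is testable without the original
measurements. What it emulates, per module:

* **Spectra.** Black stripes are low-reflectance with a melanin-brown tilt
  (reflectance rising with wavelength). The tilt matters twice: melanin
  really is brownish rather than spectrally flat, and perfectly flat black
  and white patches would all sit at the white point of the chromaticity
  space, which would misrepresent the pattern's chromatic structure. Paling
  scales the stripe curve multiplicatively (dark 0.04 to pale 0.20), which
  leaves its chromatic position unchanged — exactly the "luminance channel
  moves, chromatic channel does not" property the study design turns on.
  White is flat at 0.80; blue is a Gaussian band (470 nm peak); yellow is a
  moderately saturated long-pass sigmoid (0.15 to 0.45, cutoff 540 nm).
  Smooth multiplicative noise (spline through random knots, sd 0.05) stands
  for measurement error and between-individual variation together.
* **Contests.** 20 same-sex pairs by default, sizes matched within pairs
  (within-pair sd 0.3 cm); winning follows a logistic function of the
  latent size difference; winners behave aggressively at a higher Poisson
  rate than losers (40 vs 15 aggressive, 5 vs 25 submissive events per
  combat); both fish start dark-striped and losers pale with probability
  0.9 (winners 0.1).
* **Mirror trials.** 48 fish by default. Bouts are Poisson-lognormal with
  treatment multipliers 1.0 (control), 1.5 (paled), 2.6 (darkened),
  individual sd 0.3 and a small second-trial order effect; latencies are
  lognormal with multipliers 1/1.2 (paled) and 1/1.7 (darkened) relative to
  a 120 s control baseline, censored at the 600 s trial duration. The
  multipliers are generator parameters chosen to produce effect sizes of
  the magnitude reported for this kind of experiment; they are not measured
  values, and recovering them from generated data is part of the test
  suite, not evidence about real fish.

What the generator does **not** emulate: the exact shapes of measured
reflectance, sensitivity or irradiance curves; spatial pattern geometry
beyond the pairwise adjacency map; viewing distance and spatial acuity;
temporal dynamics of color change; any behavioral validation of the 1 JND
criterion. Passing tests on synthetic data therefore demonstrate that the
machinery is correct and calibrated — not that real fish behave this way.

## Numerical choices and degenerate inputs

* Spectra are clamped to $[10^{-6}, 1]$ (reflectance-like kinds) before
  logs; catches to $\ge 10^{-9}$.
* Rank tests use exact p-values up to 25 observations, then a normal
  approximation with continuity correction; all-zero difference vectors
  report p = 1 rather than erroring.
* REML fits ignore the singular-fit warning class deliberately: boundary
  variance estimates are legitimate (and are exactly the case in which the
  mixed-model F collapses onto the fixed-effects ANOVA F, a property the
  tests exploit).
* Complete separation in the outcome model triggers the Firth fallback
  described above rather than reporting a divergent odds ratio.
* Bootstrap ratios with a zero-mean denominator are reported as `NA`, never
  as infinities.

## Problem sizes used by the test suite

The statistical calibration tests run 500 null replicates per procedure at
study-like sizes (20 fish for the adjacency model, 20 pairs for the
contest model, 48 fish for the mirror-trial model), and the recovery tests
use 200 replicates at 20 fish, one dataset of 500 fish for the bout
multipliers, and 1000 pairs for the paling probability. These sizes give
Monte Carlo bands (three binomial standard errors) tight enough to detect
real miscalibration while keeping the default test run fast.

## Known limitations

* The RNL model ignores spatial and temporal vision entirely; conspicuous
  is defined pairwise and at close range.
* Containment df are exact for the balanced designs produced here; for
  badly unbalanced real datasets a Satterthwaite or Kenward–Roger
  approximation would be preferable.
* The sequential variance partition depends on term order (stated above and
  fixed); a different convention will give different shares on the same
  fit.
* The Firth fallback is a fixed-effects approximation: it drops the pair
  random intercept, which is defensible exactly in the separated case where
  that variance is not identifiable anyway.
* Censored latencies are excluded, not modeled; with heavy censoring a
  survival model would be the right tool and is out of scope here.
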