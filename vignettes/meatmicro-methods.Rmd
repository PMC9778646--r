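---
title: "Methods: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meatmicro)
```

`meatmicro` bundles four pieces of machinery around the microbiological
quality of minced beef: the m/M classification scheme, a synthetic
surveillance-data generator, a 9-10-4 perceptron with goodness-of-fit
metrics, and Yoon connection-weight sensitivity analysis. This vignette
explains each model, the parameters that matter, and the design decisions
that were genuinely open.

## The m/M classification scheme

Food-hygiene guides classify a count result `x` (log10 CFU/g) against two
limits `m < M`: satisfactory when `x ≤ m`, acceptable when `m < x ≤ M`,
unsatisfactory when `x > M`. Two boundary conventions were possible; we
place a result *exactly equal* to a limit in the lower (better) class,
following the usual reading that a result "less than or equal to the limit"
complies with it.

For a replicate set of `n` units (five is typical), the sampling-plan rule
takes a tolerance number `c < n`: any unit above `M` condemns the batch;
otherwise up to `c` units may sit in `(m, M]` for an *acceptable* verdict,
more than `c` is *unsatisfactory*, and all units at or below `m` is
*satisfactory*. The guides that describe five repetitions do not fix `c`;
we default to `c = 2` for `n = 5`, the tolerance number used by the EU
microbiological-criteria regulation for comparable minced-meat plans, and
expose it as an argument. Note one consequence of the rule as written:
when *every* replicate falls in `(m, M]`, the count in the band exceeds any
admissible `c`, so the verdict is unsatisfactory even though no single unit
breached `M`.

Presence-based criteria (Salmonella spp., *L. monocytogenes*: absence in
25 g) have no intermediate class: detection is unsatisfactory, absence is
satisfactory. Lactic acid bacteria carry no regulatory limit and are
summarised as a histogram over `[0,2)`, `[2,4)`, `[4,6)`, `[6,7]` log10
CFU/g instead; counts above 7 log10 CFU/g are the conventional spoilage
association and are flagged by the binning function rather than folded
into the three-level scheme.

A batch tested for several analytes inherits its worst per-analyte class.

## The synthetic surveillance generator

No dataset for this surveillance design was ever deposited, so the
generator recreates its statistical structure; every downstream stage is
tested against simulated tables.

**Design.** Three seasons, 24 sampled weeks per season, Monday/Wednesday/
Friday: 3 × 24 × 3 = 216 sampling events. The season is indexed by week
number, not calendar dates — the published design (January–June) would
admit ~26 weeks, but 24 weeks is the value that reconciles the stated
weekday pattern with the stated total of 216 samples, so the generator
defaults to it and exposes `weeks_per_year`. Butchers A–D rotate
deterministically one event at a time by default (the real shift pattern
was not published); any rotation sequence can be supplied.

**Temperatures.** Storage temperature is Normal(4, 1) °C clipped to the
cold-chain range [2, 7] °C; meat temperature adds a non-negative
Normal(1.5, 0.8) offset, so meat never arrives colder than its storage
environment. The clipped storage mean is ≈ 4.01 °C.

**Counts.** Each analyte follows
`count = baseline + butcher_effect + weekday_effect +
slope · (meat_temp − 4) + N(0, σ)`, clipped to [0, 9] log10 CFU/g
(clipping, not resampling: clip events are rare except for *S. aureus*,
where the sub-zero baseline deliberately produces a large point mass at 0,
i.e. below detection). Salmonella positivity is Bernoulli(0.069);
*L. monocytogenes* is never detected under defaults, matching a
surveillance record with zero detections.

**Calibration.** The defaults were fitted once, against the package's own
classifier at 200,000 simulated samples, to reproduce the published class
marginals: MAB (32.85, 26.85, 40.3) % satisfactory/acceptable/
unsatisfactory, *E. coli* (95.4, 4.6, 0), *S. aureus* (94, 3.7, 2.3), and
a LAB histogram with modal bins 2–4 and 4–6 log10 CFU/g. Those marginals
fix each analyte's total distribution but not how its variance splits into
systematic signal and noise; we allocate a large share to butcher,
weekday and temperature effects (e.g. MAB butcher effects A +0.2, B −2.1,
C +1.2, D +0.7 log10 CFU/g around baseline 5.07, residual σ = 0.70) so
that the simulated study, like the real one, has a strongly
butcher-driven microbial profile with effect signs echoing the published
sensitivity analysis. The *S. aureus* marginals are the binding
constraint in the other direction: placing 94 % of samples at or below
2 log while keeping 2.3 % above 3 log forces a wide noise tail
(σ ≈ 2.1), so that analyte remains mostly irreducible noise whatever the
effect sizes.

**What the generator does not emulate.** Real calendar structure and
holidays, transport times, spoilage kinetics over shelf life, serial
correlation between consecutive sampling days, and any distribution shape
beyond clipped Gaussians. Tests passing on synthetic data therefore
demonstrate that the machinery is correct and calibrated, not that the
trained network would perform identically on the original measurements.

## The 9-10-4 perceptron

The network maps nine features — storage temperature, meat temperature,
one-hot butcher (A–D), one-hot weekday (Friday, Monday, Wednesday) — to
the four counts through ten logistic hidden units and an identity output
layer:

$$y = W_2 \,\sigma(W_1 x + B_1) + B_2, \qquad \sigma(t) = 1/(1+e^{-t}).$$

Choices that the source material left open:

* **Normalization.** The original analysis normalized its data without
  stating the method; we use min–max scaling to [0, 1] of the two
  temperatures and all four outputs (one-hot columns pass through), the
  common default of the modelling software family used for such networks.
  Because the original scaling ranges are unrecoverable, the published
  weight fixture is used only for weight-structure analyses (sensitivity,
  symmetry tests), never for physical-unit prediction.
* **Optimizer.** BFGS on the sum-of-squares error with an analytic
  gradient, run in segments of `check_every = 25` iterations; after each
  segment the validation SOS is checked and training stops once it has
  failed to improve for `patience = 3` consecutive checks (the
  operational version of "training until the learning and validation
  curves flatten"), returning the best-validation parameters. The total
  budget is `max_iter = 10000`, far more than the early stopping
  typically uses.
* **Splits and initialization.** 70/15/15 train/test/validation at random
  under the training seed (fractions were not published); initial weights
  uniform in [−0.1, 0.1]. All randomness flows from the one seed, making
  fits exactly reproducible.
* **Restrained early stopping is deliberate.** Longer training keeps
  shrinking the training SOS but inflates the weight magnitudes, and
  connection-weight importances computed from over-trained networks lose
  their interpretability: in our experiments the planted butcher sign
  pattern was recovered far less often with aggressive optimization
  (wider initialization, tighter tolerance) than with the restrained
  defaults. Prediction-focused users can lengthen `patience` and
  `max_iter`; `reltol` tightens the BFGS stopping rule for
  high-precision fits on noiseless data.

**What r² means here.** `tidy()`/`glance()` report, per split, the mean
over the four analytes of `1 − SS_res/SS_tot` on the original count scale.
Under the default generator this lands around 0.4: MAB is predicted well
(per-analyte r² ≈ 0.7) but *S. aureus* is mostly noise by construction
(r² ≈ 0), which caps the average. The original study reported a training
performance of 0.867 on its real (undeposited) measurements; that value is
not a reproduction target here, and the structural reason the synthetic
default cannot reach it is the marginal-calibration constraint described
above.

**Verification.** On noiseless data generated by a known 9-10-4 network
the trainer recovers the input–output map almost exactly (held-out
r² ≥ 0.99; per-analyte RMSE on the order of 10⁻³–10⁻² — BFGS plateaus
before numerical zero on this 144-parameter nonconvex surface, which is
why the tests assert the r² form of the recovery property).

## Goodness-of-fit metrics

For observed `x_exp` and predicted `x_pre` of length `N` with `n`
constants:

$$\chi^2 = \frac{\sum_i (x_{exp,i}-x_{pre,i})^2}{N-n},\quad
RMSE = \Big[\tfrac1N\sum_i (x_{pre,i}-x_{exp,i})^2\Big]^{1/2},$$
$$MBE = \tfrac1N\sum_i (x_{pre,i}-x_{exp,i}),\quad
MPE = \frac{100}{N}\sum_i \frac{|x_{pre,i}-x_{exp,i}|}{x_{exp,i}},$$

plus `r² = 1 − SS_res/SS_tot` (the sum-of-squares definition, not a
squared correlation) and residual moments. Conventions that had to be
chosen: skewness is the moment estimator `g1 = m3/m2^{3/2}` and kurtosis
the excess `g2 = m4/m2² − 3` (computed via `e1071`, type 1) — recorded in
the result's `"conventions"` attribute; MPE uses the absolute deviation as
printed in its defining formula; elements with `x_exp = 0` (possible for
clipped log counts) are excluded from MPE with a warning and an exclusion
count in the output, rather than poisoning the mean with infinities. The
default `n = 0` makes `χ²` the mean squared error scaled by `N/(N−0)`;
callers comparing nested models can pass their constant count.

## Yoon connection-weight sensitivity

The signed relative importance of input `i` for output `k` is

$$RI(i,k) = 100\,\frac{\sum_j W_1[j,i]\,W_2[k,j]}
{\sum_{i'} \big|\sum_j W_1[j,i']\,W_2[k,j]\big|},$$

summing the products of input→hidden and hidden→output weights over the
hidden layer, excluding biases and activations, and normalizing each
output column by its total absolute score. The cited source for the
method does not print the formula; this variant is adopted because it is
the standard connection-weight form and reproduces all eight published
extreme importances from the shipped weight fixture to well within 0.1
percentage points (the fixture's two-decimal rounding budget). The
measure is scale-invariant (positive rescaling of either weight matrix),
hidden-permutation-invariant, and sign-equivariant in each input's
weights; all three are enforced by property tests, and the implementation
is checked against an explicit double-loop oracle at 10⁻¹² tolerance.

Whether the original importances were computed on normalized-input
weights is unknowable but irrelevant here: only the printed weights are
available, and they reproduce the quoted values as-is. Garson-style
absolute-value variants and perturbation methods are out of scope.

## Pipeline and reproducibility

`run_pipeline()` chains simulate (or load) → classify → train → evaluate →
sensitivity and writes plain CSV artifacts plus a run log; a single seed
drives the generator, the split and the initialization, so two runs with
the same configuration are byte-identical. Report tables are written at
full precision; round for presentation, not for storage. In
published-weights mode the pipeline skips data and training entirely and
emits the sensitivity analysis of the reference network.

Problem sizes used throughout the tests and the acceptance script — 216
samples per dataset, 200 replicate datasets for calibration checks, 20
seeded runs for the sign-recovery property, 1,000 random vectors for the
formula oracles — were chosen as the smallest sizes at which the checked
quantities are stable to well within their tolerances.

## Known limitations

* The published weight fixture cannot make physical-unit predictions (its
  normalization ranges were never published); it serves the sensitivity
  analysis and structural tests only.
* Synthetic defaults are Gaussian-with-clipping; heavy-tailed or
  zero-inflated alternatives beyond the *S. aureus* clip mass are not
  modelled.
* The overall r² of networks trained on default synthetic data is capped
  near 0.45 by the *S. aureus* marginal constraint; per-analyte r² is the
  more informative number.
* Yoon importances from a single trained network are seed-sensitive on
  noisy data (the sign-recovery property holds in ~90 % of seeded runs,
  not all); averaging importances over several training seeds is sensible
  practice and is left to the user.
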