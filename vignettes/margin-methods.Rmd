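---
title: "Internal margins from intra-fractional motion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Internal margins from intra-fractional motion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motionmargins)
```

## The problem

During a radiotherapy fraction the prostate moves — slow baseline drift from
bladder filling and rectal changes, fast jitter, and occasional abrupt
shifts when rectal gas passes.  Delivery techniques with long beam-on times
(step-and-shoot IMRT, around eight minutes) expose the target to more of
this motion than fast rotational delivery (VMAT, one to three minutes).  The
*internal margin* (IM) is the expansion of the target volume that absorbs
this intra-fractional motion.  This package turns time-sampled displacement
traces (SI/AP/LR components, millimetres, typically 4 Hz, zeroed at the
start of monitoring) into variance components and margins, by two routes
whose disagreement is itself the point of interest.

## The nested model

All estimation in the package refers to one model per axis.  With patients
$p$, fractions $f$ nested in patients, and samples $t$:

$$y_{pft} = m + a_p + b_{pf} + e_{pft}, \qquad
  a_p \sim N(0, \Sigma_{pt}^2),\;
  b_{pf} \sim N(0, \sigma_{fr}^2),\;
  e_{pft} \sim N(0, \sigma_{intra}^2),$$

all mutually independent.  $\Sigma_{pt}$ is the inter-patient SD (how far
whole patients sit from the population mean $m$), $\sigma_{fr}$ the
inter-fraction SD (day-to-day shifts of one patient), and $\sigma_{intra}$
the intra-fraction SD (motion around the fraction's own level).  Fraction
labels are only meaningful within a patient.

Two estimators are provided.

**Moment ("classic") definitions.**  The systematic error $\Sigma$ is the
sample SD over patients of the per-patient mean displacement; the random
error is the root mean square over fractions of the within-fraction sample
SDs.  `moment_components()` reports both, plus the pooled within-patient SD
of fraction means as `sigma_fr_mm` so the moment components can also be
pushed through the finite-$N$ corrections.  Because each patient mean is
estimated from $N$ fractions, $E[\Sigma^2] \approx \Sigma_{pt}^2 +
\sigma_{fr}^2/N$: the classic recipe systematically overestimates the true
inter-patient component.  This inflation is exactly what the REML route
removes, and the package asserts it as a Monte-Carlo trend in its test
suite.

**REML.**  `reml_fit()` maximizes the restricted likelihood of the nested
model.  The implementation is the package's own: an orthonormal rotation
within each fraction separates $(n-1)$ residual contrasts from the scaled
fraction mean, so the criterion is computed from per-fraction sufficient
statistics (count, mean, within-fraction sum of squares) with
Sherman–Morrison inversion of each patient's fraction-mean covariance.
Cost per evaluation is linear in the number of fractions and independent of
the 4 Hz sample count behind the sufficient statistics.  The criterion
includes the $\log|X'V^{-1}X|$ term and the generalized-least-squares
quadratic form, so at the GLS mean it equals the REML log-likelihood of
standard mixed-model software (the test suite checks agreement with
`lme4::lmer` to 1e-6 on the log-likelihood, and with a dense-covariance
brute-force evaluation to 1e-8 on small cohorts).

### Numerical choices

* Optimization is derivative-free: Nelder–Mead on log variances with five
  fixed starts derived from the moment estimates, simplex restarts, and a
  quasi-Newton polish; convergence tolerance 1e-10 on the objective.  The
  log-variance parameterization is robust near the $\Sigma_{pt} = 0$
  boundary; after convergence the $\Sigma_{pt} = 0$ and $\sigma_{fr} = 0$
  boundaries are refitted explicitly and an exact zero is reported when the
  boundary is at least as good.  The fit is deterministic given the data.
* Confidence intervals are profile-likelihood intervals at the
  $\chi^2_1$ cutoff, truncated below at 0 for SDs; the overall mean is
  profiled the same way with all three variances re-optimized at each fixed
  mean.  Wald intervals are deliberately not offered: they misbehave at the
  boundary, where the profile interval correctly returns a lower limit
  of 0.  Root-finding uses bracket expansion plus `uniroot` to about 1e-4 mm.
* Observation unit: every 4 Hz sample, treated as exchangeable within its
  fraction.  This matches the extremely tight intra-fraction CIs that
  full-rate fitting produces (hundreds of thousands of residual degrees of
  freedom).  A `thin` stride is provided to probe sensitivity to the
  exchangeability assumption under autocorrelation.
* Reported tables round to 2 decimals (mm); everything internal is full
  precision.

## Effective errors and the margin

For a course of $N$ fractions, part of the inter-fraction variance does not
average out and acts systematically:

$$\Sigma_{eff}^2 = \Sigma_{pt}^2 + \sigma_{fr}^2/N, \qquad
  \sigma_{eff}^2 = (1 - 1/N)\,\sigma_{fr}^2 + \sigma_{intra}^2,$$

and the margin is the population recipe $IM = 2.5\,\Sigma_{eff} +
0.7\,\sigma_{eff}$, whose coefficients guarantee a 95% minimum dose to the
clinical target volume for 90% of patients; they are taken as given, not
re-derived, and are configurable in `margin()`.

`effective_errors()` applies the corrections; with `method = "raw"` it
instead passes the classic columns through unchanged ($\Sigma_{eff} =
\Sigma$, $\sigma_{eff} =$ RMS of within-fraction SDs), which is the
convention of classic margin tables whose $\Sigma$ already absorbs the
finite-$N$ share.  `margin_table()` defaults to raw for the moment
estimator and effective for REML (`pathway = "auto"`).

For cohorts with unequal fraction counts the default $N$ is the largest
per-patient count (`n_policy = "max"`); recomputing published margin tables
from their printed components reproduces the printed effective errors and
margins at that choice, to within the ±0.02 mm that two-decimal input
rounding permits.  A harmonic-mean policy and an explicit `n_fractions`
override are available.

## The synthetic cohort generator

No public trace archive exists for this kind of monitoring data, so
`simulate_cohort()` is a first-class module: the generative twin of the
nested model, with defaults chosen to mimic a realistic prostate cohort
(five patients, 37 fractions, 490 s fractions at 4 Hz, components of a few
tenths of a millimetre — the scale reported for ultrasound-monitored
prostate courses).

Design choices worth stating explicitly:

* **Zero reference.**  Clinically, displacement is measured from the
  prostate position at the monitoring start, so every trace starts at
  exactly zero.  Subtracting a literal $t=0$ draw of the model process from
  the whole trace would cancel $a_p$ and $b_{pf}$ outright and destroy the
  hierarchy the generator exists to provide.  The generator therefore
  treats the first sample as the definition of the coordinate origin: it
  is exactly zero, and samples at $t > 0$ carry the patient and fraction
  offsets, drift and noise.  The one hard-zero sample per fraction slightly
  perturbs recovered components (order $1/n$ with $n$ near 1000 samples);
  recovery tests use tolerances accordingly.
* **Intra-fraction process.**  First-order autoregressive noise scaled to
  stationary SD $\sigma_{intra}$, with correlation time
  `ar_corr_time_s` (default 0 = white noise, matching the estimator's
  exchangeability assumption; positive values let tests probe violations of
  it).
* **Drift.**  Each fraction draws a linear baseline slope from
  $N(0, \text{rate}^2)$ in mm/min per axis; default off.  Published
  monitoring studies report drifts up to about 2 mm over 16 min, so 0.1–0.2
  mm/min is a realistic scale when enabled.
* **Gas events.**  A Poisson number of transient excursions per fraction,
  each a smooth unipolar half-sine pulse on the AP axis with half-normal
  peak amplitude — the simplest shape reproducing the sudden
  several-millimetre anterior spikes seen on ultrasound when rectal gas
  moves.  `inject_gas_event()` exposes the pulse deterministically for
  bookkeeping tests.
* **Unbalanced designs** are first-class: `fractions_per_patient` is
  per-patient, mirroring real cohorts where patients contribute 20–37
  monitored fractions.

What the generator does **not** emulate: heavy-tailed displacement
distributions (real traces show rare excursions far outside a Gaussian
envelope — visible in classic margin tables whose raw random errors exceed
the nested model's components), missing samples and tracking dropouts,
rotation of the target (the monitoring modality does not report it), and
nonstationary variance within a fraction beyond linear drift plus pulses.
Passing recovery tests therefore demonstrate correctness of the estimators
under the stated model, not robustness to every pathology of clinical data.

## Descriptive summaries

`summarize_fractions()` / `summarize_patients()` implement the common
clinical report: the per-fraction maximum absolute displacement from the
start position per axis, summarized as mean ± SD (sample SD, $n-1$; defined
as 0 for a single fraction) over each patient's fractions.
`mean_abs_curve()` bins $|$displacement$|$ by time from monitoring start
(default 1 s bins — the underlying binning of published summary curves is
not stated, and results are insensitive to bins of a few seconds);
fractions contribute only to bins they reach, so late bins reflect the
longer deliveries.  `compare_techniques()` runs a two-sided Wilcoxon
rank-sum test per axis on per-fraction maxima pooled by technique.  The
unit of comparison (fractions, not patients or raw samples) is a package
choice: fraction-level maxima are the quantity clinical motion reports
tabulate immediately before quoting the test.  The test enumerates the
exact permutation distribution (midranks under ties) for combined $n \le
20$ and otherwise uses the tie-corrected normal approximation.

## Degenerate inputs and edge behaviour

* A zero-variance cohort is legal for the generator, I/O and the moment
  route, and produces margins of exactly 0; the REML criterion requires a
  positive residual variance and rejects such data.
* `moment_components()` needs ≥ 2 patients ($\Sigma$ undefined otherwise);
  `reml_fit()` additionally needs a patient with ≥ 2 fractions and
  within-fraction replication.
* All-identical groups in the rank-sum test return $p = 1$ with a warning.
* Ties in the per-fraction maximum take the first occurrence for the
  signed value at the maximum.

## Problem sizes used by the test suite

Unit tests run on cohorts of 2–8 patients and seconds-long traces; the
oracle comparisons use cohorts of ≤ 30 samples (dense brute force) and
balanced 8 × 6 designs (closed-form nested ANOVA).  The parameter-recovery
study uses 200 cohorts of 14 patients with 20–37 fractions of 240 s at
4 Hz — about 375 000 samples per cohort — with truth set to a
published-components-like vector ($\Sigma_{pt} = 0.10$, $\sigma_{fr} =
0.80$, $\sigma_{intra} = 0.69$ mm, mean $-0.10$ mm).  These sizes keep the
whole suite within a few minutes on one CPU while leaving Monte-Carlo error
well below the tolerances asserted.

## Known limitations

* At realistic cohort sizes (say 14 patients) a small inter-patient
  component sits close to its boundary relative to its sampling noise:
  REML estimates of $\Sigma_{pt}$ then pile up at 0, giving a downward
  bias on the SD scale of order 10–20% of a 0.1 mm truth, and the
  truncated profile intervals become conservative (observed coverage near
  1).  This is a property of the estimation problem, not of the
  implementation — the same behaviour appears with any REML fitter — and it
  is the honest price of avoiding the moment estimator's upward inflation.
  The interval/bias behaviour is quantified in the acceptance suite.
* The REML route assumes exchangeable residuals within a fraction.  With
  autocorrelated intra-fraction noise the point estimates remain sensible
  but the intra-fraction CIs are anti-conservative; use `thin` to check.
* Margins here are *internal* margins only: setup error, delineation
  uncertainty and inter-fraction positioning are outside the model, and no
  dose-coverage simulation behind the (2.5, 0.7) coefficients is performed.
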