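---
title: "Growth-rate inhibition and combination synergy in preclinical efficacy studies"
author: "tumorgri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-rate inhibition and combination synergy in preclinical efficacy studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorgri)
library(dplyr)
```

## The analysis problem

A caliper-based in vivo efficacy study follows cohorts of tumor-bearing
mice (typically a syngeneic allograft in an immunocompetent host, ~10
animals per arm) from randomization — conventionally near a 30 mm³ mean
tumor volume, "Day 0" — through thrice-weekly tumor and body-weight
measurements until a humane endpoint or the scheduled end of study. Tumor
volume is computed from perpendicular caliper diameters as
$V = 0.5 \, L W^2$ (mm³).

The quantities of scientific interest are all functions of the *growth
rate*, not the raw volumes:

* **Per-animal growth rate.** Each animal's series is fit to a simple
  exponential growth model $V(t) = V_0 e^{rt}$, i.e. ordinary least
  squares of $\log V$ on study day. The arm summary is the arithmetic
  mean rate $\mu_g$, with a standard error from the between-animal spread.
* **Growth-rate inhibition (GRI).**
  $\mathrm{GRI}\,(\%) = 100 \times (\mu_\text{control} -
  \mu_\text{treatment}) / \mu_\text{vehicle}$.
  Positive GRI means treated tumors grew more slowly; GRI = 100% is
  complete stasis on the rate scale. Significance is assessed with a
  two-sided Welch test on the per-animal rates, the natural test when the
  comparison object is the two arm means with unequal variances.
* **Combination synergy score.** For a four-arm design (control, A, B,
  AB),
  $$S = \frac{\mu_{AB} - \mu_A - \mu_B + \mu_\text{control}}{\mu_V}
  \times 100\%.$$
  Under additivity of rate effects ($\mu_{AB} - \mu_\text{control} =
  (\mu_A - \mu_\text{control}) + (\mu_B - \mu_\text{control})$) the score
  is exactly 0. The standard error propagates the four group SEs as a
  root sum of squares scaled by $100 / |\mu_V|$, the degrees of freedom
  come from the Welch–Satterthwaite equation over the four groups,
  $$\nu = \frac{\left(\sum_i s_i^2\right)^2}{\sum_i s_i^4 / (n_i - 1)},$$
  and $t = S / \mathrm{SE}(S)$ is referred two-tailed to $t_\nu$. A
  significant negative score is *synergistic*; a non-significant score is
  *additive*; a significant positive score is *sub-additive* if the
  combination still beats the best single agent (lower mean rate) and
  *antagonistic* otherwise.
* **Surrogate survival.** First crossing of a 1200 mm³ endpoint volume
  stands in for mortality; arms are compared by Kaplan–Meier curves and a
  two-sided unweighted log-rank test.
* **Tolerability and response.** Maximal mean percent body-weight loss
  versus pre-dose Day-0 weights, and complete responders (recorded volume
  0 mm³, sustained through the end of observation).

## Modeling choices and their rationale

**Log-linear OLS, not nonlinear least squares.** "Simple exponential
growth" is fit on the log scale, where the estimator is closed-form,
exactly testable, and correctly specified when measurement noise is
multiplicative — the empirically dominant error mode for calipers.
Nonlinear fitting on the volume scale would weight the largest (least
reliable) volumes most heavily. Gompertz/logistic growth and mixed-effects
models are deliberately out of scope: the method is per-animal OLS plus
arm means.

**The volume floor.** The log of a recorded 0 (no palpable tumor) is
undefined, yet complete responders must contribute strongly negative,
finite rates. Volumes are floored at a configurable `floor` (default
1 mm³) before the log transform, and every fit that touched the floor is
flagged (`floored`), so the floor's influence is auditable. The floor is
in the measurement's own units and sits well below the caliper detection
limit, so it only engages for regressing tumors.

**Day windows.** A "GRI on Day d" uses all measurements from
randomization through day d (`window = c(0, d)`): a single per-animal
exponential model makes cumulative-from-Day-0 the only coherent choice.
The window is a parameter, never hard-coded.

**Between-animal error only.** Arm SEs use the spread of per-animal
fitted rates. The per-animal OLS slope SE is reported but not propagated:
the fitted-rate spread already contains the within-animal fitting noise,
and adding the slope SEs would double-count it.

**Vehicle as a fixed normalizer.** The synergy SE propagates the four
group SEs only; the vehicle mean in the denominator is treated as fixed,
matching a Welch–Satterthwaite df that spans exactly four groups. A
first-order delta-method variant (`se_method = "delta"`), which adds the
vehicle's sampling error and its covariance with the numerator when
vehicle = control, is available for sensitivity analysis; with a vehicle
arm of n = 10 growing at a well-measured rate the two differ little.

**Welch everywhere.** Both the GRI test and the synergy test allow
unequal variances across arms — effective treatments routinely compress
or inflate rate spread — so pooling is never assumed.

**Surrogate events on the measurement grid.** The event time is the first
*scheduled* day at or above threshold, with no interpolation: measurements
happen three times a week and endpoint days are reported on that grid. An
animal that crosses and later regresses keeps its event at first crossing.
Animals euthanized for non-tumor humane reasons are censored at removal.

## The synthetic-cohort generator

`simulate_cohort()` emulates the study design end to end so every stage is
testable with known ground truth and no external data:

* starting volumes lognormal around `baseline_mtv = 30` mm³ with CV
  `baseline_cv = 0.3` — enrollment near 30 mm³ with realistic spread;
* per-animal true rates Normal(arm mean, `rate_sd`); the default
  `rate_sd = 0.03`/day gives an arm-mean SE of ~0.01/day at n = 10,
  in line with well-run syngeneic studies; vehicle arms near 0.30/day
  reach the 1200 mm³ endpoint inside two weeks from 30 mm³, matching the
  kinetics such models show;
* multiplicative lognormal measurement noise (`noise_sd = 0.1` on the log
  scale, ~10% caliper error), so the log-linear fitting model is
  correctly specified by default; an additive-Gaussian option exists as a
  deliberate misspecification scenario for robustness studies;
* a thrice-weekly schedule (0, 2, 4, 7, 9, 11, …) to `study_end_day = 74`,
  the span of a long combination study;
* a complete-response process: with probability `p_cr` an animal's rate
  switches to a negative `cr_rate` at `cr_onset_day` — a rate switch, not
  instantaneous clearance, so regressing series exercise the flooring
  logic realistically; volumes below `detection_floor = 5` mm³ record as
  0 (no palpable tumor);
* humane-endpoint removal at `humane_removal_volume = 2000` mm³ keyed on
  the *latent* (noise-free) volume, so dropout is reproducible and
  independent of the noise draw on the removal day; the animal is measured
  on the removal day and contributes no further rows — informative
  dropout, as in a real study;
* body weights constant at 20 g unless an arm configures a `bwl_rate`.

`simulate_additive_null()` pins the AB arm's true mean rate at
$r_A + r_B - r_\text{control}$ before sampling, so the true synergy score
is exactly 0 — the null instrument for type-I-error studies.

What the generator does *not* emulate: tumor-size-dependent growth
deceleration, immune-mediated delayed response kinetics, measurement-day
jitter, cage effects, or any pharmacology. Passing tests therefore
demonstrate the statistical machinery is correct under the stated
generative model, not that the exponential model is adequate for any given
real study — that judgment stays with the analyst.

## Numerical and degenerate-input behavior

* Noiseless data recover generating rates to machine precision; the OLS
  slope SE is reported as 0 when residuals vanish (n = 2, or exact
  exponential data).
* A zero vehicle mean rate makes GRI and the synergy score undefined and
  raises a degenerate-normalizer error rather than returning an infinity.
* `gri_test()` on zero-variance rate vectors returns the limiting test
  (t = 0, p = 1 for equal means; p = 0 otherwise) so noiseless pipelines
  run end to end; the synergy test errors instead when all four group SEs
  are 0, because its df is then undefined.
* Ties between events and censorings at the same day are handled
  events-first (the product-limit convention).
* Swapped caliper length/width warns and computes as given — silent
  swapping would hide data-entry errors.
* Animals with fewer than two usable points are excluded from fits with a
  named warning; arm n's reflect exclusions.

## Operating characteristics

The test suite verifies, among other properties:

* exact recovery of rates, GRI, and a zero synergy score on noiseless
  additive-null cohorts;
* calibration of the synergy t-test: under the additive null with
  n = 10/arm and lognormal noise 0.1, the rejection fraction at
  $\alpha = 0.05$ over 2000 seeded replicates lies in [0.03, 0.07] — an
  operating-characteristic check with binomial tolerance, not an exact
  calibration claim;
* unbiased GRI recovery (within 3 Monte-Carlo SEs of 50% when the
  treatment rate is half the control rate, 600 replicates);
* agreement of the Kaplan–Meier and log-rank implementations with
  brute-force product-limit and per-event-time hypergeometric oracles on
  50 randomized small studies.

Replicate counts (2000 for test size, 600 for GRI recovery, 50 for the
survival oracles) were chosen to give Monte-Carlo standard errors well
inside the tolerances being checked.

## Known limitations

* The exponential model is a deliberate simplification; large tumors
  decelerate and the fitted rate then under-states early growth.
* Informative dropout at the humane endpoint biases late-window arm means
  toward slower growers; no imputation beyond the observed series is
  attempted, and the bias is documented rather than corrected.
* The GRI significance test compares rates only; it does not model
  per-animal measurement schedules or serial correlation.
* Greenwood confidence bands and Cox regression are intentionally absent;
  the survival module covers the product-limit estimate and the
  unweighted log-rank comparison only.
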