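---
title: "Clearance-corrected SUVR: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clearance-corrected SUVR: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Reference-tissue PET quantification rests on the simplified reference
tissue model (SRTM): the target concentration obeys

$$C_T(t) = R_1 C_{ref}(t) + \left(k_2 - R_1 k_{2a}\right)
  C_{ref}(t) \otimes e^{-k_{2a} t}, \qquad
  k_{2a} = \frac{k_2}{1 + BP_{ND}},$$

with delivery ratio $R_1$, target efflux rate $k_2$ (min$^{-1}$) and
binding potential $BP_{ND}$; the distribution volume ratio is
$DVR = BP_{ND} + 1$. A windowed uptake ratio
$SUVR = \overline{C_T}/\overline{C_{ref}}$ overestimates $DVR$ at late
windows because the tracer is still clearing. If both curves decay
mono-exponentially within the window, with rates $\beta_{tar}$ and
$\beta_{ref}$, substituting quasi-stationary decay into the SRTM
differential equation gives the corrected estimate implemented by
`correctSuvr()`:

$$SUVR_c = \frac{SUVR}
  {1 - \beta_{ref}/k_{2,ref} + \beta_{tar}\,SUVR/(k_{2,ref} R_1)}.$$

The derivation assumes (i) quasi-stationary mono-exponential decay of
both curves inside the window, (ii) the target efflux rate is
approximated by $R_1 k_{2,ref}$ with a literature value of
$k_{2,ref}$, and (iii) $R_1 \approx 1$. Each assumption fails gracefully:
at equilibrium ($\beta = 0$) the correction is the identity, and
`r1SensitivityExperiment()` quantifies the error when the true delivery
ratio departs from the assumed one.

Directly fitting $\beta_{tar}$ in a small region from five late frames is
noise-dominated, so `estimateBetaTar()` uses the empirical regression

$$\beta_{tar} = \beta_{composite} +
  a\left(\frac{1}{SUVR_{tar}} - \frac{1}{SUVR_{composite}}\right),$$

anchored to a large high-binding composite region (volume-weighted
caudate + putamen). The radiotracer constant $a$ is tracer- and
window-specific; `estimateRadiotracerConstant()` reproduces the
leave-one-out ordinary-least-squares procedure used to fix it from
training subjects whose reference $\beta_{tar}$ values come from
low-noise SRTM fits to full dynamic data.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `k2Ref` | 0.10 | min$^{-1}$ | median SRTM reference efflux across regions for fast DAT tracers |
| `r1Assumed` | 1 | – | a-priori delivery ratio of the correction |
| `a` | 0.0024 | min$^{-1}$ | empirical clearance-regression constant for this tracer/window |
| SUVR window | 50–80 | min | late window whose bias the correction removes |
| early window | 15–45 | min | low-bias comparator measure |
| composite volumes | caudate 4, putamen 6 | mL | volume weighting of the composite; subject-specific volumes are configurable |
| `fineDt` | 1 | s | convolution grid; frame values are time-averages, matching scanner output |
| k2a search grid | 0.006–0.6, 128 log-spaced points | min$^{-1}$ | deterministic basis-function SRTM fit |

A frame belongs to a window when its midpoint falls in the half-open
interval $[t_0, t_1)$ — unambiguous and schedule-independent. All times
are minutes internally; TAC files may be authored in seconds and are
converted at I/O. Activity is assumed decay-corrected throughout, as
reconstructed PET frames are.

## Numerical choices

* **SRTM fitting** is the basis-function method: for each candidate
  $k_{2a}$ the two linear coefficients are solved by
  frame-duration-weighted least squares, the best grid point is polished
  by bounded 1-D minimisation, and model predictions are frame-averaged
  so that data and model live on the same support. The grid search is
  restricted to admissible solutions ($R_1 > 0$, $k_2 > 0$); noisy
  low-binding curves can otherwise pull the optimum into a
  non-physiological corner. Solutions at the grid boundary are flagged.
  The weighting (frame durations) and the basis-function choice are
  implementation decisions — nonlinear fitting with other weights is
  equally defensible; the basis method is deterministic and standard.
* **Convolution** uses an exponential-trapezoid recurrence on a 1-s grid
  (a first-order linear recurrence evaluated in C), exact for the
  exponential kernel and second-order in the input.
* **Clearance fits** minimise the duration-weighted residuals of a
  *frame-averaged* mono-exponential, so noiseless frame-averaged
  exponentials are recovered to machine-level accuracy rather than with
  the systematic error a midpoint fit would leave. Rates may be negative
  (still-rising curves) and are never clamped.
* **SUVR** is the ratio of duration-weighted window means (the ratio of
  plain frame means is an alternative the literature leaves open).
* A non-positive SUVRc denominator raises an error carrying the
  offending values; clamping would hide exactly the sensitivity the
  correction is known to have.
* Sample ($n-1$) standard deviations are used for CV, Cohen's d pooling
  and Bland–Altman; Lin's concordance uses population moments
  consistently so identity input scores exactly 1. The ROC confidence
  interval is DeLong's. The Bonferroni family defaults to 3 (the three
  pairwise measure contrasts), giving the familiar 0.0167 threshold.

## What the synthetic cohorts emulate

`cohortSpec()` defines the study conditions: 38 + 38 cross-sectional
subjects, 9 test-retest pairs, 21 longitudinal pairs with a
2.3 ± 0.5-year interval, a 37-frame 93-min acquisition, striatal DVR
reduced in the patient group, and a true annual striatal DVR decline
near 4–5 %/year. No regional DVR tables exist for this tracer to copy,
so the distribution parameters are calibration choices, fixed once:

* **Plasma input and reference kinetics.** A Feng-type tri-exponential
  input (terminal clearance 0.024 min$^{-1}$) drives a one-tissue
  reference region with $K_1 = 0.35$, $k_2' = 0.10$ min$^{-1}$. These
  were tuned once so that the quantification path yields reference
  clearance faster than composite clearance and group-mean target
  clearance rates near 0.010 min$^{-1}$ (controls) and 0.013–0.015
  min$^{-1}$ (patients) in the 50–80-min window — the bands the
  acceptance tests check.
* **Regional efflux is tied to binding.** All regions of a subject share
  a near-common apparent clearance rate $k_{2a}$ (the composite's SRTM
  value, with 5% log-normal jitter), i.e. $k_2 = k_{2a} \cdot DVR$. Full
  SRTM coupling ($k_2 = R_1 k_2'$ in every region) would make low-binding
  regions clear several-fold faster than the striatum, implying an
  effective radiotracer constant an order of magnitude above 0.0024
  min$^{-1}$; observed clearance spreads for this tracer class are
  narrow, and the compressed spread keeps the regression estimator
  meaningful in-world.
* **Noise** is zero-mean Gaussian per frame with SD
  $scale\sqrt{A/\Delta t}$, a count-statistics proxy, seeded and
  reproducible. The scale (1.2) was calibrated so striatal DVR
  test-retest variability is ≈3%. Because frame noise is the *only*
  source of test-retest variability in DVR (the between-scan
  perturbation below cannot move an SRTM-exact DVR), this single knob
  must carry variability that real studies spread over several sources;
  a side effect is that the composite clearance rate is noisier per scan
  than clinical region-level estimates, which inflates the mean of the
  convex SUVRc transform by a few percent on noisy cohorts. The
  acceptance suite documents this honestly: the bias *ordering* tests
  pass, while the strict sub-5% mean-bias band is missed at this noise
  level.
* **Test-retest perturbation.** Visits share identical kinetic truth;
  the retest applies 3% multiplicative jitter to reference $K_1$ and to
  the plasma terminal clearance. A pure $K_1$ jitter cancels in every
  ratio-based measure, so the shape jitter is what creates
  clearance-level day-to-day variation.
* **Longitudinal decline** multiplies baseline DVR by
  $(1-r)^{\Delta t}$ with a per-region drawn annual rate $r$, truncated
  at DVR = 1 (and flagged); the apparent clearance is re-anchored to the
  follow-up composite DVR, so clearance rises at follow-up through the
  kinetics, not by fiat.
* **Seeding.** One master seed; each (subject, visit) derives its seed
  by a fixed affine scheme modulo $2^{31}-1$, so any record is
  regenerable in isolation and whole cohorts are byte-identical across
  runs.

What the generator does **not** emulate: scanner resolution and
partial-volume effects, motion, attenuation artefacts, co-registration
and ROI-placement variability between visits, age/sex structure, or any
deviation of real tissue kinetics from SRTM. Passing tests therefore
demonstrate the correctness and internal consistency of the estimators
under SRTM-generated data with count-like noise — not performance on
clinical images.

## Known limitations

* The correction systematically under-corrects low-binding regions
  (substantia nigra most visibly): their true efflux is far from the
  assumed $R_1 k_{2,ref}$ and their disequilibrium is not fully captured
  by the one-parameter clearance regression. The per-region acceptance
  check is the attainable ordering — corrected bias smaller than
  uncorrected bias in every region — not a uniform bias band.
* SUVRc is convex in the clearance rates, so noisy clearance estimates
  inflate its mean; with the noise calibrated to a 3% DVR test-retest
  variability, corrected-SUVR variability is roughly double that of DVR
  (the ordering the test-retest arm checks).
* The regression estimator is linear in inverse SUVR; quadratic or
  Bayesian extensions, voxel-wise maps, and non-SRTM input models are
  out of scope.

## Problem sizes

The test suite simulates the full default conditions once (76 + 18 + 42
scans, each 37 frames at 1-s convolution resolution) and reuses them
across acceptance blocks; Monte-Carlo checks use 100–10,000 replicates
of cheap operations. `scripts/acceptance.R` re-runs the same pipeline
from scratch in well under five minutes on one CPU.
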