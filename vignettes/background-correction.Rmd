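---
title: "Stationary-tissue background correction for PC-CMR flow quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stationary-tissue background correction for PC-CMR flow quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcflow)
```

## The measurement problem

Phase-contrast CMR encodes through-plane blood velocity in the image
phase: a phase of $\pi$ radians corresponds to the velocity-encoding limit
(VENC), so $v = \phi \cdot \mathrm{VENC}/\pi$. Residual eddy currents from
gradient switching add a spatially smooth, temporally stable spurious
phase, i.e. a spurious velocity surface $b(x,y)$, to every frame. For a
vessel ROI of area $A$ and a cardiac cycle of duration $T_{RR}$, a constant
offset $b$ changes the measured net volume by exactly

$$\Delta V \;=\; b \cdot A \cdot T_{RR},$$

and for a general surface by $T_{RR} \cdot a_{px} \sum_{(x,y) \in ROI}
b(x,y)$ with $a_{px}$ the pixel area — the *bias law*, which holds exactly
for rectangle-rule integration and which the test suite asserts to float
precision. A 0.5 cm/s offset over a 6 cm² aortic ROI for a 1 s cycle is a
3 ml error on a ~90 ml stroke volume; because Qp/Qs divides two such
measurements with independent offsets, the ratio accumulates error from
both acquisitions and healthy subjects spill outside the 0.9–1.2 normal
range.

## The model and its assumptions

Stationary tissue (chest wall, muscle) has essentially zero mean velocity,
so whatever mean velocity it shows *is* the background. `pcflow` fits

$$p(x,y) = a_{00} + a_{10}x + a_{01}y \;[+\; a_{20}x^2 + a_{02}y^2 + a_{11}xy]$$

by unweighted ordinary least squares to the time-averaged velocity of
static pixels, and subtracts $p$ from every frame. Assumptions, and where
they come from:

* **The offset is a low-order polynomial in space and constant in time.**
  Order 1 ("linear", a tilted flat surface) and order 2 ("quadratic") are
  the two corrections in clinical use; both are supported and compared.
* **Time-average first, then fit one surface per series.** Per-frame fits
  averaged afterwards would be an alternative; the time-average
  formulation is the one clinical implementations describe, and averaging
  first reduces the noise the fit sees by $\sqrt{n_{frames}}$.
* **Unweighted least squares.** Magnitude weighting was considered and
  rejected: the mask's magnitude gate already removes low-SNR pixels, and
  weighting would change the estimator away from what clinical tools
  describe.
* **Fit on velocity, not phase.** The two differ by the constant
  VENC$/\pi$; velocity keeps a single unit (cm/s) through the whole
  pipeline.
* **Normalized centered coordinates** $x, y \in [-1,1]$ condition the
  design matrix and make coefficients comparable across pixel spacings
  (not across aspect ratios; documented on the fit object).

Rank-deficient designs (e.g. all static pixels on one image row) raise an
explicit error rather than silently pseudo-inverting.

## Static-tissue detection

The clinical procedure is "maximize static tissue by raising the phase
deviation threshold, then exclude non-static structures with ROIs".
`detect_static()` implements the three gates:

| knob | meaning | default | why |
|---|---|---|---|
| `sd_threshold` | max temporal SD of pixel velocity, cm/s | 2 | at tissue SNR ~30 and VENC 150 the noise-floor SD is ~1.6 cm/s; 2 keeps ~97% of true static pixels |
| `mag_threshold` | min time-averaged magnitude, fraction of image median | 0.3 | scanner units are arbitrary; the median is a robust tissue reference |
| exclusion / vessel ROIs | polygons or masks removed outright | — | lungs (noise) and vessels (flow) must never anchor the fit |

"Phase deviation" is interpreted as the temporal standard deviation of the
pixel's velocity: the vendor screenshots show a monotone include-more knob,
and temporal SD is the standard static-tissue criterion; whether vendors
threshold SD, range, or a residual is not public, so only this
interpretation is implemented. The mask is monotone in both thresholds and
invariant to constant velocity shifts — both properties are tested.
Vessel ROIs are excluded even when the user supplies no exclusion ROI.

## What the simulator emulates — and what it does not

`make_phantom()` builds a chest-slice phantom: two circular vessels
(ascending aorta, main pulmonary artery) with pulsatile parabolic flow,
surrounded by static tissue, lateral low-magnitude lung fields, an additive
polynomial background, and Gaussian phase noise with per-pixel SD
$\mathrm{VENC}/(\pi \cdot \mathrm{SNR} \cdot m_{rel})$ — the standard
phase-noise behaviour in which low-magnitude (lung) pixels carry wildly
noisy velocities, which is exactly why the exclusion-ROI step exists.

Choices the field's literature does not pin down, fixed once here:

* **Waveform**: half-sinusoid systolic ejection over the first 40% of the
  cycle plus a 5% constant diastolic component. Any smooth pulsatile shape
  serves; the peak is scaled so the *discrete* pixel sum equals the target
  stroke volume exactly.
* **Vessel membership** is pixel-center-in-circle with no partial-volume
  weighting, and the flow ROI is the identical pixel set — discretization
  cancels, ground truth is exact, and flow recovery on a noise-free
  phantom is a float-precision test. This deliberately isolates
  background-correction error from segmentation error.
* **Geometry/protocol defaults** follow a typical 1.5 T protocol: VENC
  150 cm/s (within the clinical 100–200 range), ~240 mm field of view,
  5 mm-scale pixels, 30 frames, 1000 ms R-R; single-phantom work uses a
  96×96 grid, cohort simulation a 64×64 grid at 3 mm with 20 frames —
  coarse enough for fast repeated whole-cohort runs, fine enough that the
  aortic ROI spans ~80 pixels.

Not emulated: k-space/coil physics, respiratory motion, partial-volume
edges, aliasing wrap (aliasing *rejects* with an error instead),
beat-to-beat waveform variation (only an R-R series for the eligibility
filter), and moving anatomy — the ROI is fixed across frames, which is
exact for these rigid phantoms and a documented simplification for real
data. Passing tests therefore demonstrate correctness of the *correction
arithmetic*, not robustness to segmentation or motion error in clinical
images.

## Cohort simulation and its calibration

`make_cohort()` emulates a clinical study population: each subject's true
Qp/Qs is drawn from $N(1.0, 0.04)$ truncated to $(0.5, 2.0)$ (a shunt-free
referral population), the aortic stroke volume from $N(90, 15)$ ml
truncated to $[50, 120]$, and each of the subject's two acquisitions
(aortic and pulmonary) receives an independent order-2 background whose
coefficients are i.i.d. $N(0, \sigma_b^2)$.

$\sigma_b$ is the one free knob with no published value: the magnitude of
real eddy-current offsets is site- and sequence-specific. It is calibrated
once, by Monte-Carlo over 60 seeds using the exact bias law, so that the
*uncorrected* out-of-range fraction is ≈18% at $n = 91$ — the out-of-range
burden a consecutive clinical cohort shows before correction. The
calibrated default is $\sigma_b = 0.7$ cm/s, giving a mean fraction of
0.180 (Monte-Carlo SD across seeds 0.043). The demonstration the
acceptance tests make is directional and scaled — correction strictly
lowers the out-of-range fraction in ≥95% of seeds, quadratic at least
matches linear in most seeds — not a reproduction of any clinical
percentage, which desk-scale synthetic data cannot provide.

## Numerical and statistical choices

* **Flow integration**: rectangle rule with uniform $\Delta t = T_{RR}/n$
  (retrospective gating); no trapezoidal end-correction. Forward/backward
  volumes split per-frame net flow by sign, so net = forward − backward
  holds exactly.
* **Normal-range bounds inclusive**: 0.9 and 1.2 classify as normal; the
  clinical phrasing "0.9 to 1.2" carries no boundary language, and
  inclusive bounds make the three labels a partition.
* **Eligibility**: excluded only when the R-R SD *exceeds* 10% of the mean
  (strict inequality) for any acquisition.
* **Exact McNemar**: $p = \min(1,\, 2 P(X \le \min(b,c)))$,
  $X \sim \mathrm{Bin}(b+c, \tfrac12)$, rather than the chi-square
  approximation — well defined at the small discordant counts
  reclassification tables produce. At counts like $b=9, c=2$ the exact
  two-sided p is ≈0.065; printed clinical p-values for such tables are
  sometimes far smaller, which this package makes no attempt to reproduce.
* **"Non-parametric Levene"** is implemented as Brown-Forsythe (median
  centering) on the rank-transformed pooled data, making it invariant to
  monotone transforms; the name in clinical-statistics usage is ambiguous
  and this is the deterministic reading.
* **ICC** is fixed to the two-way, absolute-agreement, single-measures
  form ICC(2,1), the form appropriate for "same subjects, two readings"
  agreement; negative values are returned unclamped.
* **KS normality gate** uses the sample's own mean/SD (as clinical
  packages do), which is conservative — prone to labelling data normal;
  the gate's role is routing (t/F vs rank tests), and both routes are
  calibrated under the null in the acceptance tests (rejection ≤6% at
  nominal 5% over 1000 replicates).
* **Median dichotomization** sends ties to the low group,
  deterministically; groups under 3 subjects are skipped with a warning.

## Problem sizes used by the test suite

Unit tests run on 32×32, 10-frame phantoms where exactness, not
resolution, is at stake (the bias law and flow recovery are exact at any
grid). Parameter-recovery checks use the full 96×96, 30-frame geometry at
tissue SNR 20 over 20 seeds (background coefficients recovered at the
few-hundredths-of-a-cm/s level — the theoretical coefficient standard
errors there reach 0.024 cm/s for the x² term, since the lateral lung
exclusion removes the highest-leverage pixels — and corrected
stroke-volume error under 1%). The cohort
demonstration runs 50 seeds of a 91-subject cohort on the 64×64 cohort
geometry. These sizes are the package's chosen study conditions; they keep
a full run in the minutes range on a single core.

## Known limitations

* Static-tissue correction cannot distinguish a true global velocity
  offset from one that merely *looks* constant over the thorax; a
  third-order or phantom-based (gel) correction is out of scope.
* No phase unwrapping: aliased data are rejected, not repaired.
* DICOM ingestion is a thin optional path; the documented directory
  container produced by `write_series()`/`write_phantom()` is the format
  the pipeline and tests exercise.
* The simulator's noise is Gaussian on velocity; real phase noise is
  Rician-derived and spatially correlated by reconstruction filters, so
  absolute SNR numbers do not transfer to scanners — only the relative
  behaviour (lung ≫ tissue noise) does.
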