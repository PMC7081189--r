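# pcflow

Stationary-tissue background phase correction and Qp/Qs shunt
quantification for phase-contrast cardiovascular magnetic resonance
(PC-CMR).

## The problem

Velocity-encoded PC-CMR measures through-plane blood velocity in the image
phase and is the standard way to quantify the pulmonary-to-systemic flow
ratio **Qp/Qs** used to detect and grade intra-cardiac shunts (normal range
0.9–1.2; above 1.2 suggests a left-to-right shunt, below 0.9 right-to-left).
Eddy currents from gradient switching superimpose a spatially smooth,
spurious velocity offset `b(x, y)` on every frame. Even a few mm/s of offset,
integrated over a vessel cross-section and a cardiac cycle, biases net
stroke volumes and pushes healthy patients outside the Qp/Qs normal range.

`pcflow` implements the stationary-tissue remedy end to end, for anyone who
wants a tested, scriptable reference for this correction (physicists,
clinical-software evaluators, methods students):

1. **Static-tissue detection** — chest-wall and muscle pixels have near-zero
   true velocity; [`detect_static()`] keeps pixels whose temporal velocity
   SD is below a phase-deviation threshold and whose magnitude passes a
   gate, minus exclusion/vessel ROIs (lungs, great vessels).
2. **Background surface fit** — the core model. With `v̄(x, y)` the
   time-averaged velocity and `S` the static-pixel set, `fit_background()`
   solves the ordinary least-squares problem

   ```
   min_a Σ_{(x,y) ∈ S} [ v̄(x,y) − p_a(x,y) ]²,
   p_a(x,y) = a00 + a10·x + a01·y            (order 1)
            + a20·x² + a02·y² + a11·xy       (order 2)
   ```

   in normalized image coordinates `x, y ∈ [−1, 1]`, and
   `apply_correction()` subtracts the fitted surface from every frame.
3. **Flow quantification** — `flow_curve()` integrates velocity over a
   vessel ROI (rectangle rule, uniform frame duration R-R/n); `qpqs()`
   forms the ratio and classifies it.
4. **Cohort statistics** — exact McNemar on paired classifications,
   F/rank-Levene spread tests behind a Kolmogorov-Smirnov normality gate,
   ICC(2,1) for observer agreement, median-dichotomized covariate screens
   with Bonferroni correction (`0.05/20 = 0.0025`).
5. **Synthetic ground truth** — `make_phantom()`/`make_cohort()` simulate
   cine acquisitions with known background coefficients, exact discrete
   stroke volumes and label maps, so every stage above is testable without
   clinical data.

## Worked example

```r
library(pcflow)

# a phantom with a known quadratic eddy-current background
ph <- make_phantom(phantom_params(background_order = 2,
                                  background_coeffs = c(1, 0.5, -0.25, 0.3, -0.2, 0.1),
                                  snr_tissue = 20, seed = 5))
msk <- detect_static(ph$series, sd_threshold = 4, mag_threshold = 0.3,
                     exclusion_rois = list(ph$truth$lung_mask),
                     vessel_rois = ph$truth$vessel_masks)
fit <- fit_background(ph$series, msk, order = 2)
round(coef(fit), 4)
#>     a00     a10     a01     a20     a02     a11
#>  1.0051  0.5003 -0.2519  0.3159 -0.2206  0.1239

flow_curve(ph$series, ph$truth$vessel_masks$aorta)$net_volume - 90
#> [1] 6.08103      # uncorrected stroke-volume bias, ml
corr <- apply_correction(ph$series, fit)
flow_curve(corr, ph$truth$vessel_masks$aorta)$net_volume - 90
#> [1] -0.4575881   # residual error after correction, ml
```

The fitted coefficients recover the injected background to a few
hundredths of a cm/s, and the 6 ml (~7%) stroke-volume bias collapses to
under 0.5 ml. At cohort scale:

```r
ev <- run_pipeline(list(n_subjects = 91, seed = 1))
ev$summaries$linear
#> Reclassification over 91 subjects
#>   pathological: 15% before -> 4% after correction
#>   2x2 counts: a=74 b=13 c=3 d=1 (b,c discordant)
#>   normalized among initially pathological: 93%
#>   exact McNemar p = 0.02127
```

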