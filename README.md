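# trunkgait

Gait-quality analysis from a single lumbar accelerometer, for the
neurorehabilitation setting: does a stroke patient's immune status
(stroke-induced immunosuppression, SII, operationalized as a
neutrophil-to-lymphocyte ratio NLR ≥ 5) go along with a more asymmetric,
less stable gait than in immunocompetent (IC) patients and healthy
subjects (HS)?

The package implements the full computation chain on tri-axial trunk
acceleration (anterior–posterior AP, medio-lateral ML, vertical V,
100 Hz):

* **Gait events** — detrend + 3.2 Hz FIR low-pass of the vertical axis,
  numerical integration, Gaussian-wavelet differentiation (gaus1,
  scale 9); initial contacts at the extrema between zero-crossings;
  final contacts from the push-off transient envelope; stride
  segmentation with the first/last two strides trimmed and a 20-stride
  minimum.
* **Harmonic ratio (HR)** — per stride, 20 stride-locked harmonic
  amplitudes A₁…A₂₀ by DFT; HR_AP,V = ΣA_even / ΣA_odd (first ten each),
  HR_ML = ΣA_odd / ΣA_even; averaged over the walk. Higher = more
  symmetric.
* **Short-term largest Lyapunov exponent (sLLE)** — 20 strides
  time-normalized to 100 points each; delay from the first AMI minimum
  (lags 7–18), dimension from false nearest neighbours (max 10);
  Rosenstein's algorithm, slope of the mean log divergence over 0–0.5
  stride, per stride. Higher = locally less stable.
* **Log-dimensionless jerk (LDLJ)** —
  −ln[ (t₂−t₁)/a²_peak ∫ (da/dt)² dt ] after a 20 Hz zero-phase
  Butterworth. Closer to zero = smoother.
* **Symmetry index (SI)** — (V_p − V_np) / (0.5 (V_p + V_np)) × 100 for
  stance, swing, double- and single-support durations.
* **Statistics** — Kruskal–Wallis + η², Dunn/Holm post hocs, Pearson χ²
  (no continuity correction), Mann–Whitney, and a nonparametric
  time × group repeated-measures analysis (ANOVA-type statistics, Box
  approximation).
* **Synthetic cohorts** — a generator with analytic ground-truth HR/SI
  and ordinal stability dials, with presets calibrated to the three
  study groups (42 HS / 32 IC / 14 SII).

## Worked example

```r
library(trunkgait)

# one synthetic hemiparetic walk with known ground truth
spec <- synthetic_spec(hr_v = 1.5, hr_ml = 1.3, delta = 0.02,
                       stance_left = 0.66, stance_right = 0.60,
                       sigma_n = 0.1, sigma_t = 0.02, sigma_a = 0.06,
                       paretic_side = "left", seed = 42)
g  <- generate_trace(spec)
ev <- gait_events(g$trace)
ev
#> gait_events: 53 ICs, 51 FCs, 26 strides detected, 22 retained (left lead)

walk_hr(g$trace, ev)
#> harmonic ratios over 22 strides: V 1.53 (0.10)  ML 1.30 (0.05)  AP 1.80 (0.08)

walk_slle(g$trace, ev, axes = "ml")
#> sLLE_ML = 0.623 /stride (tau 18, m 5)
```

The harmonic ratios land on the programmed targets (1.5 / 1.3; the
deviation is the programmed noise), and the medio-lateral exponent sits
between the healthy and impaired group scales, as set by the wobble
dials.

A full cohort with the study's group sizes, through events, indexes and
the statistical report:

```r
rp <- run_pipeline(n_hs = 42, n_ic = 32, n_sii = 14, seed = 1,
                   slle_axes = c("v", "ml"))
subset(rp$report$baseline, index %in% c("hr_ml", "slle_ml"),
       c(index, mean_hs, mean_ic, mean_sii, H, p, eta_sq))
#>   index mean_hs mean_ic mean_sii    H        p eta_sq
#>   hr_ml   1.812    1.39    1.292 24.9 3.84e-06  0.270
#> slle_ml   0.514    0.69    0.813 29.4 4.06e-07  0.323
```

Healthy subjects show the highest medio-lateral harmonic ratio and the
lowest divergence exponent; the immunosuppressed group sits at the
impaired end of both, with the group effect overwhelmingly significant —
the cross-sectional pattern the index set is designed to expose.

There is also a small CLI (`inst/cli/trunkgait`) with `simulate`,
`events`, `indexes` and `run` subcommands writing plain CSV/JSON.

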