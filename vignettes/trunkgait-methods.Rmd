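---
title: "Trunk acceleration-derived gait indexes: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trunk acceleration-derived gait indexes: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`trunkgait` computes the standard trunk acceleration-derived gait indexes
from a single lumbar (L5) inertial sensor sampled at 100 Hz: gait events,
temporal parameters and gait speed; harmonic ratios (HR, symmetry); the
short-term largest Lyapunov exponent (sLLE, local dynamic stability); the
log-dimensionless jerk of accelerations (LDLJ, smoothness); and temporal
symmetry indexes (SI). A rank-based statistical layer compares three
cohorts — healthy subjects (HS), immunocompetent stroke patients (IC,
neutrophil-to-lymphocyte ratio NLR < 5) and patients with stroke-induced
immunosuppression (SII, NLR ≥ 5) — cross-sectionally and over an
admission/discharge pair of timepoints. A synthetic-cohort generator with
analytic ground truth exercises the whole chain.

## Event detection

The vertical axis is detrended and low-pass filtered with a linear-phase
FIR filter (windowed sinc, Hamming window, order 128, cutoff 3.2 Hz),
applied with group-delay compensation. The filtered signal is numerically
integrated and differentiated with a Gaussian first-derivative wavelet
(gaus1, scale 9 samples), which amounts to Gaussian smoothing with a sign
flip. Initial contacts (IC) are the dominant extrema of this signal
between successive zero-crossings, one per step; shallow lobes are
rejected against the median lobe depth, near-duplicates merged, events
within half a mean step of the trace edges discarded, and extrema refined
to sub-sample precision by parabolic interpolation. The wording of the
underlying method family leaves the sign convention open: heel strikes
are detection-signal *minima* under the default polarity, and a config
flag (`ic_polarity`) flips it.

Final contacts (FC) are not observable with comparable sharpness in the
heavily smoothed detection signal; vendor software estimated them with an
unpublished method. Our replacement heuristic assumes that push-off emits
a brief high-frequency transient: the raw vertical axis is band-passed
around `fc_harmonic` (default 24) times the stride frequency estimated
from the ICs, the smoothed RMS envelope is taken (Gaussian window, SD
15 ms — wide enough to cancel the envelope ripple at twice the carrier
frequency), and one FC is placed at the envelope peak in the first 55% of
each inter-IC interval (double support occupies roughly 10–35% of a
step). Intervals without a clear peak (below 1.5× the interval median)
contribute no FC, and the affected stride is dropped. Both detectors are
config-replaceable; temporal-parameter agreement with any vendor chain is
approximate by construction.

Side labels alternate; polarity comes from the sign of the medio-lateral
acceleration just after each contact (positive ML = left, by convention).
If fewer than 80% of steps fit a strict alternation the walk is flagged
side-ambiguous and labels fall back to alternation from the first step.

Strides span successive same-foot ICs. The first and last two strides are
trimmed; at least 20 must remain or the walk errors out. Gait speed is
corridor distance over the first-to-last IC interval: single-sensor
spatial models are proprietary, so the corridor length is trusted
instead.

## Harmonic ratios

Per retained stride, the first 20 stride-frequency harmonic amplitudes
are computed by DFT on the exact stride window (no zero-padding, no
taper, so harmonics sit on bins). For the anterior–posterior and vertical
axes HR = (sum of the first ten even harmonics)/(sum of the first ten odd
harmonics); the convention inverts for the medio-lateral axis, whose
fundamental period is the stride. Per-stride HRs are averaged
(unweighted) over the walk. Degenerate spectra are handled with a 1e−12
denominator floor and a 1e6 cap. Two documented deviations from the
protocol text: the stated 20 Hz *high-pass* noise filter would delete
every gait harmonic (stride ≈ 1 Hz), so a 20 Hz low-pass is applied, with
the direction exposed as `hr_filter_direction`; and "first ten even +
first ten odd" is used where an equation legend suggests 20 + 20,
matching the stated total of twenty harmonics.

## Short-term Lyapunov exponent

The first 20 retained strides of the *raw* axis (filtering would remove
exactly the fluctuations of interest) are each linearly resampled to 100
points and concatenated (2000 samples). The embedding delay τ is the
first local minimum of the average mutual information over lags 7–18
(equiprobable binning, ⌈√(N/5)⌉ bins; the AMI curve is lightly smoothed,
a 10%-of-range prominence is required — otherwise estimator wiggles
masquerade as minima — and a flat curve, range < 0.1 bits as for iid
noise, is treated as minimum-free; with no qualifying minimum in range
the argmin is used).
The dimension m is chosen by false nearest neighbours (R_tol = 15,
A_tol = 2, < 1% criterion, max 10). Rosenstein's algorithm then tracks
each point's nearest neighbour outside a Theiler window of 100 samples
(one normalized stride) and fits the mean log divergence over offsets
0–50 samples (0–0.5 stride) by least squares; the exponent is reported
per normalized stride (slope × 100). Exact all-pairs neighbour search is
used (compiled, but verified against a plain-R brute-force oracle to
1e−9). An exactly periodic series has all neighbour distances zero; the
exponent is then 0 by convention, with a warning.

Units are a convention, not physics: the per-stride slope over the
short-term window reproduces the dimensionless 0.5–0.9 scale reported in
the gait literature. Comparisons of absolute values against published
tables are therefore calibration-level, not formula-level.

A note on commensurate sampling: a sine whose period divides the sample
grid exactly produces duplicate delay vectors, making the FNN distance
ratio 0/0; tests use incommensurate periods. Real (noisy) data never hits
this case.

## Smoothness and symmetry

LDLJ of a segment [t₁, t₂] is
−ln[ (t₂−t₁)/a²_peak · ∫(da/dt)² dt ], computed over the retained-stride
span after a zero-phase low-pass Butterworth (order 4, 20 Hz); derivative
by central differences, integral by trapezoid. The printed source formula
shows a *second* time-derivative inside the integral, but the stated
peak-of-acceleration normalization is dimensionless only with the first
derivative (the jerk of the acceleration profile), which also matches the
closed-form worked examples; we implement the first derivative. The
measure is exactly amplitude-scale invariant.

SI = (V_paretic − V_non-paretic)/(0.5 (V_paretic + V_non-paretic)) × 100,
applied to the per-side means (not per-stride SIs averaged) of stance,
swing, double-support and single-support durations. Per-side double
support is the loading-response interval (own IC to contralateral FC);
single support of one side is the contralateral swing. Subjects without a
paretic side (HS) get NA with a warning.

## Statistics

Baseline three-group comparisons use the tie-corrected Kruskal–Wallis H
with η² = (H − k + 1)/(n − k) as effect size, and Dunn's pairwise z from
pooled mid-ranks (large-sample normal, tie-corrected) with Holm's
step-down over the three pairs. Two-group clinical contrasts use Pearson
χ² *without* continuity correction (this choice reproduces the reference
contingency-table p-values; Yates' correction does not) and the
Mann–Whitney test (exact enumeration when both n ≤ 8 without ties,
tie-corrected normal approximation otherwise).

The longitudinal analysis is a nonparametric two-way design — time
(within, 2 levels) × group (between) — via pooled mid-ranks, relative
treatment effects, and ANOVA-type statistics with the Box approximation
for the numerator degrees of freedom; within-subject effects are referred
to F(f, ∞) and the between-subject effect to F(f, f₀) with a
Satterthwaite-style denominator. The type-I error of the interaction test
is verified by simulation (1000 null replicates) in the test suite.
Post-hoc analyses downstream of the longitudinal model are gated on a
significant interaction, as the protocol prescribes. Covariates cannot
enter this rank procedure natively; an optional pre-ranking
residualization switch exists, off by default, and is an interpretation
caveat rather than a covariate-adjusted model.

## The synthetic world

Each walk is built from parts whose stride-harmonic coefficients are
known in closed form, so the true HR is analytic even though the waveform
is rich:

* broad Gaussian "step bumps" (SD 0.09 stride) at the true step times —
  the even-dominant trunk oscillation, following the step-timing
  asymmetry δ;
* a sharp positive Gaussian pulse per initial contact (SD 0.05 stride)
  and a small negative pulse per final contact;
* a high-frequency push-off burst at each FC (Gaussian envelope, SD 0.012
  stride, carrier at the 24th stride harmonic) — above the 20 counted
  harmonics and the 20 Hz filters, but included in the analytic spectrum
  because its envelope is spectrally wide;
* an odd-harmonic asymmetry background whose scale is solved (1-D root
  finding) so the total spectrum hits the subject's target HR exactly.
  Harmonics 1 and 3 stay in cosine phase (zero slope at the steps, so
  detected event times stay unbiased); harmonics 5 and 7 get random
  phases. On the V/AP axes the odd content sits mainly in harmonics 5–7 —
  the sharp left/right differences of pathological gait — which the HR
  counts in full but the 3.2 Hz event filter removes, keeping
  low-symmetry walks detectable. The ML odd content stays at the
  fundamental (lateral sway alternates with the stepping foot), which
  side assignment relies on.

Divergence (sLLE) has no analytic truth; it is driven ordinally by three
dials: a within-stride Brownian "motor wobble" that resets at each heel
strike (SD σ_n at stride end; this, not white noise, is what makes nearby
trajectories genuinely separate), stride-time variability σ_t (which
perturbs the phase structure around the event pulses), and per-stride
amplitude jitter σ_a. A fixed white sensor-noise floor (σ_w = 0.04 m/s²)
sets the neighbour-distance baseline. The vertical/AP wobble is scaled to
0.45× the medio-lateral wobble: lateral balance is actively controlled
and carries most of the instability.

Group presets draw per-subject HR targets, gait speeds, NLR values
(SII ≥ 5 with probability 1), paretic sides, stance fractions, δ, and
demographics from the published cohort means/SDs; the three noise dials
were calibrated **once** so that the pipeline's group-median exponents
land on the reported scale (ML ≈ 0.51/0.75/0.87 for HS/IC/SII), and are
not revisited. The calibrated stride-time CVs (1.0–2.2%) sit below
typical physiological values — a deliberate trade: σ_t also controls the
vertical-axis divergence floor in this signal family. Stroke type is
assigned by deterministic counts matching the published cohort
composition (1/32 and 2/14 hemorrhagic) rather than sampled, so the
cohort-level shares are reproduced exactly. Discharge (T1) walks shift
the per-subject targets by the published group-level improvements and
relax the noise dials by 12%.

What a green synthetic test does **not** establish: that the detectors
work on real accelerometry (no soft-tissue artifact, turning, pauses or
sensor misalignment are simulated); that absolute sLLE values are
comparable beyond the calibration; or that vendor temporal parameters
would be reproduced (FC detection here exploits a transient the generator
itself states).

## Numerical choices and degenerate inputs

Zero-phase filtering is implemented in the frequency domain with the
squared Butterworth magnitude (equivalent to forward–backward filtering
up to edge transients, which reflection padding suppresses). Stride
windows for spectra stay on the integer sample grid (exact-period DFT
windows); sub-sample event times serve the temporal parameters. Constant
series, flat ML, all-zero traces, too-short signals, missing columns,
non-uniform sampling, < 20 strides, zero-distance neighbour pairs and
empty groups all raise typed errors or documented warnings rather than
propagating garbage. The double-support symmetry index is the least
precise output (shortest phase, two event estimates); noise-free
validation bounds it near ±1% while stance SI holds ±0.5%.

## Known limitations

* FC detection presumes a push-off transient; on recordings without one
  the yield drops and strides are discarded (by design, loudly).
* The AMI delay frequently falls back to the range argmin on
  quasi-periodic signals whose first true minimum lies beyond 18 samples;
  this is the documented fallback, recorded per axis in run metadata.
* The longitudinal covariate switch residualizes before ranking; it is
  not a joint model.
* Synthetic SDs of some indexes are narrower than the published cohort
  SDs; between-subject spread was calibrated to group means and
  orderings, not to second moments.
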