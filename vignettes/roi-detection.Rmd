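---
title: "Detecting repetitive focal activations in atrial electrograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting repetitive focal activations in atrial electrograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focalroi)
```

## The detection problem

A focal driver in fibrillating atrial tissue is a site that repeatedly
fires and spreads activation radially outward. On a unipolar electrogram
this has two signatures: the deflection at the source is entirely negative
(QS morphology — all wavefront movement is away from the electrode), and
the source's local activation time (LAT) precedes that of every neighboring
electrode. `focalroi` implements the automated detector built on these
signatures: a site is a *region of interest* (ROI) when it shows (1) QS
morphology, (2) activation earlier than all its neighbors, and (3) at least
two consecutive repetitions of such focal activations.

The package contains the full pipeline — catheter geometry, signal
conditioning, LAT annotation with quality gating, the ROI criteria, driver
metrics, and diagnostic-accuracy statistics — plus a kinematic simulator
that generates ground-truth recordings, so every stage is testable without
clinical data.

## Signal conditioning

Unipolar signals are band-pass filtered at 2–240 Hz with a 60 Hz mains
notch (`filter_spec()`). Only the corner frequencies are fixed by
convention; the realization here is a fourth-order Butterworth band-pass
plus a second-order notch (quality 30), each applied forward–backward.
Zero-phase filtering matters: a causal filter would delay every deflection
and bias the LATs by a channel-independent but morphology-dependent amount.
The notch is configurable to 50 Hz for other mains regions. No far-field
ventricular (QRS) subtraction is attempted.

## LAT annotation and morphology

The clinical system annotates with a proprietary wavelet method; `focalroi`
uses the standard unipolar convention as a documented surrogate, isolated
behind `detect_activations()` so an alternative annotator can be swapped in:

* **LAT** = local maxima of the negative slope $-dV/dt$, computed with a
  derivative-of-Gaussian kernel (scale 3 ms). Candidates are accepted
  greedily from steepest downward with a 60 ms blanking period.
* **Adaptive threshold.** The slope threshold is
  `max(min_slope, noise_k * sigma_d)`, where `sigma_d` is the channel's own
  slope-noise level, estimated from the 20th percentile of chunk-wise
  (64 ms) variances. The low quantile makes the estimate insensitive to
  signal occupancy: chunks containing activation waves inflate only the
  upper quantiles. This keeps detection invariant to amplitude rescaling
  and stable between sparse tachycardia and dense fibrillation.
* **Morphology.** In a ±20 ms window around the LAT, the R amplitude is the
  largest positive deflection *before* the LAT measured relative to the
  local baseline at the window start, and the S amplitude the largest
  negative deflection. Both are read off a lightly smoothed trace and
  debiased by the channel noise floor, because the maximum of ~20 noisy
  samples otherwise masquerades as an R wave. The event is **QS** when the
  R fraction $r/(r+s) \le 0.10$ *and* the S deflection stands clear of the
  noise floor (five times the noise level): a noise-scale negative blip
  carries no morphology information. The baseline correction matters in
  fibrillation, where the 2 Hz high-pass's slow recovery lobes from
  neighboring waves would otherwise be read as initial positivity.

**Channel quality gate** (`quality_gate()`): a channel is ignored — no
timings downstream — unless it has at least 15 beats per 30 s, a
signal-to-noise ratio of at least 3 (median per-event peak-to-peak over the
chunked noise level), at least 0.05 mV peak-to-peak, and a dominant
frequency between 3 and 12 Hz. The parameter *kinds* follow clinical
practice; the numeric defaults are this package's documented assumptions.
The dominant frequency is the spectral peak of the rectified,
moving-average-smoothed trace, searched above 2 Hz so that slow amplitude
modulation (e.g. the on/off run structure of an intermittent driver, ~0.5 Hz)
is never mistaken for an activation rate.

## The ROI criteria

For each activation of electrode $e$ at time $t$, each quality-passed
neighbor's earliest activation in $(t - 30\,\mathrm{ms},\, t +
60\,\mathrm{ms}]$ is bound (`associate_cycle()`). The backward part of the
window is essential: a neighbor that fired slightly *before* the candidate
must be seen (with negative offset), otherwise a non-leading site could
appear to lead. The candidate is

* **ineligible** when fewer than 3 neighbors are bound (poor local coverage
  must not manufacture false sources),
* **focal** when it is QS and strictly earlier than every bound neighbor
  (ties are not leading; the lead tolerance is 0 ms).

Runs of consecutive focal activations are counted per electrode; a run is
broken by any non-focal activation or by an inter-firing gap exceeding 1.5
times the electrode's median cycle length (the gap rule is this package's
choice; "consecutive" is otherwise undefined for intermittent firing). An
electrode with at least one run of ≥ 2 repetitions becomes an ROI site
(`detect_roi()`). Sites within 10 mm merge, keeping the electrode with the
most occurrences — 10 mm mirrors the 1 cm center-to-center rule used for
site correlation, which is strict (`correlate_sites()`: exactly 10 mm does
*not* correlate). ROI are reported at electrode resolution.

`radial_spread_test()` verifies the driver-definition wavefront signature
separately: all first-ring neighbors activate after the source and the mean
second-ring delay exceeds the mean first-ring delay.

Sequential maps are pooled by greedy centroid clustering with the same
10 mm radius (`aggregate_sequential()`).

## Driver metrics and accuracy statistics

`driver_metrics()` computes, per driver site: consistency (fraction of maps
with a correlating ROI, excluding maps whose coverage missed the site),
temporal stability (mean counted run length), and recurrence rate (counted
occurrences per 30 s). `cycle_length()` averages the first 30
inter-activation intervals. `ablation_response()` labels termination, cycle
length slowing (≥ 30 ms), or none; `lvz_classify()` applies the strict
< 0.5 mV low-voltage rule.

`evaluate_detection()` builds site-level confusion counts under the strict
10 mm rule. True negatives are not well defined for site-level detection;
this package defines explicit **control sites** (driver-free locations at
least twice the threshold from every reference) and documents the
divergence. Rates carry exact Clopper–Pearson intervals
(`binomial_ci_exact()`, via beta quantiles; Wilson intervals are offered as
an option), and group associations use Fisher's exact test
(`fisher_exact_2x2()`). Percentages print rounded half-up to integers.

## The simulator

`simulate_recording()` is deliberately kinematic (eikonal-style), not
reaction–diffusion: the detector consumes timing and morphology structure,
and that structure can be produced exactly and cheaply.

* **Geometry.** Sources live on a spherical stand-in for the left atrium
  (radius 28.8 mm, chosen so the circular cross-section is 26 cm², a
  typical planimetered left-atrial area). The 64-electrode basket
  (8 splines × 8, configurable) sits on the sphere; the 20-electrode
  five-spline array has the standard 2-6-2 mm spacing.
* **Propagation.** Focal firing reaches an electrode `geodesic / cv` after
  onset (conduction velocity 1 mm/ms by default, bounds 0.2–2); planar
  wavefronts by projection on the propagation direction; reentry by
  rotation phase around a circuit (radius ~5 mm for micro-, ~20 mm for
  macro-reentry) plus radial delay outside the core.
* **Morphology model.** Electrodes within 5 mm (geodesic) of a firing
  origin receive a monophasic negative template whose steepest negative
  slope falls exactly at the activation time; remote electrodes receive a
  biphasic RS template with R fraction drawn from 0.35–0.55. Amplitude
  falls with distance as $d_0 / (d_0 + d)$, $d_0 = 20$ mm from a 1 mV
  source. QS-within-5-mm is a geometric idealization of the physics that
  makes QS the operational source signature.
* **Fibrillation.** Background activity is a sequence of planar wavelets
  from random directions at a jittered cycle length (145 ± 10 ms,
  matching reported left-atrial appendage cycle lengths), with 2 ms
  per-electrode timing jitter. An intermittent driver interleaves runs of
  focal firings: occurrences per 30 s are Poisson with mean 11 and run
  lengths are 2 + Poisson(1) (mean 3), matching the reported driver
  statistics (≈ 11 occurrences per 30 s, ≈ 3 consecutive repetitions).
* **Noise.** White noise at RMS `amp / snr` (default SNR 10 relative to the
  1 mV source amplitude) plus a 0.2 mV 60 Hz mains tone are injected
  *before* filtering, so the notch is exercised. Identical seeds give
  bit-identical recordings.

**What passing tests show — and what they do not.** The simulator
reproduces the *mechanistic* contrast the detector relies on (focal sources
are QS-and-leading repeatedly; reentry and planar sweeps are not), the
reported driver occurrence statistics, and realistic noise levels. It does
not reproduce real AF's richer spatiotemporal statistics (meandering
wavefronts, wave breaks, fibrosis-conditioned conduction), electrode
contact variability, basket deformation, respiratory/cardiac motion, or
ventricular far field. Detection performance on these simulations therefore
validates the algorithm's logic and calibration, not its clinical operating
characteristics.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| band edges / notch | 2–240 / 60 | Hz | published filter settings; notch configurable to 50 |
| `blanking_ms` | 60 | ms | atrial refractory floor; prevents double-annotation |
| `noise_k` | 5 | – | ~5 sigma slope threshold: no spurious events in 30 s of pure noise while keeping attenuated neighbors detectable |
| `qs_threshold` | 0.10 | – | "QS" read strictly: no significant initial positivity |
| `qs_min_snr` | 5 | – | a QS call must stand clear of the noise floor |
| quality gate | 15 beats/30 s, SNR 3, 0.05 mV, 3–12 Hz | | documented assumptions for the unstated clinical thresholds |
| `min_consecutive` | 2 | – | the published repetition criterion |
| `assoc_window_ms` / `lead_window_ms` | 60 / 30 | ms | shorter than one cycle (≥ 100 ms), longer than the basket's inter-electrode conduction delays (~10–25 ms) |
| `min_valid_neighbors` | 3 | – | poorly covered electrodes are ineligible rather than falsely focal |
| `gap_factor` | 1.5 | × median CL | breaks runs across silent gaps; "consecutive" is otherwise undefined |
| `merge_radius_mm` | 10 | mm | internal consistency with the 1 cm correlation rule |

## Numerical and design choices

* Strict inequalities everywhere a boundary is stated (leading, 10 mm
  correlation, 0.5 mV low voltage); ties break conservatively (a tie is
  not leading — two adjacent electrodes cannot both claim the source).
* Whether the clinical algorithm demands QS on *every* repetition is
  unstated; here every counted repetition must itself pass both criteria
  (the stricter reading).
* Electrode neighborhoods: structural catheter adjacency by default, with
  a metric fallback (`neighbor_graph(mode = "metric")`, 6–10 mm radius
  suggested) for aggregated sequential maps; neither is claimed canonical.
* Degenerate inputs: constant/empty traces annotate to zero events;
  recordings shorter than two cycles detect to an empty site list with a
  warning; the quality gate labels rather than raises.
* Bundle I/O is byte-stable (fixed float format, fixed key order) so
  identical runs produce identical artifacts.
* Acceptance-scale problem sizes: the tachycardia validation analog uses
  15 focal maps (5 sources × 3 seeds) and 35 reentrant maps across circuit
  radii 5–25 mm; driver-profile recovery uses 20 seeds; interval coverage
  uses 2000 draws at p = 0.7, n = 30. These sizes make the whole suite
  reproducible on a single CPU in a few minutes.

## Known limitations

* The annotator is a surrogate for the proprietary wavelet method; only
  the observable behavior (annotate or ignore) is reproduced.
* Rotational (phase-singularity) driver detection is out of scope; the
  detector deliberately rejects reentry rather than characterizing it.
* The spherical atrium ignores real chamber anatomy; basket deformation
  and variable electrode contact are not modeled.
* The specificity denominator relies on explicitly constructed control
  sites, a divergence from clinical reports where true negatives are
  undefined.
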