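# focalroi

Automated detection of repetitive focal activations ("regions of interest",
ROI) in multichannel unipolar atrial electrograms.

## The problem

During persistent atrial fibrillation (AF), intermittent focal drivers —
sites that repeatedly fire and spread activation radially into the
surrounding tissue — are candidate ablation targets, but picking them out of
30-second multichannel recordings by eye is slow and subjective. A site can
be recognized automatically from the unipolar electrograms: at the source,
the unipolar deflection is entirely negative (**QS morphology**, because all
activation moves away from the electrode), and the source activates
**earlier than its neighboring electrodes**. `focalroi` implements that
detector for panoramic basket-catheter recordings and sequential
five-spline (PentaRay-style) recordings, together with everything needed to
exercise it without clinical data.

A site is flagged as an ROI when it shows

1. QS morphology on the unipolar electrogram,
2. local activation earlier than all of its neighboring electrodes, and
3. at least **2 consecutive repetitions** of such focal activations.

Two detected/reference sites are considered the same driver when they lie
strictly within 1 cm of each other (center to center). Detected drivers are
characterized by their **consistency** (fraction of maps showing the site),
**temporal stability** (mean consecutive repetitions per occurrence) and
**recurrence rate** (occurrences per 30-s recording), and detection accuracy
is summarized with sensitivity/specificity/PPV/NPV carrying exact
(Clopper–Pearson) 95% confidence intervals.

## What is in the package

| module | functions |
|---|---|
| geometry | `make_basket_array()`, `make_pentaray_array()`, `neighbor_graph()`, `correlate_sites()`, `atrial_surface()` |
| signal I/O | `unipolar_recording()`, `save_bundle()` / `load_bundle()` (CSV + JSON) |
| preprocessing | `filter_spec()`, `filter_unipolar()` — zero-phase 2–240 Hz band-pass with 60 Hz notch |
| annotation | `detect_activations()`, `classify_morphology()`, `quality_gate()`, `annotate_recording()` |
| ROI detection | `detect_roi()`, `focal_test()`, `radial_spread_test()`, `aggregate_sequential()`, `roi_pipeline()` |
| metrics & statistics | `driver_metrics()`, `cycle_length()`, `ablation_response()`, `lvz_classify()`, `evaluate_detection()`, `binomial_ci_exact()`, `fisher_exact_2x2()` |
| simulation | `simulate_recording()` — focal / reentrant / planar tachycardia and fibrillation with an intermittent focal driver, with ground truth |

Results are tibbles throughout; fitted evaluation objects support
`tidy()` / `glance()` and every result type has an `autoplot()` method.
A thin command-line interface lives at `inst/cli/focalroi.R`
(`simulate`, `detect`, `metrics`, `evaluate`, `reproduce-fixtures`).

## Worked example

Simulate a 30-s focal atrial tachycardia on a 64-electrode basket and run
the full pipeline (filter → annotate → detect):

```r
library(focalroi)

sim <- simulate_recording("focal_at", seed = 42)
sim$recording
#> <unipolar_recording 'focal_at_seed42': 64 ch x 30.0 s @ 1000 Hz, stage n/a>

roi_pipeline(sim$recording)
#> # A tibble: 1 x 9
#>   electrode_id        x     y     z occurrences max_run ...
#> 1 C4           1.74e-15  28.4  5.00           5      49
sim$truth$drivers[[1]]$electrode_id
#> [1] "C4"
```

The detector finds exactly one ROI, at the true source electrode `C4`: the
site fired in 5 counted runs, the longest spanning 49 consecutive cycles.

Site-level evaluation against reference driver positions (here 2 of 3
references detected, no false positives on 2 control sites):

```r
ev <- evaluate_detection(roi, refs, controls)
ev
#> <roi_evaluation: tp 2, fn 1, fp 0, tn 2 (threshold 10 mm)>
#>   sensitivity  67 (9-99)
#>   specificity  100 (16-100)
#>   ppv          100 (16-100)
#>   npv          67 (9-99)
tidy(ev)      # tibble of rates with exact 95% CIs
```

Rates print as integer percentages with their exact 95% confidence
intervals, e.g. `67 (9-99)` means 67%, CI 9–99%.

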