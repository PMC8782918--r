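# platefdc

Single-platelet mechanophenotyping by real-time fluorescence
deformability cytometry (RT-FDC), as an R pipeline.

## The problem

Platelets flowing through a narrow microfluidic constriction deform
hydrodynamically; imaging each cell in bright field and extracting its
contour gives a label-free readout of platelet mechanics at thousands of
cells per sample. The central statistic is the isoperimetric
**deformation**

```
deformation = 1 - 2 * sqrt(pi * A) / P
```

where `A` is the projected area of the cell contour and `P` its
perimeter: 0 for a circle, rising toward 1 for elongated shapes. Paired
with per-event fluorescence maxima (CD61-PE identity gate, CD62P and
PAC-1 activation markers), this supports flow-cytometry-style analysis
of platelet mechanics: per-sample medians, geometric-mean fluorescence
(gMean), percent-positive fractions, and fold changes on agonist
(TRAP-6) stimulation. Platelet mechanics are strongly perturbed by the
ex vivo anticoagulant used at blood draw (ACD-A, Na-Citrate, K2-EDTA,
Li-Heparin, r-Hirudin), which is what the calibrated synthetic presets
in this package emulate — including an MYH9-like macrothrombocytopenia
phenotype (large, stiff platelets) and latrunculin-B-like actin
disruption. A separate module quantifies cytoskeletal organisation in
confocal images by cross-sectional line profiles: the edge-to-edge
distance of the marginal-band tubulin ring and a subcortical F-actin
enrichment index.

The package is aimed at users of deformability cytometry who want a
transparent, scriptable measurement chain — and at method developers who
need ground-truth synthetic populations with realistic donor-level
variability to validate gating and summary statistics against.

## What is implemented

- **Synthetic populations** — `fdc_preset()`, `sample_events()`,
  `simulate_donor_panel()`: log-normal event distributions calibrated to
  published per-anticoagulant condition values, with mean-one donor-level
  jitter and donor-consistent paired stimulation responses; analytic
  (exact ellipse) and rasterised modes.
- **Imaging** — `render_frame()`, `segment_frame()`, `contour_area()`,
  `contour_perimeter()`, `area_ratio()`: anti-aliased frame rendering and
  sub-pixel contour extraction with a curvature-corrected threshold
  level set.
- **Features and gating** — `deformation()`, `apply_gates()` (CD61 hard
  gate 150–33000 AU, area ratio ≤ 1.1, size 0–10 µm²),
  `acquisition_stop()` (5000 events or 10 min).
- **Statistics** — `summarize_sample()`, `percent_positive()`,
  `fold_change()`, `kde_density()`, `condition_panel_table()`.
- **Line profiles** — `render_confocal_platelet()`, `extract_profile()`
  (5 µm × 1 µm averaged line), `tubulin_edge_distance()`,
  `actin_peripheral_index()`.
- **I/O and CLI** — `write_events()` / `read_events()` (CSV/TSV with a
  commented JSON metadata header sufficient to re-run gating
  bit-identically), plus a thin command-line wrapper at
  `inst/cli/platefdc`.

## Worked example

Simulate a paired six-donor ACD-A panel (basal and TRAP-6-stimulated,
5000 events each), gate it, and summarise:

```r
library(platefdc)
library(dplyr)

presets <- list(fdc_preset("ACD-A"), fdc_preset("ACD-A", "TRAP-6"))
panel  <- simulate_donor_panel(presets, n_donors = 6, n_events = 5000,
                               seed = 1)
gated  <- apply_gates(as_event_records(panel))
gated$audit
#>       cd61 area_ratio       size
#>          2          0       1562

summ <- gated$kept |>
  group_by(donor_id, condition_label) |> group_split() |>
  lapply(summarize_sample) |> bind_rows()
condition_panel_table(summ) |>
  filter(metric == "median_deformation", statistic == "condition_mean_sd")
#>   donor_id condition_label metric             statistic          value     sd
#> 1 <NA>     ACD-A:TRAP-6    median_deformation condition_mean_sd 0.0479 0.0164
#> 2 <NA>     ACD-A:none      median_deformation condition_mean_sd 0.126  0.0322
```

The basal condition mean of per-donor median deformation, 0.126 ± 0.032,
is the simulated analogue of the published ACD-A value (0.127 ± 0.033,
mean ± SD over 6 donors). Per-donor fold changes on stimulation follow
the decrease-factor convention (`unstim / stim`):

```r
# mean +/- SD over donors
#> deformation fold change: 2.72 +/- 0.49 (n = 6 donors)
```

Confocal cytoskeleton metrics from a rendered platelet (radius 1.5 µm,
intact tubulin ring, 2x subcortical actin weighting):

```r
cp <- render_confocal_platelet(1.5, "ring", "subcortical")
pr <- extract_profile(cp, center = cp$center)
ed <- tubulin_edge_distance(pr)
#> tubulin edge-to-edge: 2.94 um; actin peripheral index: 1.78
```

The edge-to-edge distance recovers the 3 µm ring diameter to within one
pixel; the peripheral index sits below the nominal 2x weighting because
the 1 µm-wide averaged line mixes intensity across the curved band (see
the methods vignette).

## Layout

```
R/                  implementation
tests/testthat/     unit, property and acceptance tests
scripts/acceptance.R   condition-level recovery report
vignettes/          methods vignette (model, calibration, limitations)
inst/cli/platefdc   command-line wrapper
```
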