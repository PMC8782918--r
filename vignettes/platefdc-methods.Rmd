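---
title: "Models and methods behind platefdc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind platefdc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(platefdc)
```

# The measurement model

Deformability cytometry reduces each imaged platelet to two geometric
quantities, projected area $A$ and contour perimeter $P$, combined into
the isoperimetric deformation

$$ d \;=\; 1 - \frac{2\sqrt{\pi A}}{P}. $$

By the isoperimetric inequality $P \ge 2\sqrt{\pi A}$, so $d \ge 0$ for
exact geometry, with $d = 0$ only for a circle. Every downstream
statistic in this package — medians, fold changes, KDE scatter
densities — is a function of $(d, A)$ and per-event fluorescence maxima.

`deformation()` clamps tiny negative values (possible when vertex
smoothing slightly undershoots the bound on measured contours) to zero
and counts the clamps in an attribute, so silent violations cannot
accumulate.

# The synthetic population model

## Shape model

Simulated platelets are ellipses, parameterised by area and aspect
ratio. Real advected cells are bullet-like rather than elliptical, but
$d$ depends only on $(A, P)$, and ellipses span the relevant deformation
range analytically: the circumference is the complete elliptic integral
of the second kind (`ellipse_geometry()`), and the aspect ratio for a
target deformation is recovered by bisection
(`solve_aspect_for_deformation()`). Internally the generator draws $d$
first and defines the perimeter exactly as $P = 2\sqrt{\pi A}/(1-d)$, so
the deformation identity holds to machine precision on every event; the
aspect ratio consistent with that circumference is attached for the
raster renderer (agreement within $10^{-6}$ relative).

## Event-level distributions

Deformation, area and per-channel fluorescence are log-normal —
strictly positive and right-skewed, the standard working assumption for
cytometry intensities; the source measurements publish only medians and
between-donor spreads, not event-level distributional forms. Medians are
the location anchors; event-level coefficients of variation default to
0.45 (deformation) and 0.35 (area), wide enough to reproduce the visual
spread of single-donor KDE scatter plots. Deformation is truncated to
$[0, 0.6]$ by rejection; at all calibrated medians ($\le 0.127$) the
truncated mass is negligible, so medians are unaffected. Fluorescence
channels optionally take a two-component mixture (`f_pos`,
`gmean_pos`) for partially activated samples; the built-in presets use
single components whose locations carry the activation fold changes.

Timestamps follow a homogeneous Poisson process at `event_rate` (default
12 events/s, so a 5000-event acquisition completes in roughly 7 minutes,
inside the 10-minute stop window).

## Calibration anchors

Non-stimulated medians per anticoagulant (deformation / area in µm²):

| | ACD-A | Na-Citrate | K2-EDTA | Li-Heparin | r-Hirudin |
|---|---|---|---|---|---|
| deformation | 0.127 | 0.111 | 0.037 | 0.071 | 0.100 |
| area | 5.035 | 4.70\* | 4.158 | 4.337 | 4.60\* |

TRAP-6-stimulated medians are derived from the basal ones through the
published fold responses (deformation folds 2.76, 2.58, 1.14, 1.72,
2.27; size folds 1.28, 1.14, 0.98, 1.04, 1.18; CD62P folds 18.19,
21.48, 2.03, 9.82, 15.72; PAC-1 folds 2.86, 3.39, ~1, 2.64, 3.55 —
same column order). Values marked \* (and all basal fluorescence
locations except Li-Heparin PAC-1 at 82.48 AU: CD61 at 1500 AU, CD62P at
10 AU, PAC-1 at 25–45 AU) have no published anchor and are package
choices fixed once at plausible mid-range values; they are documented
here rather than inferred from data. The MYH9-like phenotype uses the
single-patient medians (ACD-A basal 0.068 / 5.77 µm², stimulated
0.036 / 6.585 µm²; K2-EDTA basal 0.0195 / 7.515 µm²) with zero donor
jitter, since they describe one individual, not a population. LatB
treatment multiplies basal deformation by 1.4 — a moderate softening
chosen once; the source reports the direction and significance of the
LatB effect but no condition-level median.

## Donor-level variability

Each simulated donor perturbs the model medians by a multiplicative
log-normal jitter with mean exactly 1, so condition means of donor
medians converge to the anchors. The jitter SD is per metric
(deformation, area, fluorescence), calibrated to the published
between-donor SDs — deformation CVs of 0.22–0.27 versus area CVs near
0.06–0.10; a single shared scalar could not reproduce both. Paired
conditions (basal and stimulated, same anticoagulant) reuse the donor's
jitter, which makes per-donor fold changes meaningful; a second,
independent mean-one jitter on the *fold response itself*
(`response_sd`, calibrated to the published fold-change SDs) restores
the realistic between-donor spread of responses that shared jitter
would otherwise cancel exactly.

Random streams are split hierarchically (panel → donor → sample) by
deterministic seed derivation, so enlarging a panel never perturbs
existing donors, and `sample_events()` leaves the caller's RNG state
untouched.

# The imaging chain

`render_frame()` draws the ground-truth ellipse as anti-aliased
coverage (supersampling factor 8) on a brighter background, with the
channel walls of the 15 µm constriction as dark bands, optional
Gaussian point-spread blur and additive noise. The default pixel size
of 0.34 µm/px is a typical calibration for this class of instrument and
is configurable; it is *not* taken from the source publication, which
does not state one.

`segment_frame()` mirrors a vendor-style detector while remaining fully
specified:

1. background = median of border pixels (falling back to the 0.9 border
   quantile when dark wall bands dominate the border);
2. detection mask at `background - threshold_offset` (default 0.15);
   connected components labelled with EBImage, components touching the
   frame border (walls) or below `min_area_px` discarded;
3. per component, a sub-pixel iso-intensity polygon at the level halfway
   between background and the component's interior median, traced with
   `contourLines()` on a natural-spline 8× upsampled copy of the frame;
4. circular moving-average vertex smoothing (default window 7 on the
   upsampled polygon — a smaller arc than a window of 5 on a raw raster
   trace, chosen because perimeter, and hence deformation, is the
   noise-sensitive quantity);
5. a first-order curvature correction: each vertex moves outward along
   its normal by $\kappa\sigma^2/2$, where $\sigma^2 = 1/12\,\text{px}^2$
   is the pixel-integration variance (plus any known PSF variance).
   A threshold level set under symmetric blur is biased inward by
   exactly this amount at curvature $\kappa$; applying the correction to
   the vertices keeps `contour_area()`/`contour_perimeter()` pure
   polygon operations.

With these defaults, noise-free rendered ellipses across aspect ratios
1–3 and areas 2–8 µm² reproduce analytic deformation within ±0.01 at
0.34 µm/px, and areas within ~2% in the physiological range (4–6.5 µm²).
At 2 µm² — a radius of barely 2.3 px — area retains a few percent of
irreducible pixelation bias; accuracy improves monotonically as pixel
size shrinks.

# Gating and summaries

The default `gate_config()` encodes the acquisition protocol: CD61-PE
hard gate 150–33000 AU, convex-hull area ratio ≤ 1.1, size gate
0–10 µm², stop at 5000 gated events or 600 s. The size limit is
interpreted as projected *area* because condition-level sizes are
reported in µm². Gate flags are appended rather than rows dropped, so
audits and re-gating need no recomputation; audit counts are per gate
(an event can appear under several gates) while conservation is checked
on unique rejected events.

`summarize_sample()` uses midpoint medians and the geometric mean over
strictly positive intensities (non-positive values excluded and
counted). Fold-change direction follows the reporting convention:
mechanics shrink on stimulation, so their fold is the decrease factor
`unstim/stim`; fluorescence rises, so its fold is `stim/unstim` — both
give baseline 1. The percent-positive cutoff is not published; the
default convention is the 99th percentile of the matched vehicle
control per channel (`control_cutoff()`), configurable.

`kde_density()` uses a bivariate Gaussian product kernel with
per-axis Scott bandwidths ($\hat\sigma\,n^{-1/6}$), evaluated at the
events themselves and min–max rescaled for the linear colour scale. At
$n = 10^4$ the mode estimate carries the usual $\sim\!5\%$ smoothing
bias of plug-in bandwidths.

# Confocal line profiles

`extract_profile()` samples a 5 µm × 1 µm averaged line (bilinear
interpolation, steps of half a pixel along and across). Peaks are local
maxima with topographic prominence above 10% of the profile range
(robust on noisy profiles; configurable), refined to sub-sample
positions by parabolic interpolation. `tubulin_edge_distance()` is the
distance between the outermost two peaks; with the default 0.08 µm/px
confocal sampling (Nyquist-scale for a ~0.2 µm PSF), rendered rings are
recovered within one pixel-equivalent. Fewer than two qualifying peaks
flags the ring unresolved rather than emitting a number.

`actin_peripheral_index()` divides the mean intensity of the peripheral
band (outer 25% of the half-width on each side, inside the cell as
defined by the tubulin edges) by the mean of the central 50%. The band
fractions are a package convention — the underlying protocol reports
profiles with significance tests but no scalar metric. Two geometric
effects keep measured indices below their nominal weightings: the 1 µm
perpendicular averaging width mixes intensity across the curved
subcortical band, and blur/pixelation soften the band edges. A
2× edge-weighted disc therefore measures ~1.8 under the default
protocol; the tests validate the pipeline against a quadrature oracle
that integrates the generator's radial profile over the same line
footprint, and the nominal value is approached as width and blur
shrink.

# Problem sizes and determinism

The test suite and the acceptance script use the study's own design
sizes where they matter: 6 donors × 5000 gated events per condition for
parameter recovery, ~1000 events for the single MYH9-like sample,
12 shape/area combinations for raster validation, and $n = 2\times10^4$
for convergence checks. Everything stochastic flows from a single
integer seed through hierarchical derivation; identical seeds give
byte-identical event tables.

# Known limitations

- Ellipse shapes, independent $(d, A)$ draws and channel-aligned
  orientation are idealisations; real advected platelets are
  bullet-shaped, correlated in size and deformation, and imaged with
  structured noise. Passing recovery tests therefore validates the
  *measurement chain*, not the realism of any particular biological
  dataset.
- The anchors marked as package choices above (two basal sizes, most
  basal fluorescence locations, the LatB factor) are conventions, not
  published values.
- The MYH9-like presets describe one patient; they carry no donor-level
  variability and should not be read as a disease population model.
- Hypothesis testing (mixed-effects models, multiple comparisons) is
  deliberately out of scope: `condition_panel_table()` exports tidy
  tables for any statistics environment.
- The event store is CSV/TSV with a JSON metadata header; no HDF5
  backend is provided.
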