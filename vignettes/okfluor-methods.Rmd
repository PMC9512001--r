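---
title: "Measuring ortho-k fluorescein patterns: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring ortho-k fluorescein patterns: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(okfluor)
```

## The measurement problem

Orthokeratology (ortho-k) corrects myopia with reverse-geometry rigid
gas-permeable lenses worn overnight. At fitting, the practitioner instils
sodium fluorescein and judges the "bull's eye" pattern under blue light: a
dark **central bearing** zone where the lens nearly touches the cornea
(tear film thinner than roughly 15–20 µm fluoresces weakly), a bright
**tear reservoir** annulus of clearance under the reverse curve, a dark
**mid-peripheral bearing** (alignment) annulus, and a narrow bright
**edge-lift** annulus at the lens rim. The widths of these zones along the
horizontal meridian — especially a central bearing of about 3.5–4.5 mm —
are the quantities a fitter wants, but they are usually eyeballed, with
poor agreement between practitioners. `okfluor` turns a cropped slit-lamp
photograph into those four widths in millimetres, semiautomatically: edge
candidates are found by signal processing and the eight true zone
boundaries are selected either automatically or by the observer.

## The pipeline

Given a photograph cropped so the lens is approximately centred,
`measure_pattern()` applies, in order:

1. **Proportional resize** to a working width of 1,000 px (bilinear with
   antialiasing). Height follows as `round(h · 1000 / w)`. All positions
   below are 0-based column indices on this resized image.
2. **Green-channel extraction.** Fluorescein emission through a yellow
   barrier filter is carried almost entirely by the green channel; red and
   blue contribute mostly noise and reflections.
3. **Contrast maximisation**: the linear min–max stretch
   `(I − min) / (max − min)`. Any monotone map leaves edge *positions*
   unchanged, so this standardises the scale without biasing the
   measurement; a constant image is rejected as carrying no pattern.
4. **Meridian band**: the central 60 rows
   (`row_start = floor((h − 60)/2)`, half-open range). The pattern is
   close to left–right symmetric for a centred lens, and a band (rather
   than a single row) suppresses noise.
5. **Intensity profile**: the column-wise mean over the band (the mean is
   the best linear noise suppressor under additive Gaussian noise; a
   median option exists for images with specular highlights).
6. **Absolute first derivative** of the profile, after Gaussian
   pre-smoothing (σ = 2 px by default, 0 disables). Element `i` is
   `|p[i+1] − p[i]|`, attributed to column `i` — a uniform half-pixel
   convention that cancels in every diameter difference.
7. **Peak detection**: local maxima with topographic prominence at least
   `0.1 × max(derivative)` and pairwise separation of at least 10 px.
   When two candidates collide, the larger magnitude wins; exact ties go
   to the smaller column.
8. **Peak re-localisation** (`refine_peaks()`): each accepted peak is
   moved to the argmax of the *unsmoothed* derivative within ±3 px.
   Averaging over a 60-px band turns a circular boundary of radius `r`
   into a ramp spanning `[√(r² − 30²), r]` from the centre; the raw
   discrete derivative of that ramp is steepest at its outer end — the
   true crossing — but smoothing pulls the maximum about a pixel inward on
   small circles (≈ 1 px at r ≈ 150 px). Detecting on the smoothed signal
   and localising on the raw one keeps both robustness and accuracy.
9. **Edge assignment.** The eight boundary crossings
   `L1 < L2 < L3 < L4 < R4 < R3 < R2 < R1` form four nested symmetric
   pairs. Automatic mode splits the peaks at the image midline, and over
   every choice of four left and four right peaks (paired in nesting
   order, which makes strict diameter nesting automatic) minimises the
   total symmetry residual `Σ |(l + r)/2 − width/2|`. Selections implying
   a lens centre more than 5% of the image width off the midline are
   flagged, mirroring the clinical rule of discarding photographs of
   decentred lenses. Manual mode (`assign_edges_manual()`, or
   `chosen_indices` in `measure_pattern()`) reproduces the observer-driven
   protocol: the user names the eight true peaks from the printed list —
   useful when reflections add spurious peaks that happen to be symmetric.
10. **Widths and calibration.** With diameters `d(k) = Rk − Lk`:
    total = `d(1)`; edge lift = `(d(1) − d(2))/2`; mid-peripheral =
    `(d(2) − d(3))/2`; tear reservoir = `(d(3) − d(4))/2`; central
    bearing = `d(4)`. These close exactly:
    central + 2·(reservoir + mid-peripheral + edge lift) = total.
    Pixels convert to millimetres through
    `mm_per_px = total_diameter_mm / total_diameter_px`, anchored to the
    manufacturer's nominal lens diameter — so the calibrated total
    diameter equals the nominal one by construction, and all information
    is in the four zone widths. Full precision is kept internally; round
    only for presentation.

### Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `target_width` | 1000 | px | working width; all positions live on this grid |
| `band_height` | 60 | px | meridian band; wider = more noise suppression, more chord bias |
| `smoothing_sigma` | 2 | px | derivative pre-smoothing; 0 for pristine synthetic images |
| `min_prominence_frac` | 0.1 | – | rejects texture/noise peaks relative to the strongest edge |
| `min_separation_px` | 10 | px | merges double responses of one edge; must stay below the narrowest ring |
| `refine_window` | 3 | px | raw-derivative re-localisation; 0 disables |
| `decentration_frac` | 0.05 | – | centre-offset fraction that triggers the decentred-lens flag |

The prominence and separation defaults are chosen so that a realistic
photograph yields the eight true edges plus at most a couple of spurious
reflections (which the assignment step then rejects); both are exposed on
the command line.

## The synthetic generator

No photograph database ships with the package, so `pattern_spec()` /
`render_pattern()` generate test imagery with *exact* ground truth: four
concentric boundary circles, piecewise-constant green intensity per zone
(bright reservoir and edge-lift rings must exceed every dark level by at
least 0.2), red and blue fixed at 25% of green (so green extraction is
consequential in tests), then Gaussian blur, seeded additive Gaussian
noise clipped to [0, 1], and optionally a lossy JPEG round trip.
`pattern_from_lens()` maps a lens data sheet to boundary diameters:
`d1 = total/scale`, `d2 = (D0 + 2D1 + 2D2)/scale`,
`d3 = (D0 + 2D1)/scale`, `d4 = central_bearing/scale`, with the central
bearing necessarily narrower than the back optic zone diameter.

What the generator deliberately does **not** model: the physical
thickness-to-fluorescence response (quenching, film drainage), lens
decentration and movement, corneal toricity (elliptical boundaries),
specular reflections, eyelid shadows, and uneven illumination. Passing the
recovery tests therefore demonstrates that the signal chain localises
concentric intensity edges correctly under blur, noise and JPEG
compression — not that it is robust to every artefact of clinical
photography; on real images the manual mode exists precisely for the
hard cases.

The recovery checks run on 52 patterns (central bearing 3.5–4.5 mm in 13
steps × blur σ ∈ {0, 1, 2, 3}, noise SD 0.02, scale 0.012 mm/px at
1000×600 px), a grid that covers the clinically recommended bearing range
at the study's image scale while keeping the full suite fast; every zone
width must be recovered within ±(2 + σ) px.

## Agreement statistics

`paired_summary()` implements the Bland–Altman analysis used to compare
observers and methods: for paired measurements `a` and `b`, differences
`d = a − b`, their mean and SD (n−1 denominator), the 95% limits of
agreement `mean ± 1.96·SD` (the literal multiplier, not a t-quantile),
a two-sided paired t-test, and the Pearson correlation of `a` with `b`.
Differences are always first-listed minus second-listed, and the report
labels the order. `agreement_report()` assembles the study-style tables:
inter-observer per method and zone, and inter-method per zone with each
eye's value per method taken as the mean of the two observers.

Confidence intervals for the limits of agreement default to the
Bland–Altman large-sample formula `SE = SD·√(1/n + z²/(2(n−1)))` with
`CI = limit ± t_{n−1}·SE`; an exact mode inverts the noncentral-t pivot
(`√n(d̄ − (μ + zσ))/S ~ t_{n−1}(ncp = −z√n)`). The approximate mode is
the default because it reproduces published intervals of this kind to
printed precision; the exact intervals are somewhat wider at n = 26.

Degenerate inputs follow explicit conventions: zero-variance differences
give LoA of width zero and an undefined (NA) t; a constant group makes
Pearson's r undefined (NA); both carry a human-readable note. Fewer than
three complete pairs is an error, and incomplete pairing reports the
missing eyes by name.

## Numerical conventions and edge cases

* All positions are 0-based columns of the resized image; manual peak
  indices are 0-based to match the printed peak list.
* Plateau maxima contribute their central sample; prominence is computed
  topographically (height above the higher of the two valley floors
  towards the nearest taller sample or the signal end).
* The automatic assignment is an exhaustive minimisation (at most
  `C(7,4)²` ≈ 1.2k combinations for up to 14 peaks), not a greedy pick;
  ties are resolved by a fixed enumeration order, so runs are bit-for-bit
  reproducible.
* Images whose stretch is degenerate (constant), whose height is below
  the band, or with fewer than eight detected peaks fail with specific
  errors; batch processing logs the failure and continues.
* The generator restores the caller's RNG state, so seeded rendering does
  not perturb surrounding simulations.

## Known limitations

* EXIF orientation tags are not read (none of the available decoders
  exposes them); photographs must be upright as exported.
* Only the horizontal meridian is measured — by design, matching standard
  practice; toric patterns and zone *areas* need multi-meridian analysis.
* Band averaging biases edges of strongly curved (small) circles inward;
  re-localisation removes most of this, but sub-pixel accuracy is not
  attempted.
* Calibration trusts the nominal lens diameter; any true deviation of the
  manufactured diameter scales all widths proportionally.
* The tool measures the pattern; it does not judge the fit. Clinical
  thresholds belong to the fitter.
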