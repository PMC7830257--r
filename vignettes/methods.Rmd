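---
title: "Breathing-pattern extraction from thermal video: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breathing-pattern extraction from thermal video: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irtbreath)
```

## The measurement problem

Respiration rate (RR) is a routine vital sign in cattle, but contact methods
(stethoscope, flank observation) disturb the animal or fail in cold weather.
Infrared thermography offers a contact-free alternative: air exhaled through
the nostrils is warm, inhaled air is cool, so the temperature field inside
the nostril openings oscillates at the breathing frequency. Given a thermal
video and a per-frame binary mask of the nostril region (the ROI), the
breathing pattern is the time series of an ROI temperature statistic, and RR
follows from counting its peaks.

`irtbreath` implements this pipeline end to end:

1. **ROI masks** — imported from an external instance-segmentation system
   (JSON + PNG), produced by a classical thermal-contrast detector
   (`threshold_detector()`), or taken from simulator ground truth
   (`oracle_provider()`). Training or running a neural detector is out of
   scope by design; masks enter through a provider contract.
2. **Fusion** — masks act multiplicatively on the co-registered temperature
   frames; `extract_series()` aggregates the in-mask values per frame.
3. **Aggregation** — three rival statistics: per-frame maximum (`max`),
   mean (`mean` = sum / mask pixel count), and integrated sum (`sum`,
   °C·pixels).
4. **Smoothing and rate** — Gaussian-window smoothing
   (`smooth_series()`), prominence-based peak detection (`detect_peaks()`),
   and conversion to breaths/min via the five-breath rule
   (`estimate_rr()`).
5. **Scoring** — detection quality (IoU, precision, recall, AP/mAP at an
   IoU threshold) and agreement between rate series (OLS regression,
   `rr_regression()`), plus a method-comparison screen
   (`method_comparison()`) for the known failure modes of `max` and `sum`.

## Why three aggregation statistics

The statistics differ in what they are sensitive to, and the package's
method-comparison machinery operationalizes exactly those differences:

- **mean** is invariant to the apparent ROI size. Camera-distance changes
  rescale the nostril's pixel footprint, and head turns alternate between
  one and two visible nostrils; neither changes the mean of a
  (near-uniform) interior temperature.
- **sum** scales with ROI area: a one-to-two nostril switch doubles it and
  a distance change multiplies it by the apparent area ratio, regardless of
  breathing. `method_comparison()` flags such level shifts when the ratio
  of 5-second trailing/leading medians around a mask pixel-count
  change-point exceeds 1.25 — a deliberate operationalization of a
  judgment that is otherwise made by eye.
- **max** ignores the spatial extent of the warm region: shallow and deep
  breaths with equal peak temperature produce identical max traces, so
  breath-strength information is lost and the usable oscillation can fall
  below the noise floor (the `low_amplitude` flag, default threshold
  0.2 °C on the smoothed trace).

One subtlety: in the simulator the nostril interior is spatially uniform,
so the mean over an *exact* interior mask is also extent-invariant. The
shallow-versus-deep contrast is therefore demonstrated with one *fixed* ROI
mask that covers both warm extents (the larger scene's mask applied to both
scenes): the max traces are then identical while the mean traces differ with
breath depth. This mirrors practice, where a detected ROI is never a perfect
interior crop.

## The synthetic scene model

Real recordings of hospitalized calves and a trained detector are not
distributable, so validation rests on a simulator (`scene_config()`,
`generate_scene()`) that emulates the acquisition geometry and its
confounds:

- breathing-driven nostril temperature: `baseline + amplitude *
  sin(2*pi*rate/60 * t)`, warm peak = exhalation. A sinusoid is the
  simplest periodic waveform that makes every downstream expectation
  analytic; real breath waveforms are asymmetric, which shifts peak shape
  but not peak count.
- one or two elliptical nostril openings on a uniform ambient background,
  with slow two-axis sinusoidal head motion (periods 23 s and 17 s, well
  below the breathing band), a per-frame `distance_schedule` that rescales
  radii and separation (apparent area scales by the square), and a
  per-frame `nostril_schedule` in {1, 2}.
- additive i.i.d. Gaussian sensor noise per pixel per frame, default sd
  0.07 °C — the stated sensitivity of the consumer thermal camera the
  pipeline targets, and the only noise figure available.

Defaults mirror the target acquisition stream: 640 x 480 frames at 10 fps
for 60 s (184,320,000 temperature values per minute), nostril baseline
33 °C, ambient 25 °C, nostril semi-axes (20, 14) px and separation 90 px at
scale 1. No amplitude in °C is documented for cattle breath; the default
2 °C is exposed (never hard-coded downstream) and was chosen once as a
visible-but-not-extreme oscillation relative to the 8 °C nostril-ambient
contrast. The seed controls only the noise, so ground-truth masks are
identical across seeds; identical configurations reproduce bit-identical
scenes.

What the simulator deliberately does **not** model: exhaled-air plumes and
turbulence, emissivity physics (emissivity is metadata only, matching how
the field uses these cameras), RGB photorealism (the RGB channel is a flat
background with a darker nose region — segmentation here is oracle- or
threshold-based), parallax between RGB and thermal (a shared pixel grid is
assumed), and non-uniform interior temperature. Passing tests therefore
demonstrate the *pipeline's* correctness under controlled confounds, not
detector performance on real animals.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `noise_sd` | 0.07 | °C | stated device sensitivity |
| `amplitude` | 2 | °C | exposed; see above |
| smoothing window | 1 s of samples, rounded up to odd | samples | must stay below the shortest breath period in the 10–60 bpm band (1 s at 60 bpm); a 2 s window attenuates a 1 Hz breath to ~12% gain and buries its peaks under boundary effects |
| kernel `sigma` | window / 6 | samples | ±3 sigma spans the window |
| `min_prominence` | 0.3 | fraction of trace range | rejects ripple while keeping attenuated breaths |
| `min_distance_s` | 0.5 | s | refractory period; no cattle breath cycle is shorter |
| `iou_threshold` | 0.5 | fraction | conventional detection threshold; a match requires IoU *strictly* above it |
| `n_bins` | 256 | bins | standard 8-bit histogram for Otsu search |
| shift threshold | 1.25 | ratio | level-shift flag on 5 s trailing/leading medians |
| gap interpolation | ≤ 1 s | s | linear interpolation for short empty-mask gaps; longer gaps split the trace and the longest segment is used |

## Rate estimation rules

`estimate_rr()` mirrors the observer protocol: with at least six detected
peaks, the time from the 1st to the 6th peak spans five complete breaths and
converts as `5 / duration * 60` (`rr_from_five_breaths()`; ten seconds for
five breaths is 30 breaths/min). With two to five peaks it falls back to the
reciprocal mean inter-peak interval. The five-breath window is anchored at
the first detected peak; since observers and algorithm need not align their
windows, agreement analyses compare *rates*, never window placement. Peaks
mark exhalations (warm); an `invert` flag handles conventions where the
cool phase dominates.

## Numerical and tie-break choices

- **Otsu threshold**: the criterion behind "optimal quantization" is
  maximal between-class variance over an `n_bins` histogram (the cited
  technique's exact criterion is not documented; Otsu is the standard
  reading of "best separates object from background"). Candidate
  thresholds are interior bin edges; ties break toward the *lower*
  threshold. Thresholding is per-frame ("dynamic") by default; a
  per-recording threshold can be passed explicitly to `optimal_quantize()`.
- **Quantization map**: sub-threshold pixels → 0; `[threshold, max]` maps
  linearly onto `[0, 255]`, so the frame maximum is always 255.
- **Matching**: greedy in descending score; score ties break by frame
  index, then box coordinates, then input order — intrinsic geometry in
  the tie-break makes precision/recall/AP invariant to the order
  detections arrive in, which pure input-order tie-breaking does not
  guarantee. Box IoU is the default ("two bounding boundaries"); mask IoU
  is available via `use_mask`.
- **AP**: all-point interpolation (precision envelope integrated over
  recall), the COCO-style choice; with one class, mAP = AP.
- **Connected components**: 8-connectivity (4-connected labelling from
  EBImage, then a union-find merge of diagonally adjacent labels);
  boundary-touching components are kept.
- **Smoothing boundaries**: reflected padding. A truly constant segment
  bypasses the convolution so constants are preserved exactly, not merely
  to rounding error.
- **Peak plateaus**: runs of equal values flanked by lower neighbours
  count as one peak at the plateau center — essential at rates whose peak
  falls midway between samples, where floating-point ties are otherwise
  resolved arbitrarily.
- **Prominence**: standard topographic definition (height above the higher
  of the two key saddles), with series ends treated as ground.
- **Empty-mask frames** become missing values with pixel count 0; `sum`
  keeps its °C·pixels units explicit to prevent cross-method comparisons
  of incommensurable series.
- **Regression**: OLS with intercept, estimated rate regressed on true
  (reference) rate; the two-sided zero-slope p-value is reported. Forcing
  through the origin was rejected to keep intercept bias visible.

## Problem sizes used for validation

The statistics of exact masks are resolution-independent, so simulation
studies run at reduced frame sizes with geometry scaled proportionally
(e.g. 160 x 120 with radii (5, 3.5) px, or 120 x 160 with radii (8, 6) px in
unit tests), while the worked bookkeeping examples use the full 640 x 480
stream. The recovery experiment defaults to 50 recordings of 60 s at 10 fps
with rates uniform on 10–60 breaths/min, exact ground-truth masks and mean
aggregation; the `rgb` and `annotation_masks` switches of `generate_scene()`
skip rendering outputs that such batch studies never read.

## Known limitations

- The simulator's uniform nostril interior makes `mean` and `sum` perfectly
  clean absent confounds; real traces carry segmentation jitter and
  physiological variability, so real-data agreement will be lower than the
  near-perfect synthetic recovery.
- Spectral (FFT) rate estimation, apnea/arrhythmia classification and
  pulmonary-sound analysis are out of scope; auscultation remains necessary
  for such diagnoses.
- Thermal/RGB parallax alignment and radiometric file decoding are not
  handled; inputs are assumed co-registered on one pixel grid.
- Very long empty-mask gaps discard data (longest-segment rule); no
  stitching across gaps is attempted.
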