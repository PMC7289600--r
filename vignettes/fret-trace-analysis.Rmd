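---
title: "Quantifying sustained versus transient kinase activity from FRET biosensor traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sustained versus transient kinase activity from FRET biosensor traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretquant)
```

## The measurement model

A ratiometric FRET biosensor reports kinase activity as the ratio of
acceptor to donor emission (Y/C for epifluorescence emission ratiometry;
GFP/RFP for TIRF translocation assays, where the denominator controls for
cell spreading). `fretquant` treats a single-cell experiment as:

1. a two-channel image stack with physical calibration (µm/px, s/frame);
2. a region set: one cell-free background region plus one region per cell;
3. per-frame, per-channel subtraction of the background region mean from
   every pixel (per-frame, so slow lamp drift is absorbed), floored at 0
   because counts are physical;
4. the per-frame ratio of the numerator to denominator region means;
5. normalization of each trace by its baseline R0, the ratio at the last
   frame before stimulus addition, so the normalized trace is exactly 1 at
   that frame.

The region statistic is the arithmetic mean of member pixels — the
convention of ratio-imaging acquisition software. Regions are fixed over
time; cells that wander out of their region are a QC matter, handled by
exclusion rather than tracking. All pixel coordinates in the public
interface are R-native (1-based, `x` = column, `y` = row).

Ratio extraction is invariant to any common positive rescaling of the two
channels, and background subtraction is idempotent once the background
mean is zero; both properties are exercised in the test suite.

## Response metrics

For a normalized trace with stimulus frame `stim_index`:

- **Rmax, Rmin** are the maximum and minimum ratio recorded *strictly
  after* stimulation. Two magnitudes are reported: `(Rmax - Rmin)/Rmin`
  and the percent increase over baseline `(Rmax - R0)/R0`. Ties in Rmax
  resolve to the earliest frame (this affects only the reported peak
  time).
- **SAM40** = `(R40 - R0)/(Rmax - R0)`, the fraction of the maximal
  response still present 40 min after stimulation: 1 for a fully
  sustained response, 0 for a full return, negative for an undershoot
  (reported, never clamped). The 40-min time point rarely coincides with
  a frame; R40 is linearly interpolated between the bracketing frames —
  at 30-s sampling the correction is below one frame. SAM40 is invariant
  under affine transformation of the trace, so raw and normalized traces
  give identical values. If an inhibitor is added after the stimulus, the
  Rmax/SAM40 window still runs from the stimulus.
- **Time to half-max** is the first post-stimulus crossing of
  `R0 + 0.5 (Rmax - R0)`, linearly interpolated, reported relative to the
  stimulus time. It is a proxy for activation kinetics. Note that it is
  defined against the *observed* Rmax: for a slowly saturating response
  the observed maximum sits below the asymptote unless the trace is long,
  so closed-form comparisons (t½ = ln 2 / k for a pure saturating rise)
  are made on long noiseless traces (120 min) where the two coincide to
  well under a frame interval.
- **Slope change** around a drug addition fits OLS slopes in
  `[t - w, t)` and `(t, t + w]`. The default window `w` is 5 min; it is a
  free parameter, since the procedure itself only presumes local
  linearity. An immediate slope change after adding a kinase inhibitor
  indicates the kinase was still actively phosphorylating the sensor.

R0 defaults to the single pre-stimulus frame; `baseline_frames = k`
averages the last k pre-stimulus frames for noisy data. No smoothing is
applied before metric computation. Degenerate non-responders
(Rmax = R0, SAM40 undefined) are flagged, not dropped silently.

## Quality control

Two exclusion procedures operate on the per-cell metric table, always
within a condition:

**Robust FDR outlier flagging.** Values are centred on the median and
scaled by 1.4826·MAD; two-sided tail probabilities come from a
t-distribution with n−1 degrees of freedom, and a Benjamini–Hochberg
step-up at rate Q (default 1%) marks outliers. This is a documented
single-sample variant of regression-based robust-FDR outlier detection
(which is defined for nonlinear curve fits and is proprietary in its
best-known implementation); for a one-dimensional metric sample the
variant has the same intent — FDR-controlled flagging against a robust
centre — and is fully specifiable and testable. Flags are invariant under
affine transforms of the data. A zero MAD with non-identical values falls
back to an IQR-based scale with a warning; identical values yield no
flags.

**Iterative expression-artifact filter.** Cells with extremely high or
low biosensor expression can behave abnormally. While any |Pearson r|
between a response metric (`max_over_baseline`, `sam40` by default) and
an expression covariate (starting ratio, starting donor fluorescence)
reaches 0.5 and more than `min_cells` remain, the cell with the most
extreme robust z-score on the covariate of the worst pair is removed and
all correlations recomputed. Exactly one cell is removed per iteration,
so termination within `n − min_cells` steps is structural. The removal
order (worst pair, most extreme covariate) is a design choice — the
procedure is fully determined only up to its stopping rule — and both the
metric and covariate sets are configurable. The `min_cells = 5` floor
guarantees termination on pathological inputs (e.g. perfectly collinear
data, where r is invariant under subsetting); such conditions are
retained at the floor and flagged `unfiltered`. Manual exclusions (e.g.
visibly apoptotic cells) enter as an explicit id list in the pipeline
config.

## Morphology and protrusion quantification

Cell shape is measured from the equivalent ellipse of the second central
moments of a segmentation mask: axis lengths are four times the square
roots of the coordinate-covariance eigenvalues (exact for an ideal solid
ellipse), and roundness is the minor:major ratio. Masks must be a single
connected component of at least 20 px; morphology is measured on the
frame at stimulus time.

Protrusions are quantified on a kymograph: the mask profile sampled along
a fixed line through the centroid at the equivalent-ellipse orientation
(nearest-pixel sampling, 1-px width), one column per frame. Deriving the
line from the ellipse orientation automates what is traditionally drawn
by hand; manually chosen endpoints can be passed instead. The line
extends 25% beyond the baseline boundary by default so later protrusions
stay on it; for large programmed extensions the margin should be raised
accordingly. For a near-circular mask the orientation is undefined and
the line falls back deterministically to the image x-axis with a warning.

For each end of the line, the per-frame edge is the outermost foreground
pixel; the baseline edge is the median over pre-stimulus frames. A
protrusion event is a maximal run of frames with outward displacement of
at least `min_extension_um` (default 1 µm); its length is the peak
displacement along the line (the only reading consistent with a 1-D
kymograph) and its persistence the run duration. Events shorter than
`min_persistence_min` are discarded. Frames with no foreground on the
line have their edge interpolated from neighbours, with a warning.
Population classification reports fractions of round (ratio > 0.8) and
elongated (ratio < 0.6) cells, cells with any protrusion longer than 5
µm, and — among those — the fraction whose long protrusions persist
beyond 15 min. Event side (left/right end of the line) is reported so
polarization can be summarized; that summary is an extension beyond the
core measurements.

## The synthetic-data generators

No raw imaging data accompanies the analysis this package implements, so
the generators define the ground truth every stage is tested against.
They emulate the *statistical structure* the analysis assumes, not the
biology:

- **Traces.** Two minimal kernels reproduce the two observed trace
  families: transient
  `f(τ) = A·c·(e^(−k_dec·τ) − e^(−k_act·τ))` (c normalizes the peak to
  A; `k_act = k_dec` is rejected as undefined, and `k_dec = 0`
  degenerates continuously to the saturating form), and sustained
  `f(τ) = A·(1 − e^(−k_act·τ))·e^(−k_dec·τ)` with `k_dec = 0` allowed
  for a plateau. The raw ratio is
  `R(t) = R0·(1 + f + drift·t)·(1 + ε_t)` with i.i.d. multiplicative
  Gaussian noise — multiplicative because a ratio of two shot-noise
  limited region means fluctuates on a relative scale. These are
  emulations of observed shapes, not mechanistic models of the signalling
  cascade.
- **Defaults as study conditions.** Amplitude mean 0.745 (a 74.5% mean
  maximal response, the calibration target for a strong cytosolic ERK
  reporter), 30-s frames, stimulus after 2.5 min of baseline, 45 min of
  post-stimulus imaging (96 frames). Transient kinetics default to
  `k_act = 0.2`, `k_dec = 0.04` /min (peak ≈ 10 min post-stimulus);
  sustained to `k_act = 0.15`, `k_dec = 0.005` /min (slower rise,
  near-plateau), reflecting that membrane-proximal responses accumulate
  more slowly. The per-frame noise sd defaults to 0.03; no published
  value constrains single-cell trace noise, so this is a free fixture
  parameter, chosen as a realistic relative noise for EMCCD ratio
  imaging, and stated wherever results depend on it.
- **Expression artifacts.** Artifact cells are drawn as extremely bright
  or dim: their expression covariate sits 5–6 population sd from the mean
  (either side, a tail draw rather than a wider normal) and their
  response amplitude is linearly coupled to it
  (`A = A_mean·(1 + z/5)` by default, floored at a small positive
  amplitude). With 10% artifact cells this yields a population Pearson
  correlation of ≈ 0.8 between maximal response and expression — the
  regime the expression filter is designed for. A wider-normal artifact
  model was considered and rejected: a 10% subpopulation with
  normally-spread expression cannot produce r ≈ 0.8 without implausible
  amplitudes, and it leaves most artifact cells statistically
  indistinguishable from normal cells, which no covariate-based filter
  could (or should) remove.
- **Image stacks.** Disk-shaped cells over a uniform background; donor
  carries `donor_level` counts above background inside a cell and the
  acceptor `donor_level·R_t`, so the extracted ratio equals the
  programmed trace exactly in the noiseless case; optional additive
  Gaussian read noise per pixel, with a first-order error-propagation
  bound (`ratio_noise_sd()`) used to test the noisy case. Textures,
  photobleaching, bleed-through and chromatic shift are deliberately out
  of scope: only region means and boundaries matter downstream.
- **Mask movies.** An elliptical cell with square-pulse finger
  protrusions of programmed length and duration along the major axis.
  The realized ground truth is reported in pixels and frames
  (`round(extension_um / pixel_size_um)` px; frames with
  `onset ≤ t < end`), which is what a pixel/frame-quantized measurement
  can recover.

Every generator is a pure function of its arguments including the seed.
Passing tests on these fixtures demonstrates that the *measurement
pipeline* is correct — the kernels match real trace families only in
shape, and none of the generators model focus drift, segmentation error,
cell movement or division, so performance on real microscopy data still
depends on acquisition and segmentation quality upstream of this package.

## Numerical and interface choices

- Linear interpolation for R40 and t½; first-crossing and
  earliest-tie-break rules make all metrics deterministic.
- Negative pixels after background subtraction are floored at 0; region
  means remain unbiased for the fixtures used (backgrounds well above
  zero).
- TIFF I/O stores counts as 16-bit integers against a fixed full scale of
  65535: integer counts round-trip byte-losslessly; fractional values are
  quantized to 1/65535. The analysis itself operates in memory, so the
  quantization affects only optional file round-trips.
- Welch's correction for two-group comparisons is applied when an F-test
  of variances rejects at 0.05 (the conventional formalization of
  "correct if variances differ"); forced Welch/pooled modes are
  available, and both tests are always reported. The multiple-comparison
  method after one-way ANOVA is Tukey HSD. Zero-variance degenerate
  groups follow explicit conventions (identical constants: t = 0, p = 1;
  distinct constants: infinite statistic, p = 0) rather than erroring.
- `run_pipeline()` is a pure function of (config, seed); every
  intermediate is written as CSV, and the log records the package
  version, config hash and per-cell exclusion decisions. Cell ids are
  prefixed with their condition so they remain unique across conditions.

## Problem sizes used in verification

The test suite and the acceptance script verify the pipeline at these
scales, chosen to make sampling statements stable: 1,000 random traces
(500 per kinetic family) for the brute-force oracle comparison; 100
traces for affine invariance; 100 + 100 cells for the
sustained-versus-transient contrast; a 4 × 5 grid of programmed
protrusions (2–10 µm × 5–30 min) at 0.5 µm/px and 30 s/frame; five mask
rotations for morphology; 100 seeds (plus 40 null seeds) for the
expression filter; and 250 seeds × 2 slopes for noisy slope recovery.
The noisy slope fixture uses 25-min OLS windows (50 frames per window):
the slope t-statistic is pivotal, so the fraction recovered within 3
standard errors depends only on the window's degrees of freedom, and
5-min windows at 30-s sampling (8 df) would cap that fraction near 97%
no matter how small the noise.

## Known limitations

- Regions are static; moving cells must be handled by exclusion or by
  supplying per-frame masks upstream.
- No spectral bleed-through or FRET-efficiency correction is applied; the
  package analyses raw emission ratios.
- The protrusion reading is one-dimensional along the chosen line; full
  perimeter edge-velocity mapping is out of scope.
- The ROUT-style outlier flagger is a documented single-sample variant,
  not a reimplementation of the regression-based original; results can
  differ on samples that a nonlinear-regression fit would treat
  differently.
- The 0.8/0.6 roundness and 5 µm/15 min protrusion thresholds are
  conventional cut-offs for this assay class; the classification
  functions expose them as arguments so other conventions can be
  applied.
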