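---
title: "Measuring body movement from video: model, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring body movement from video: model, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhimotion)
```

## The measurement model

`mhimotion` estimates a single per-frame index of general body movement from
video. The model deliberately avoids face, limb or body models: it asks only
*how much of the frame changed recently*, which is cheap, robust to varied
backgrounds, and sensitive both to small movements (eye blinks, postural
micro-adjustments) and large ones (head tilts, leaning).

Per frame `F_t`:

1. convert to grayscale (BT.601 luma, rounded half-up);
2. form the absolute difference against `F_{t-1}` and threshold it at `T`:
   pixels that changed by **strictly** more than `T` are foreground;
3. stamp foreground pixels in a motion history image (MHI) with the current
   timestamp and expire stamps older than the memory `N`; a stamp exactly
   `N` ms old is retained.

The **motion index** is the fraction of MHI cells carrying a stamp. Because
the MHI holds everything that moved within the last `N` ms, the index is a
momentum-smoothed activity measure, not an instantaneous one. The
**estimated movement** series — the absolute difference of the index across
adjacent frames — is the primary dependent measure: it converts an activity
*level* into a magnitude of *change*, which is what change-sensitive contact
sensors measure, making the streams comparable.

Two worked examples anchor the arithmetic: 10 active pixels in a 10 × 10
frame give an index of `10/100 = 0.1`; adjacent indices 0.1 and 0.3 give an
estimated movement of 0.2.

```{r}
prev <- matrix(0L, 10, 10); curr <- prev; curr[3, 1:10] <- 255L
sil <- binarize(frame_difference(curr, prev), 30)
motion_index(mhi_update(mhi_create(10, 10), sil, 1000 / 30))
absolute_difference(c(0.1, 0.3))$value
```

## Parameters and defaults

* **`N` (MHI memory), default 1000 ms.** Controls smoothing: large `N`
  averages over long history and mutes small changes; small `N` lets
  momentary lighting noise masquerade as motion, and `N` shorter than the
  actions of interest loses them. 1000 ms suits gross body movement, which
  unfolds over tens to hundreds of milliseconds. Because the engine is
  offline, `N` can be re-chosen per analysis without re-recording.
* **`T` (binary threshold), default 30 of 255.** The noise filter: uniform
  intensity shifts of at most `T` between consecutive frames produce index
  exactly 0. Too low lets sensor/lighting noise through; too high discards
  true motion of low-contrast regions. The comparison is strict (`> T`), so
  `T = 0` marks exactly the nonzero differences.
* **Burn-in, default 1 s.** The rolling background model needs time to
  stabilise; recordings differ (3 s was needed with one camera setup, 1/5 s
  with clips cut from a longer recording), so the span is configurable in
  seconds or samples, with an automatic mode that strips the maximal leading
  run above `mean + 2.5 SD` of the full series.
* **Outlier rule, 2.5 SD, one pass, two-sided.** Mean and sample SD are
  computed once over non-missing values; flagged values become missing
  (never imputed). One pass keeps the rule deterministic; iterating to
  convergence would flag progressively more as the SD shrinks. The test
  suite documents that a second pass may flag additional values.
* **Windows, `k = 10`.** Streams at different rates (30 fps video, 4 Hz
  pressure pad) are aligned *only* through equal-width windowing — no
  resampling or interpolation. Width is `floor(n/k)` samples; the trailing
  remainder is dropped so "equal width" holds exactly; all-missing windows
  stay missing.
* **Lags −1, 0, +1.** One window of tolerance for imperfect stream
  synchronisation, with the *best positive lag* rule: strongest positive
  correlation wins; with no positive value, lag 0 is reported; exact ties
  prefer lag 0.

## Numerical choices

* Timestamps derive from frame index and fps (`t = i · 1000/fps`), never
  from a wall clock, so runs are bit-reproducible.
* Frame 0 emits no sample: no predecessor, no difference; burn-in discard
  removes the unstable start anyway.
* Grayscale rounding is half-up (`floor(x + 0.5)`), avoiding banker's
  rounding asymmetries; inputs deeper than 8 bits are rescaled to
  `[0, 255]`.
* The MHI stores raw per-pixel timestamps rather than decaying brightness;
  the familiar fading-silhouette picture is an affine rendering of stamp
  age (`mhi_render()`). The two representations are equivalent, but
  timestamps are exactly testable.
* The normalized cross-correlation divides the lagged cross-covariance by
  `s_x · s_y` computed with the population (1/n) convention over the *full*
  series at every lag. This guarantees `C(0) = 1` for a series against
  itself and keeps values in `[−1, 1]`; with 10 windows and lags of at most
  one, full-series versus overlap-segment moments differ negligibly.
* Degenerate inputs error early and descriptively: constant series have no
  defined correlation; an SD of zero flags no outliers; a clock moving
  backwards, a mid-stream frame-size change, and an unknown frame rate are
  each distinct errors.
* The one-sample effect size is defined as `d = M/SD`; `t = M/(SD/√n)`,
  `df = n − 1`. Feeding raw values or the `(M, SD, n)` triple gives
  identical results.
* Percentile subsetting excludes the `⌈n · p/100⌉` smallest values by rank
  with ties broken by original order — with 27 subjects at `p = 25`, exactly
  7.

## What the synthetic generator emulates — and what it does not

The generator reproduces the *structure* of a video-plus-contact-sensor
validation study: a 30 fps video of a subject moving against a quasi-static
background, paired with a sensor stream (scalar, tri-axis, or a 38 × 41
pressure grid at 4–50 Hz) that observes the same latent movement plus noise.

* **Latent profile.** The default `"bursts"` kind alternates quiet and
  active segments (2–6 s long, active with probability 0.5); within a
  burst, per-frame displacement is uniform on `0:A` with a per-segment
  amplitude `A ≤ 4` px/frame. This mimics fidgeting of varying vigour
  separated by stillness — the regime in which a movement index is
  scientifically interesting.
* **Scene.** A 12 × 12 bright object bounces horizontally inside a 64 × 64
  frame over a background with Gaussian pixel noise (SD 3, well below
  `T = 30`) and optional slow uniform illumination drift; intensities clamp
  to `[0, 255]`. Ground truth — the exact count of noise-free changed
  pixels per frame — is returned alongside the frames.
* **Sensor.** The profile is resampled by *integration*: each sample
  averages the displacement over the video frames whose midpoints fall in
  its sampling interval (shifted by the configured lag). Real pads and
  accelerometers integrate motion over their sampling period; point-sampling
  a 30 fps jitter signal at 4 Hz would alias and would misrepresent the
  sensor, not the method. Gain, per-channel Gaussian noise (default SD 0.5
  against a burst amplitude of ~2), and a configurable lag complete the
  model. The tri-axis layout splits the signal along a fixed unit vector so
  its Euclidean norm recovers `gain × profile` exactly at zero noise; the
  grid layout spreads a proportional load over a central patch so the grid
  mean does the same.

Under these defaults — 60 s sessions, 10 windows, sensor at 4 Hz — the
windowed lag-0 cross-correlation between the video pipeline's estimated
movement and the paired sensor is 0.85–0.97 across seeds, and injecting a
one-window (6 s) sensor lag moves the best lag to ±1. The test suite
(`test-acceptance.R`) checks exactly this, over 20 seeds.

What the generator does **not** emulate: articulated human bodies,
occlusions, shadows, camera panning/zoom, auto-exposure transients,
multiple moving objects, and correlated (non-Gaussian) lighting noise.
Passing tests therefore demonstrate the correctness of the algorithmic
chain and its recovery of a shared latent signal under controlled
conditions — not performance on arbitrary real footage, which depends on
lighting, framing and camera quality.

## Design decisions taken where the design was open

* **Which pixels the index counts.** The index counts all active MHI cells
  (motion within the last `N` ms), not merely the current silhouette: the
  composite motion image is what the proportion of displaced pixels is
  computed from, and this is what gives the index its momentum smoothing.
* **Grayscale weights.** BT.601 luma with round-half-up; any fixed
  convention would do, but this is the standard-definition video transform
  and is pinned exactly so the reference oracle can be bit-exact.
* **Strict threshold comparison** (`> T`) — the boundary case had to land
  somewhere; strictness makes `T = 0` meaningful.
* **Negative lags** are defined by the antisymmetry `C_xy(−k) = C_yx(k)`,
  the standard convention for cross-correlation.
* **Differencing as a per-stream switch.** Video-derived motion and
  position-type sensors are differenced; accelerometer-type streams already
  measure change and are not.
* **Sample SD** is used for z-scoring (outlier rules); the population
  convention appears only inside the cross-correlation normalisation, where
  it is required for `C(0) = 1`.
* **Problem sizes in the test suite.** Oracle-equivalence runs 50 random
  16 × 16 × 10 videos against a naive per-pixel reference; the cross-modal
  recovery suite runs twenty 60 s, 64 × 64, 30 fps sessions. These sizes
  exercise every code path and keep the whole suite under a minute of
  engine time while matching the session structure (60 s, 30 fps, 4 Hz,
  10 windows) the analysis defaults are built around.

## Known limitations

* Only uncompressed 24-bit AVI (plus PNG frame directories and in-memory
  arrays) is supported for video I/O; compressed AVI/MP4 requires an
  external codec library. The AVI reader rejects compressed streams with a
  clear error rather than mis-decoding them.
* The index is a whole-frame measure: it cannot separate two people in
  frame, distinguish effectors, or segment regions of interest.
* Movement toward or away from the camera is under-weighted (the method
  sees the x–y plane only).
* The one-pass outlier rule assumes outliers are rare; in pathological
  series where most mass is outlying, one pass under-flags by design.
* Windowed cross-correlation with `k = 10` has only 10 points per series;
  it is a coarse within-session agreement measure, not a spectral one.
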