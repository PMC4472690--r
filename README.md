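# mhimotion

Quantify how much a person (or any subject) moves, frame by frame, from
ordinary video — no wearables, no markers, no special hardware. `mhimotion`
is aimed at researchers in the cognitive, affective and behavioural sciences
who need a single, cheap, non-intrusive index of general body movement from
webcam-grade recordings, together with the statistical toolchain for
validating that index against contact sensors (pressure pads, wrist
accelerometers, depth-camera tracking).

## The method

Each video frame `F_t` is processed in three steps:

1. **Grayscale** — `F_t` is collapsed to BT.601 luma.
2. **Motion silhouette** — the absolute difference `|F_t − F_{t−1}|` is
   thresholded: a pixel is *foreground* iff it changed by more than `T`
   (default 30 of 255), which filters background noise such as lighting
   flicker.
3. **Motion history image (MHI)** — each foreground pixel is stamped with
   the current time; stamps older than the memory `N` (default 1000 ms)
   expire. The MHI is a rolling background model: its active cells are
   "everything that moved in the last `N` ms".

The per-frame **motion index** is the fraction of active MHI pixels — 10
moved pixels in a 10 × 10 frame give 10/100 = 0.1. Its absolute difference
across adjacent frames (*estimated movement*) is the primary dependent
measure.

For validation, series from video and contact sensors are cleaned (burn-in
discard, one-pass 2.5-SD outlier blanking), optionally differenced
(per-stream: an accelerometer already measures change), reduced to `k = 10`
equal-width window means, and compared by the normalized lagged
cross-correlation

```
C_xy(k) = [ (1/n) Σ_{t=1..n−k} (x_t − x̄)(y_{t+k} − ȳ) ] / (s_x s_y),   C_xy(−k) = C_yx(k)
```

with the *best positive lag* among −1, 0, +1 used to tolerate slight stream
misalignment, and one-sample summaries (`t = M/(SD/√n)`, Cohen's
`d = M/SD`) aggregating per-subject correlations.

A seeded generator of synthetic scenes (a moving object over a noisy
quasi-static background) and co-registered sensor streams (scalar, tri-axis,
or 38 × 41 pressure grid at 4–50 Hz) sharing one latent movement profile
makes the whole pipeline testable end to end without any real recordings.

## Worked example

Simulate a 60 s study session — a subject fidgeting in bursts, filmed at
30 fps while a 4 Hz scalar sensor records the same movement — then run the
full analysis:

```r
library(mhimotion)

profile <- movement_profile(n_frames = 1800, kind = "bursts", fps = 30, seed = 42)
video   <- generate_motion_video(profile, scene_config(), seed = 43)
sensor  <- generate_sensor_series(profile, sensor_config(rate_hz = 4, noise_sd = 0.5), seed = 44)

motion <- process_video(video, tracker_config())  # N = 1000 ms, T = 30
motion
#> # A tibble: 1,799 × 3
#>   frame timestamp_ms motion_index
#>   <int>        <dbl>        <dbl>
#> 1     1         33.3            0
#> 2     2         66.7            0
#> 3     3        100              0
#> # i 1,796 more rows

wv <- window_means(prepare_series(motion, rate_hz = 30, diff = TRUE),  k = 10)
ws <- window_means(prepare_series(sensor, rate_hz = 4,  diff = FALSE), k = 10)
cross_correlation(wv, ws)
#> <normalized cross-correlation> n = 10 windows
#>   lag -1: 0.067
#>   lag  0: 0.890  <- best
#>   lag  1: 0.089
```

The video-derived movement and the sensor agree at `r = 0.89` at lag 0 —
the two streams recovered the same latent movement profile — and the
correlation collapses at ±1 window, so the streams are correctly aligned.
Aggregating such per-subject correlations:

```r
one_sample_summary(c(.62, .48, .71, .55, .66))
#> # A tibble: 1 × 6
#>    mean     sd     n     t    df     d
#>   <dbl>  <dbl> <int> <dbl> <int> <dbl>
#> 1 0.604 0.0907     5  14.9     4  6.66
```

`autoplot()` works on motion series, windowed series and cross-correlation
results; `tidy()`/`glance()` give tibble views of correlation profiles.

There is also a command-line front end (installed under `inst/cli/`):

```sh
Rscript mhimotion.R process recordings/ --threshold 30 --out results/
Rscript mhimotion.R validate --series motion.csv:diff --series sensor.csv:nodiff --out report.csv
Rscript mhimotion.R simulate --fixture default --seed 7 --out fixture/
```

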