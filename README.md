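# pcgmap

Multichannel phonocardiogram processing and cardiac acoustic mapping in R.

Heart sounds project onto the chest wall with a spatial pattern that moves
over the cardiac cycle: S1 (mitral/tricuspid closure) concentrates over the
lower-left intercostal spaces, S2 (aortic/pulmonary closure) higher and more
medially. A dense chest-surface sensor array — 72 phonocardiogram (PCG)
channels at 10 kHz plus one ECG reference — captures that pattern, and a
*cardiac acoustic map* renders it: at each instant the modulus
`e_i(n) = |s_i(n)|` of the conditioned heart-sound signal is interpolated
across the sensor positions and painted over a standard skeleton image, blue
(quiet) through green and yellow to red (loud). `pcgmap` is for researchers
and engineers building or analyzing such multichannel heart-sound systems:
it implements the whole chain from raw signals and marker photographs to
rendered map sequences, plus the closed-form characterization of the analog
sensor front end, and a synthetic-data generator so every stage is testable
without hardware.

## What it computes

* **Signal conditioning** — ensemble mean-range normalization
  `(s_i − m_i)/(D_max − D_min)` with the range taken over all channels
  jointly; zero-phase (forward–backward) order-4 Butterworth band-pass,
  20–200 Hz; coiflet-5 wavelet denoising at 7 levels with the universal
  threshold `T = σ̂·sqrt(2 ln N)` and soft shrinkage.
* **ECG anchoring** — resample to 200 Hz, 0.5–40 Hz zero-phase band-pass,
  resample to 10 kHz; Pan–Tompkins R-wave detection (derivative, squaring,
  150 ms integration, adaptive dual thresholds, 200 ms refractory,
  search-back); R-to-R cycle segmentation.
* **Channel location** — HSV thresholding plus a circle Hough transform
  extracts colored disc markers from the chest photograph and skeleton
  image; a landmark-based rotate/scale/translate chain (four anatomical
  reference points) maps sensor coordinates into skeleton-image pixels.
* **Mapping** — thin-plate-spline interpolation of the channel moduli
  (exact at sensors, masked outside their convex hull), HSL colormap
  `hue = 240°·(1 − E/Em)`, alpha-composited frame sequences.
* **Sensor characterization** — RC cut-offs `1/(2πCR)`, dB gain chains,
  `SNR = 10·log10(P1/P2)`, two-sensor consistency difference rates
  `|ΔV|/V_B`, `|Δf|/f_B`, and Welch-PSD center frequency estimates.

## Worked example

```r
library(pcgmap)

# 1. synthesize a 72-channel recording with a known acoustic source
layout <- generate_sensor_layout(8, 9, spacing = 40, origin = c(120, 120))
schedule <- beat_schedule(c(0.5, 1.5, 2.5))       # 3 beats at 60 bpm
source <- source_spec(position = c(312, 246))      # over the "cardiac" area
rec <- generate_pcg_array(layout, schedule, list(source),
                          fs = 10000, noise_sd = 0.01, seed = 1)
rec
#> <pcg_recording> 72 channel(s) x 35000 samples @ 10000 Hz (3.500 s)

# 2. condition: normalize -> 20-200 Hz zero-phase band-pass -> denoise
cond <- preprocess_pcg(rec)
round(c(d_max = cond$stats$d_max, d_min = cond$stats$d_min), 4)
#>   d_max   d_min
#>  0.9053 -0.6047

# 3. ECG anchoring: detected R times (s) match the schedule
ecg <- generate_ecg(schedule, fs = 10000, noise_sd = 0.02, seed = 2)
peaks <- detect_r_peaks(preprocess_ecg(ecg))
peaks / 10000
#> [1] 0.5001 1.5001 2.5001

# 4. map the S1 burst of the first beat (t = 0.540 s)
fr <- interpolate_frame(layout, abs(cond$rec$data[, 5401]))
pk <- which(fr$values == max(fr$values, na.rm = TRUE), arr.ind = TRUE)[1, ]
c(x = fr$x[pk[2]], y = fr$y[pk[1]])
#>   x   y
#> 316 243       # within 7 px of the true source at (312, 246)

# 5. the blue-to-red modulus colormap at 0, Em/2, Em
hsl_to_rgb(modulus_to_hue(c(0, 0.5, 1), colormap_spec(em = 1)))
#>        r   g   b
#> [1,]   0   0 255
#> [2,]   0 255   0
#> [3,] 255   0   0
```

The detected R peaks land within 0.1 ms of the scheduled beats, and the
spatial peak of the S1 frame falls well within one inter-sensor spacing
(40 px) of the configured source — the two recoveries the map rendering
depends on.

`render_sequence()` turns a window of the recording into composited PNG
frames (e.g. 0.002 s steps across S1); `locate_channels()` goes from a
marked chest photograph and skeleton image to registered sensor coordinates.
A command-line wrapper is included at `inst/cli/pcgmap.R` with subcommands
`simulate | preprocess | ecg | register | render | sensorcal`.

## Layout

```
R/                  implementation (fixtures, preprocess, wavelet, ecg,
                    registration, mapping, sensorcal, io, cli)
tests/testthat/     unit, property and acceptance tests
scripts/acceptance.R
vignettes/cardiac-acoustic-mapping.Rmd   methods and design rationale
inst/cli/pcgmap.R   command-line entry point
```
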