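---
title: "Methods: from multichannel heart sounds to cardiac acoustic maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from multichannel heart sounds to cardiac acoustic maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcgmap)
```

## The problem

Heart sounds reach the chest wall with amplitudes and timings that depend on
where the listening sensor sits: S1 (atrioventricular valve closure) and S2
(semilunar valve closure) project most strongly over different intercostal
spaces, and the pattern moves over the course of each sound. A dense sensor
array — here emulated as 72 chest-surface phonocardiogram (PCG) channels
sampled at 10 kHz alongside one ECG reference channel — captures this spatial
structure, and a *cardiac acoustic map* displays it: at each time instant, the
absolute value (modulus) of the conditioned heart-sound signal is
interpolated across the sensor positions and painted over a standard skeleton
image, blue for quiet regions through green and yellow to red for the
loudest.

`pcgmap` implements the full chain: signal conditioning, ECG anchoring of the
cardiac cycle, locating the sensors on the skeleton image from a chest
photograph, and rendering the time-resolved maps, plus the closed-form
characterization of the analog sensor front end. A synthetic-data module
generates every input with known ground truth, so the whole pipeline is
testable without hardware.

## Signal conditioning

Conditioning runs in the order normalize, band-pass, denoise
(`preprocess_pcg()`), each stage exposed separately.

**Ensemble mean-range normalization** (`normalize_channels()`). Channel
$i$ becomes $(s_i(n) - m_i) / (D_{\max} - D_{\min})$, with $m_i$ the channel
mean and $D_{\max}, D_{\min}$ the extrema over *all channels jointly*. The
joint range is deliberate: the acoustic map encodes *relative* inter-channel
amplitude, and per-channel scaling would erase the spatial gradient that the
map exists to display. Normalization statistics are computed over the whole
record; no acquisition transient is trimmed first (callers who need trimming
can subset before normalizing).

**Zero-phase Butterworth band-pass** (`bandpass_zero_phase()`). Order 4,
20–200 Hz by default — the dominant band of normal heart sounds. The filter
runs forward, then backward over the reversed output, so the magnitude
response is the square of the single-pass response and the net phase is
zero; burst timing is therefore preserved exactly, which matters because
frames are indexed by sample. Two numerical choices suppress edge
transients: the signal is odd-reflection padded by three periods of the low
band edge (3·fs/20 samples at the defaults) before filtering, and the mean
is removed first — the passband excludes DC, and subtracting the offset
before filtering cancels the slow step response of the 20 Hz (or, for the
ECG path, 0.5 Hz) corner from the zero initial filter state.

**Wavelet denoising** (`wavelet_denoise()`). Coiflet-5 mother wavelet,
7 decomposition levels, "sqtwolog" universal threshold
$T = \hat\sigma\sqrt{2\ln N}$, soft shrinkage. At 10 kHz the dyadic detail
bands put levels 7 (39.06–78.13 Hz) and 8 (19.53–39.06 Hz) on the
heart-sound energy, which is why a 7-level decomposition with coif5 works
well here (`detail_band_edges()` tabulates the bands). The DWT is
implemented in-package as an orthogonal filter bank with *periodized*
boundary handling: circular analysis makes the transform exactly orthogonal
and reconstruction exact to machine precision, at the price of requiring
the length to be a multiple of $2^{\text{level}}$ — so each channel is
symmetrically reflect-padded up to that multiple and trimmed back after
reconstruction, which also supplies symmetric-extension behaviour at the
record ends. The noise scale $\hat\sigma$ defaults to the robust estimate
$\mathrm{median}(|d_1|)/0.6745$ from the finest detail band, the usual
companion of the universal threshold; setting `sigma = 1` in
`wavelet_spec()` gives the bare $\sqrt{2\ln N}$ threshold for the literal
reading of the rule. Soft shrinkage is applied to every detail band;
the approximation band is left untouched.

## ECG anchoring

The ECG exists to timestamp cardiac cycles, not for morphological analysis,
so the conditioning path (`preprocess_ecg()`) optimizes R-wave timing:
resample to 200 Hz, zero-phase Butterworth 0.5–40 Hz (order 3), resample to
the common 10 kHz time base. Resampling is polyphase FIR (Hamming-windowed
low-pass, delay-compensated, odd-reflection edge extension), so it is
amplitude-accurate to a few tenths of a percent and phase-free.

R waves are detected with the Pan–Tompkins stages (`detect_r_peaks()`):
5–15 Hz band-pass, five-point derivative, squaring, 150 ms moving-window
integration, adaptive dual thresholds with a 200 ms refractory period and
search-back at half threshold when an expected beat is missed. Detection
runs at 200 Hz — the algorithm's native design rate — and each detection is
then refined to the local extremum of the full-rate trace within ±40 ms, so
reported indices are at the trace's own sampling rate and timing error on
clean fixtures is well under one millisecond. Parameters follow the original
published algorithm. Consecutive R indices become half-open R-to-R cycles
via `segment_cycles()`.

## Channel location on the skeleton image

The chest photograph carries green discs at the sensor impressions and red
discs at four anatomical reference points (sternoclavicular joint, right
10th rib, right and left 6th ribs); the skeleton image carries the same four
reference points. `extract_markers()` thresholds in HSV space (presets
`"green-disc"`, `"red-disc"`; the red hue window wraps through 0°) and runs
a circle Hough transform over the radius range: edge pixels of the binary
mask vote for centers, votes are aggregated over a 3×3 neighbourhood (the
rounding of vote positions spreads a true center's votes over adjacent
pixels), candidates are validated by mask coverage — a disc center is the
point supporting the largest ≥90%-covered circle — and surviving centers are
refined to the sub-pixel centroid of the covered mask. On rendered fixtures
this recovers centers to about 0.1 px.

Detected landmarks are assigned their anatomical roles geometrically
(`label_landmarks()`): topmost = sternoclavicular joint, bottommost = right
10th rib, and of the remaining two the smaller-x point is the subject's
right 6th rib — an anterior view places the subject's right on the image
left, and the same rule applied to both images yields consistent
correspondences regardless of mirroring convention.

`estimate_transform()` recovers rotation, anisotropic scale and translation
from the two landmark sets: the rotation angle is the difference of the
6th-rib baseline angles, the x scale comes from that baseline's horizontal
span, the y scale from the vertical span of landmarks 1–2, and the
translation anchors landmark 3 in x and landmark 1 in y. Two modes exist.
The default `"consistent"` mode applies a true planar rotation by
$\theta_2 - \theta_1$ about chest landmark 3 (the anchor that the x
translation fixes exactly), then scales about the origin, then translates;
this reduces to the identity for identical landmark sets, recovers pure
similarities exactly, and has a closed-form affine inverse
(`invert_transform()`). The `"literal"` mode evaluates an alternative
transcription of the transform arithmetic sometimes seen for this
procedure — the angle taken as the cotangent of the slope ratio and the
"rotation" $w' = w\cos\theta_1\cos\theta_2$,
$h' = h\sin\theta_1\sin\theta_2$ — which is not a rotation (it zeroes a
coordinate for axis-aligned baselines and does not reduce to the identity);
it is preserved for comparison only, and `"consistent"` is the default
because only it satisfies the identity and round-trip properties a
registration needs. Pixel coordinates are
(column x, row y), origin top-left, y downward, in both images.

Channel ids are assigned row-major over the detected chest positions (rows
clustered in y with a tolerance of half the median nearest-neighbour
distance, then left-to-right), matching how a grid vest is numbered.

## Mapping and rendering

The mapped quantity is the modulus $e_i(n) = |s_{i}(n)|$ of the conditioned
signal (`compute_modulus()`). For one time instant, `interpolate_frame()`
interpolates the 72 moduli over the sensor bounding box. Registered sensor
positions are not a perfect rectilinear grid, so the default interpolant is
a thin-plate spline: it is exact at the nodes, smooth (C1 at the nodes,
analytic elsewhere), and its affine polynomial part reproduces planar fields
exactly — the three contracts the map rendering relies on. For layouts that
do form a complete grid, a tensor-product natural cubic spline path is
available (`method = "bicubic"`). Values outside the convex hull of the
sensors are masked out rather than extrapolated: color there would be
unsupported by data, and the skeleton background shows through instead.

Color follows the HSL rule: normalized modulus
$\varepsilon_g = E/E_m$ clipped to $[0,1]$, hue
$\varepsilon = 240°(1-\varepsilon_g)$, saturation 1, lightness 0.5, then a
standard HSL→RGB conversion (`modulus_to_hue()`, `hsl_to_rgb()`). Zero
modulus is blue, $E_m$ is red; clipping is required because a spline
interpolant can overshoot its node values. The normalization maximum $E_m$
defaults to the global maximum over the rendered window, so a given modulus
has the same color in every frame of a sequence and brightness is
comparable across the stages of a heart sound; per-frame normalization is
available (`colormap_spec(em_scope = "per_frame")`), and a fixed $E_m$ can
be supplied to compare across recordings. `render_sequence()` composites
the color layer over the skeleton background with alpha 0.6 (a display
choice, exposed as a parameter) at one frame per `frame_interval` —
typically 0.002 s across S1 and 0.001 s across the shorter S2 — with
inclusive window endpoints.

## The synthetic-data generator

The fixtures emulate exactly the features downstream stages consume, and no
more. `generate_pcg_array()` builds each channel as a sum over virtual
acoustic sources of Gabor atoms (Gaussian-windowed cosines) fired at the
scheduled S1/S2 times, attenuated by $\exp(-d/\lambda)$ in sensor–source
pixel distance $d$, plus white Gaussian noise drawn channel-by-channel from
one seeded generator (fixed seed ⇒ bit-identical output). Default study
conditions: an 8×9 grid of 72 sensors at 40 px spacing; beats at 60 bpm;
S1 40 ms and S2 310 ms after each R wave; 50 Hz carrier with 15 Hz
bandwidth (Gaussian envelope $\sigma_t = 1/(2\pi\,\mathrm{bw})\approx$
11 ms, so bursts last ~60 ms inside the 20–200 Hz heart-sound band); decay
length 80 px; S2 at 0.8 of the S1 amplitude. The cosine carrier makes the
waveform peak coincide with the envelope center, so burst timing and the
spatial peak are well defined sample-wise. `generate_ecg()` sums five
Gaussian component waves (P, Q, R, S, T) per beat with a narrow dominant R
spike exactly at the beat time and returns the ground-truth R indices
alongside. `render_marker_image()` draws saturated discs on a near-white
background, and `synthetic_registration_pair()` builds a matched
chest/skeleton image pair from a known similarity (7°, ×1.25, (40, −25) px
by default) with the true registered coordinates returned for scoring.

What the generator does *not* model: thoracic acoustics (no wave equation,
no dispersion, no multipath), murmurs or pathology, sensor coupling
variation, baseline wander, powerline or motion artifacts, and real
photographic conditions (lighting gradients, specularity, partial disc
occlusion). Passing tests therefore demonstrate that the *algorithms* meet
their contracts under controlled conditions — exact reconstruction,
zero-phase behaviour, sub-pixel registration, monotone color order — not
that the system performance on real chest recordings is reproduced.

## Numerical choices and degenerate inputs

* Periodized DWT requires each level to remain at least as long as the
  30-tap coif5 filter; shorter inputs raise an error rather than silently
  wrapping (`wavelet_decompose()`).
* A constant ensemble has zero range and cannot be normalized; that is a
  degenerate-input error, not a silent division by zero.
* Band edges at or above Nyquist, non-positive scales in registration, a
  zero-length 6th-rib baseline, collinear sensor layouts, and empty render
  windows all raise immediate errors with the offending quantity named.
* Landmark count ≠ 4 in either image aborts registration naming the image
  and the count found.
* Flat or all-noise ECG yields an empty detection vector, not an error.
* Tie-breaks: Hough candidates are accepted largest-disc-first; equal-score
  candidates fall back to vote score; row clustering uses half the median
  nearest-neighbour distance.

## Problem sizes in the shipped tests

The test-suite fixtures are sized for fast, deterministic runs while
remaining in the regimes the methods assume: denoising uses a single
channel of 24 000 samples at 4 kHz (10 dB SNR, seeded); R-peak recovery
uses 10–16 beats at 1 kHz input with ~20 dB SNR; registration uses the full
72-sensor pair at disc radii 6–9 px; rendering checks use 3×3 and 8×9
grids with windows of 10–21 frames. The acceptance script evaluates the
closed-form quantities directly.

## Known limitations

* The literal-mode transform is faithfully non-invertible; only consistent
  mode supports the affine inverse and error analysis.
* The Hough stage assumes filled, approximately circular, well-separated
  discs; overlapping or annular markers would need the validation step
  generalized.
* Thin-plate interpolation is global: one sensor with a wildly wrong
  modulus perturbs the whole frame. No robustness weighting is applied,
  because the interpolation contract is exactness at the nodes.
* WAV I/O covers 16-bit PCM and 32-bit float RIFF only — adequate for the
  pipeline's own files, not a general audio reader.
* Animation packing (GIF/MP4) is out of scope; frames are written as
  numbered PNGs and a manifest.
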