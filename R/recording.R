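#' Multichannel phonocardiogram recording
#'
#' Container for a channels-by-samples matrix of heart sound voltages with a
#' common sampling rate. All downstream conditioning ([normalize_channels()],
#' [bandpass_zero_phase()], [wavelet_denoise()]) and mapping operations accept
#' and return this class.
#'
#' @param data Numeric matrix, one row per channel, one column per sample.
#'   A vector is promoted to a single-channel matrix.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel_ids Optional integer or character channel identifiers,
#'   one per row. Defaults to `1:nrow(data)`.
#' @return An object of class `pcg_recording` with fields `data`, `fs`,
#'   `channel_ids`.
#' @examples
#' rec <- pcg_recording(matrix(rnorm(200), nrow = 2), fs = 100)
#' n_channels(rec)
#' @export
pcg_recording <- function(data, fs, channel_ids = NULL) {
  if (is.vector(data)) data <- matrix(data, nrow = 1)
  stopifnot(is.matrix(data), is.numeric(data))
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive finite scalar", call. = FALSE)
  if (is.null(channel_ids)) channel_ids <- seq_len(nrow(data))
  if (length(channel_ids) != nrow(data))
    stop("`channel_ids` must have one entry per channel", call. = FALSE)
  structure(list(data = data, fs = fs, channel_ids = channel_ids),
            class = "pcg_recording")
}

#' @export
print.pcg_recording <- function(x, ...) {
  cat(sprintf("<pcg_recording> %d channel(s) x %d samples @ %g Hz (%.3f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' @rdname pcg_recording
#' @param rec A `pcg_recording`.
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname pcg_recording
#' @export
n_samples <- function(rec) ncol(rec$data)

#' Single-channel ECG trace
#'
#' Holds the ECG reference signal that anchors cardiac cycles, and optionally
#' the sample indices of detected (or ground-truth) R-wave peaks.
#'
#' @param samples Numeric vector of ECG samples (volts or millivolts).
#' @param fs Sampling rate in Hz.
#' @param r_peaks Optional integer vector of strictly increasing R-peak sample
#'   indices (1-based), all within the trace.
#' @return An object of class `ecg_trace`.
#' @export
ecg_trace <- function(samples, fs, r_peaks = NULL) {
  stopifnot(is.numeric(samples))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar", call. = FALSE)
  if (!is.null(r_peaks)) {
    r_peaks <- as.integer(r_peaks)
    if (length(r_peaks) && (any(diff(r_peaks) <= 0L) ||
                            any(r_peaks < 1L) || any(r_peaks > length(samples))))
      stop("`r_peaks` must be strictly increasing indices within the trace",
           call. = FALSE)
  }
  structure(list(samples = as.numeric(samples), fs = fs, r_peaks = r_peaks),
            class = "ecg_trace")
}

#' @export
print.ecg_trace <- function(x, ...) {
  cat(sprintf("<ecg_trace> %d samples @ %g Hz, %s R peaks\n",
              length(x$samples), x$fs,
              if (is.null(x$r_peaks)) "no" else length(x$r_peaks)))
  invisible(x)
}

#' Sensor layout: per-channel pixel coordinates
#'
#' Pixel positions of the sensor array, either on the chest photograph or
#' (after registration) on the skeleton background image. Coordinates follow
#' the image convention: `x` is the column, `y` the row, origin at the
#' top-left corner with `y` increasing downward.
#'
#' @param coords Numeric n-by-2 matrix of `(x, y)` pixel coordinates.
#' @param channel_ids Optional identifiers, default `1:n`.
#' @return An object of class `sensor_layout` with fields `coords` (matrix
#'   with columns `x`, `y`) and `channel_ids`.
#' @export
sensor_layout <- function(coords, channel_ids = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) stop("`coords` must be an n-by-2 matrix", call. = FALSE)
  if (!is.numeric(coords) || any(!is.finite(coords)))
    stop("`coords` must be finite numeric", call. = FALSE)
  colnames(coords) <- c("x", "y")
  if (is.null(channel_ids)) channel_ids <- seq_len(nrow(coords))
  if (length(channel_ids) != nrow(coords))
    stop("`channel_ids` must match the number of coordinates", call. = FALSE)
  structure(list(coords = coords, channel_ids = channel_ids),
            class = "sensor_layout")
}

#' @export
print.sensor_layout <- function(x, ...) {
  cat(sprintf("<sensor_layout> %d sensors, x in [%g, %g], y in [%g, %g]\n",
              nrow(x$coords), min(x$coords[, 1]), max(x$coords[, 1]),
              min(x$coords[, 2]), max(x$coords[, 2])))
  invisible(x)
}

#' Beat schedule for synthetic recordings
#'
#' Times of the cardiac cycles in a synthetic recording, plus the latencies of
#' the first (S1) and second (S2) heart sound bursts relative to each R wave.
#' S1 follows ventricular depolarization closely; S2 arrives near end-systole.
#'
#' @param beat_times Strictly increasing beat (R-wave) times in seconds.
#' @param s1_delay S1 burst-center delay after the R wave, seconds.
#' @param s2_delay S2 burst-center delay after the R wave, seconds;
#'   must exceed `s1_delay`.
#' @return An object of class `beat_schedule`.
#' @export
beat_schedule <- function(beat_times, s1_delay = 0.04, s2_delay = 0.31) {
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) && any(diff(beat_times) <= 0))
    stop("`beat_times` must be strictly increasing", call. = FALSE)
  if (!(s1_delay > 0 && s2_delay > s1_delay))
    stop("need 0 < s1_delay < s2_delay", call. = FALSE)
  structure(list(beat_times = beat_times, s1_delay = s1_delay,
                 s2_delay = s2_delay), class = "beat_schedule")
}

#' Virtual acoustic source specification
#'
#' Describes one spatial source of heart sound energy used by
#' [generate_pcg_array()]: a Gabor (Gaussian-windowed sinusoid) burst emitted
#' at the scheduled S1/S2 times, whose amplitude at each sensor decays
#' exponentially with Euclidean pixel distance from the source.
#'
#' @param position Length-2 `(x, y)` pixel position of the source.
#' @param center_freq Burst carrier frequency in Hz; normal heart sounds
#'   concentrate in roughly 20-200 Hz.
#' @param bandwidth Burst bandwidth in Hz; sets the Gaussian envelope width
#'   `sigma_t = 1 / (2 * pi * bandwidth)`.
#' @param amplitude Peak amplitude at the source position (arbitrary units).
#' @param decay_length Spatial attenuation constant in pixels (> 0).
#' @param component Which heart sounds this source emits: `"both"`, `"s1"`,
#'   or `"s2"`.
#' @return An object of class `source_spec`.
#' @export
source_spec <- function(position, center_freq = 50, bandwidth = 15,
                        amplitude = 1, decay_length = 80,
                        component = c("both", "s1", "s2")) {
  component <- match.arg(component)
  if (length(position) != 2L || any(!is.finite(position)))
    stop("`position` must be finite (x, y)", call. = FALSE)
  if (center_freq <= 0 || bandwidth <= 0)
    stop("`center_freq` and `bandwidth` must be positive", call. = FALSE)
  if (decay_length <= 0) stop("`decay_length` must be > 0", call. = FALSE)
  structure(list(position = as.numeric(position), center_freq = center_freq,
                 bandwidth = bandwidth, amplitude = amplitude,
                 decay_length = decay_length, component = component),
            class = "source_spec")
}

# Evaluate code with a fixed seed, restoring the caller's RNG state afterwards
# so that library calls never perturb user-level reproducibility.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
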