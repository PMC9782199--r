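#' Generate a regular grid sensor layout
#'
#' Builds the pixel coordinates of an `n_rows` by `n_cols` sensor array with
#' uniform spacing, channel ids assigned row-major (left to right, top to
#' bottom). The 72-sensor vest emulated by the fixtures is an 8 x 9 grid.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param spacing Inter-sensor spacing in pixels (> 0).
#' @param origin `(x, y)` pixel position of the first (top-left) sensor.
#' @return A [sensor_layout()] with `n_rows * n_cols` coordinates.
#' @examples
#' layout <- generate_sensor_layout(8, 9, spacing = 40, origin = c(100, 100))
#' nrow(layout$coords)  # 72
#' @export
generate_sensor_layout <- function(n_rows, n_cols, spacing, origin = c(0, 0)) {
  if (n_rows < 1 || n_cols < 1 || n_rows != round(n_rows) || n_cols != round(n_cols))
    stop("`n_rows` and `n_cols` must be positive integers", call. = FALSE)
  if (!is.numeric(spacing) || spacing <= 0)
    stop("`spacing` must be > 0", call. = FALSE)
  if (length(origin) != 2L) stop("`origin` must be (x, y)", call. = FALSE)
  g <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  coords <- cbind(x = origin[1] + (g$col - 1) * spacing,
                  y = origin[2] + (g$row - 1) * spacing)
  sensor_layout(coords)
}

# Gaussian-windowed sinusoid centered at t0: the Gabor atom used for S1/S2
# bursts. sigma_t from the bandwidth so the burst is band-limited around f0.
gabor_burst <- function(t, t0, f0, bw) {
  sigma <- 1 / (2 * pi * bw)
  # cosine carrier: the waveform peak coincides with the envelope center,
  # so burst timing and spatial peak location are well defined sample-wise
  exp(-((t - t0)^2) / (2 * sigma^2)) * cos(2 * pi * f0 * (t - t0))
}

#' Generate a synthetic multichannel PCG recording
#'
#' Each channel is a superposition, over the configured acoustic sources, of
#' Gabor tone bursts fired at the scheduled S1 and S2 times, with per-channel
#' amplitude scaled by `exp(-distance / decay_length)` (distance from sensor
#' to source in pixels), plus white Gaussian noise. This reproduces the two
#' features the downstream pipeline relies on: a spatially decaying amplitude
#' gradient over the array and an S1/S2 timing structure phase-locked to the
#' ECG beat schedule.
#'
#' @param layout A [sensor_layout()] giving sensor positions.
#' @param schedule A [beat_schedule()].
#' @param sources Non-empty list of [source_spec()] objects.
#' @param fs Sampling rate in Hz; must be at least twice the highest source
#'   carrier frequency.
#' @param noise_sd Standard deviation of the additive white Gaussian noise.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param duration Recording length in seconds; defaults to the last beat
#'   time plus one second.
#' @param s2_gain Relative amplitude of S2 bursts (default 0.8).
#' @return A [pcg_recording()].
#' @export
generate_pcg_array <- function(layout, schedule, sources, fs = 10000,
                               noise_sd = 0.01, seed = 1, duration = NULL,
                               s2_gain = 0.8) {
  stopifnot(inherits(layout, "sensor_layout"), inherits(schedule, "beat_schedule"))
  if (!is.list(sources) || length(sources) == 0)
    stop("`sources` must be a non-empty list of source_spec", call. = FALSE)
  if (inherits(sources, "source_spec")) sources <- list(sources)
  fmax <- max(vapply(sources, function(s) s$center_freq, numeric(1)))
  if (fs < 2 * fmax)
    stop(sprintf("fs = %g Hz is below the Nyquist rate of a %g Hz source",
                 fs, fmax), call. = FALSE)
  if (is.null(duration)) {
    duration <- if (length(schedule$beat_times)) max(schedule$beat_times) + 1 else 1
  }
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  nch <- nrow(layout$coords)

  # clean burst train per source (shared across channels up to amplitude)
  src_wave <- lapply(sources, function(s) {
    w <- numeric(n)
    for (bt in schedule$beat_times) {
      if (s$component %in% c("both", "s1"))
        w <- w + gabor_burst(t, bt + schedule$s1_delay, s$center_freq, s$bandwidth)
      if (s$component %in% c("both", "s2"))
        w <- w + s2_gain * gabor_burst(t, bt + schedule$s2_delay,
                                       s$center_freq, s$bandwidth)
    }
    w
  })

  data <- matrix(0, nrow = nch, ncol = n)
  for (j in seq_along(sources)) {
    s <- sources[[j]]
    d <- sqrt((layout$coords[, 1] - s$position[1])^2 +
              (layout$coords[, 2] - s$position[2])^2)
    att <- s$amplitude * exp(-d / s$decay_length)
    data <- data + outer(att, rep(1, n)) *
      matrix(src_wave[[j]], nrow = nch, ncol = n, byrow = TRUE)
  }
  if (noise_sd > 0) {
    with_seed(seed, {
      for (i in seq_len(nch))  # channel order fixed for reproducibility
        data[i, ] <- data[i, ] + stats::rnorm(n, sd = noise_sd)
    })
  }
  pcg_recording(data, fs, layout$channel_ids)
}

#' Generate a synthetic ECG trace with known R-peak positions
#'
#' Produces a PQRST-like waveform by summing five Gaussian component waves per
#' beat (P, Q, R, S, T), with a narrow dominant R spike exactly at each
#' scheduled beat time, plus optional white noise. The ground-truth R-peak
#' indices are stored in the returned trace, so detector tests can score
#' recall and timing error against construction truth.
#'
#' @inheritParams generate_pcg_array
#' @param schedule A [beat_schedule()]; an empty schedule yields an empty
#'   trace (no error).
#' @return An [ecg_trace()] with `r_peaks` set to the ground-truth indices.
#' @export
generate_ecg <- function(schedule, fs = 10000, noise_sd = 0, seed = 1,
                         duration = NULL) {
  stopifnot(inherits(schedule, "beat_schedule"))
  if (fs <= 0) stop("`fs` must be > 0", call. = FALSE)
  if (length(schedule$beat_times) == 0) {
    n <- if (is.null(duration)) 0 else round(duration * fs)
    return(ecg_trace(numeric(n), fs, r_peaks = integer(0)))
  }
  if (is.null(duration)) duration <- max(schedule$beat_times) + 1
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  # (amplitude mV, delay s relative to R, width s); R is the narrow spike
  waves <- list(P = c(0.15, -0.20, 0.025),
                Q = c(-0.10, -0.025, 0.010),
                R = c(1.50, 0.00, 0.008),
                S = c(-0.25, 0.030, 0.010),
                T = c(0.35, 0.25, 0.060))
  x <- numeric(n)
  for (bt in schedule$beat_times)
    for (w in waves)
      x <- x + w[1] * exp(-((t - bt - w[2])^2) / (2 * w[3]^2))
  if (noise_sd > 0) with_seed(seed, x <- x + stats::rnorm(n, sd = noise_sd))
  r_idx <- round(schedule$beat_times * fs) + 1L
  r_idx <- r_idx[r_idx >= 1L & r_idx <= n]
  ecg_trace(x, fs, r_peaks = as.integer(r_idx))
}

# saturated fill colors suited to HSV thresholding
marker_palette <- function(name) {
  switch(name,
         red   = c(0.85, 0.08, 0.08),
         green = c(0.10, 0.72, 0.10),
         blue  = c(0.08, 0.10, 0.85),
         stop(sprintf("unknown disc color '%s'", name), call. = FALSE))
}

#' Render a synthetic marker image
#'
#' Draws filled colored discs on a near-white background, emulating the
#' photographs of the marked chest surface and the skeleton background image
#' used for registration. Pixel `(row i, col j)` has coordinates
#' `x = j, y = i` (origin top-left).
#'
#' @param width,height Image size in pixels.
#' @param discs List of discs, each a list with fields `center` (`(x, y)`),
#'   `radius` (pixels), and `color` (`"red"`, `"green"`, or `"blue"`).
#' @param background Background gray level in `[0, 1]` (default 0.96).
#' @return An `height x width x 3` numeric RGB array in `[0, 1]`.
#' @export
render_marker_image <- function(width, height, discs = list(),
                                background = 0.96) {
  stopifnot(width >= 1, height >= 1)
  img <- array(background, dim = c(height, width, 3))
  if (length(discs) == 0) return(img)
  xs <- matrix(seq_len(width), nrow = height, ncol = width, byrow = TRUE)
  ys <- matrix(seq_len(height), nrow = height, ncol = width)
  for (d in discs) {
    cx <- d$center[1]; cy <- d$center[2]; r <- d$radius
    if (cx - r < 1 || cx + r > width || cy - r < 1 || cy + r > height)
      stop(sprintf("disc at (%g, %g) radius %g extends outside the %dx%d image",
                   cx, cy, r, width, height), call. = FALSE)
    rgb <- marker_palette(d$color)
    inside <- (xs - cx)^2 + (ys - cy)^2 <= r^2
    for (k in 1:3) {
      plane <- img[, , k]
      plane[inside] <- rgb[k]
      img[, , k] <- plane
    }
  }
  img
}
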