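# Heart-sound conditioning chain: ensemble mean-range normalization,
# zero-phase Butterworth band-pass, wavelet denoising (see wavelet.R).

#' Ensemble mean-range normalization
#'
#' Removes per-channel baseline (mean) and rescales the whole ensemble by its
#' global range: channel `i` becomes `(s_i(n) - m_i) / (Dmax - Dmin)` where
#' `m_i` is the channel mean and `Dmax`, `Dmin` are the maximum and minimum
#' over **all** channels jointly. The shared denominator preserves the
#' relative inter-channel amplitudes that the acoustic map displays;
#' per-channel ranges would flatten the spatial gradient.
#'
#' @param rec A [pcg_recording()].
#' @return List with `rec` (normalized recording) and `stats` (list with
#'   `d_max`, `d_min`, `means`).
#' @examples
#' r <- pcg_recording(rbind(c(0, 1), c(1, 3)), fs = 10)
#' normalize_channels(r)$rec$data  # rows (-1/6, 1/6) and (-1/3, 1/3)
#' @export
normalize_channels <- function(rec) {
  stopifnot(inherits(rec, "pcg_recording"))
  if (ncol(rec$data) < 1) stop("empty recording", call. = FALSE)
  d_max <- max(rec$data)
  d_min <- min(rec$data)
  if (d_max == d_min)
    stop("degenerate input: global range is zero (constant ensemble)",
         call. = FALSE)
  means <- rowMeans(rec$data)
  out <- (rec$data - means) / (d_max - d_min)
  list(rec = pcg_recording(out, rec$fs, rec$channel_ids),
       stats = list(d_max = d_max, d_min = d_min, means = means))
}

#' Band-pass filter specification
#'
#' Defaults match the heart-sound conditioning chain: order-4 Butterworth,
#' 20-200 Hz passband (the dominant band of normal heart sounds), applied
#' forward-backward for zero net phase.
#'
#' @param low_hz,high_hz Band edges in Hz, `0 < low_hz < high_hz`.
#' @param order Butterworth order per pass (>= 1).
#' @param zero_phase Apply forward-backward (default TRUE).
#' @return An object of class `bandpass_spec`.
#' @export
bandpass_spec <- function(low_hz = 20, high_hz = 200, order = 4,
                          zero_phase = TRUE) {
  if (!(low_hz > 0 && high_hz > low_hz)) stop("need 0 < low_hz < high_hz", call. = FALSE)
  if (order < 1) stop("`order` must be >= 1", call. = FALSE)
  structure(list(low_hz = low_hz, high_hz = high_hz, order = order,
                 zero_phase = zero_phase), class = "bandpass_spec")
}

# Forward-backward IIR filtering with odd-symmetric reflection padding.
# The pad length covers the slow transient of the low band edge
# trail of the transient is discarded with the padding.
filtfilt_reflect <- function(x, b, a, pad) {
  n <- length(x)
  pad <- min(pad, n - 1)
  if (pad > 0) {
    pre  <- 2 * x[1] - x[(pad + 1):2]
    post <- 2 * x[n] - x[(n - 1):(n - pad)]
    xe <- c(pre, x, post)
  } else xe <- x
  # the band rejects DC, so remove the offset first: this cancels the slow
  # step-response transient of the low band edge from the zero initial state
  xe <- xe - mean(xe)
  y <- signal::filter(b, a, xe)
  y <- rev(signal::filter(b, a, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Zero-phase Butterworth band-pass filtering
#'
#' Applies the band-pass of `spec` in the forward direction, reverses the
#' result and filters again, so the effective magnitude response is the
#' square of the single-pass Butterworth response and the net phase is zero.
#' Edge transients are suppressed by odd-symmetric reflection padding sized
#' to the low band edge.
#'
#' @param rec A [pcg_recording()].
#' @param spec A [bandpass_spec()]; band edges must lie below `rec$fs / 2`.
#' @return Filtered [pcg_recording()].
#' @export
bandpass_zero_phase <- function(rec, spec = bandpass_spec()) {
  stopifnot(inherits(rec, "pcg_recording"), inherits(spec, "bandpass_spec"))
  nyq <- rec$fs / 2
  if (spec$high_hz >= nyq)
    stop(sprintf("high band edge %g Hz is at or above Nyquist (%g Hz)",
                 spec$high_hz, nyq), call. = FALSE)
  bf <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / nyq,
                       type = "pass")
  pad <- ceiling(3 * rec$fs / spec$low_hz)
  out <- rec$data
  for (i in seq_len(nrow(out))) {
    out[i, ] <- if (spec$zero_phase)
      filtfilt_reflect(rec$data[i, ], bf$b, bf$a, pad)
    else as.numeric(signal::filter(bf$b, bf$a, rec$data[i, ]))
  }
  pcg_recording(out, rec$fs, rec$channel_ids)
}

#' Dyadic detail-band edges of the wavelet decomposition
#'
#' For a sampling rate `fs`, the level-`k` detail band of a dyadic wavelet
#' decomposition spans `(fs / 2^(k+1), fs / 2^k)` Hz. At 10 kHz the level-7
#' band is 39.0625-78.125 Hz, which is why a 7-level decomposition isolates
#' the dominant heart-sound band.
#'
#' @param fs Sampling rate in Hz.
#' @param level Deepest level (>= 1).
#' @return Data frame with columns `level`, `low_hz`, `high_hz`.
#' @examples
#' detail_band_edges(10000, 8)
#' @export
detail_band_edges <- function(fs, level) {
  if (level < 1 || level != round(level)) stop("`level` must be >= 1", call. = FALSE)
  k <- seq_len(level)
  data.frame(level = k, low_hz = fs / 2^(k + 1), high_hz = fs / 2^k)
}

#' Full preprocessing chain
#'
#' Convenience wrapper running the conditioning stages in order:
#' normalization, zero-phase band-pass, wavelet denoising.
#'
#' @param rec A [pcg_recording()].
#' @param band A [bandpass_spec()].
#' @param wavelet A [wavelet_spec()], or `NULL` to skip denoising.
#' @return List with `rec` (conditioned recording) and `stats`
#'   (normalization statistics).
#' @export
preprocess_pcg <- function(rec, band = bandpass_spec(),
                           wavelet = wavelet_spec()) {
  nz <- normalize_channels(rec)
  out <- bandpass_zero_phase(nz$rec, band)
  if (!is.null(wavelet)) out <- wavelet_denoise(out, wavelet)
  list(rec = out, stats = nz$stats)
}
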