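# Sensor front-end characterization: RC cut-offs, amplifier gain chain,
# SNR, inter-sensor consistency difference rates, and PSD-based center
# frequency estimation for the bench sweep protocol.

#' First-order RC high-pass cut-off frequency
#'
#' `f_c = 1 / (2 * pi * C * R)`. Both the DC-blocking input network of the
#' amplifier (0.082 uF into 100 kOhm) and the AC-coupling output network
#' (0.82 nF into the 10 MOhm acquisition-card input impedance) evaluate to
#' 19.4 Hz.
#'
#' @param capacitance Capacitance in farads (> 0).
#' @param resistance Resistance in ohms (> 0).
#' @return Cut-off frequency in Hz.
#' @examples
#' rc_highpass_cutoff(0.082e-6, 100e3)  # 19.4 Hz
#' @export
rc_highpass_cutoff <- function(capacitance, resistance) {
  if (any(capacitance <= 0) || any(resistance <= 0))
    stop("capacitance and resistance must be > 0", call. = FALSE)
  1 / (2 * pi * capacitance * resistance)
}

#' Cascaded amplifier gain in dB
#'
#' Sum of per-stage dB gains. The three-stage amplifier chain of the sensor
#' (12 dB low-noise stage, 20 dB fixed-gain VGA with AGC disabled, 18 dB
#' output stage) totals 50 dB.
#'
#' @param stages Numeric vector of stage gains in dB (non-empty, finite).
#' @return Total gain in dB.
#' @export
gain_chain_db <- function(stages) {
  if (length(stages) == 0) stop("empty gain chain", call. = FALSE)
  if (any(!is.finite(stages))) stop("gains must be finite", call. = FALSE)
  sum(stages)
}

#' Signal-to-noise ratio in dB
#'
#' `SNR = 10 * log10(P1 / P2)` for signal power `P1` and noise power `P2`.
#'
#' @param p_signal,p_noise Positive powers (same units).
#' @return SNR in dB.
#' @examples
#' snr_db(588.6, 3)    # 22.9 dB
#' snr_db(22.6, 0.16)  # 21.5 dB
#' @export
snr_db <- function(p_signal, p_noise) {
  if (any(p_signal <= 0) || any(p_noise <= 0))
    stop("powers must be > 0", call. = FALSE)
  10 * log10(p_signal / p_noise)
}

#' Consistency difference rates between two sensors
#'
#' Dimensionless difference rates of amplitude and frequency between the
#' outputs of two sensors driven by the same test tone:
#' `delta_V = |V_A - V_B| / V_B` and `delta_f = |f_A - f_B| / f_B`.
#'
#' @param v_a,v_b Amplitudes of sensors A and B (`v_b != 0`).
#' @param f_a,f_b Estimated output frequencies (`f_b != 0`).
#' @return List with `delta_v` and `delta_f`.
#' @export
difference_rates <- function(v_a, v_b, f_a, f_b) {
  if (any(v_b == 0) || any(f_b == 0))
    stop("reference amplitude/frequency must be non-zero", call. = FALSE)
  list(delta_v = abs(v_a - v_b) / abs(v_b),
       delta_f = abs(f_a - f_b) / abs(f_b))
}

#' PSD-based center frequency estimate
#'
#' Welch-averaged power spectral density (Hann window, 2 s segments, 50%
#' overlap by default, mirroring a 40 s bench acquisition), with parabolic
#' sub-bin refinement of the spectral peak.
#'
#' @param x Numeric signal (at least one segment long).
#' @param fs Sampling rate in Hz.
#' @param segment_sec Welch segment length in seconds.
#' @param overlap Fractional segment overlap in `[0, 1)`.
#' @return Estimated center frequency in Hz.
#' @export
estimate_center_frequency <- function(x, fs, segment_sec = 2, overlap = 0.5) {
  if (stats::sd(x) == 0)
    stop("constant signal has no defined spectral peak", call. = FALSE)
  nseg <- min(length(x), round(segment_sec * fs))
  step <- max(1, round(nseg * (1 - overlap)))
  starts <- seq(1, length(x) - nseg + 1, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))  # Hann
  psd <- numeric(floor(nseg / 2) + 1)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    seg <- (seg - mean(seg)) * win
    sp <- abs(stats::fft(seg))^2
    psd <- psd + sp[seq_along(psd)]
  }
  k <- which.max(psd[-1]) + 1  # skip DC bin
  # parabolic interpolation over the log-power of the three bins around k
  delta <- 0
  if (k > 1 && k < length(psd)) {
    p <- log(psd[(k - 1):(k + 1)] + .Machine$double.xmin)
    den <- p[1] - 2 * p[2] + p[3]
    if (den != 0) delta <- 0.5 * (p[1] - p[3]) / den
  }
  (k - 1 + delta) * fs / nseg
}

#' Two-sensor consistency report for one test tone
#'
#' Computes the amplitude (as `sqrt(2) * RMS`, the sinusoid peak estimate)
#' and PSD center frequency of each sensor's output, and their difference
#' rates, for a single tone of the bench sweep.
#'
#' @param a,b Numeric signals from sensors A and B (same tone).
#' @param fs Sampling rate in Hz.
#' @param j Optional nominal test frequency in Hz (carried into the output).
#' @return One-row data frame with columns `j`, `v_a`, `v_b`, `f_a`, `f_b`,
#'   `delta_v`, `delta_f`.
#' @export
consistency_report <- function(a, b, fs, j = NA_real_) {
  amp <- function(x) sqrt(2) * sqrt(mean((x - mean(x))^2))
  v_a <- amp(a); v_b <- amp(b)
  f_a <- estimate_center_frequency(a, fs)
  f_b <- estimate_center_frequency(b, fs)
  dr <- difference_rates(v_a, v_b, f_a, f_b)
  data.frame(j = j, v_a = v_a, v_b = v_b, f_a = f_a, f_b = f_b,
             delta_v = dr$delta_v, delta_f = dr$delta_f)
}
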