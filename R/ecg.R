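# ECG conditioning and Pan-Tompkins R-wave detection. The detector runs at
# the algorithm's native 200 Hz design rate; indices are refined on the
# full-rate trace afterwards.

# linear convolution via FFT
lin_conv <- function(x, f) {
  n <- length(x) + length(f) - 1
  nf <- stats::nextn(n, 2)
  Re(stats::fft(stats::fft(c(x, numeric(nf - length(x)))) *
                stats::fft(c(f, numeric(nf - length(f)))),
                inverse = TRUE))[seq_len(n)] / nf
}

# Rational-ratio polyphase resampling: zero-stuff by p, anti-alias with a
# linear-phase FIR low-pass (delay-compensated, so no phase shift), keep
# every q-th sample. K half-length in output-period units.
resample_fir <- function(x, p, q, K = 10) {
  stopifnot(p >= 1, q >= 1, p == round(p), q == round(q))
  g <- pracma::gcd(p, q)
  p <- p / g; q <- q / g
  if (p == 1 && q == 1) return(x)
  n <- length(x)
  m <- max(p, q)
  ntaps <- 2 * K * m + 1
  f <- signal::fir1(ntaps - 1, 1 / m, type = "low")
  f <- p * f / sum(f)  # exact unit DC gain before the rate change
  # odd-reflection extension keeps the FIR warm-up out of the output;
  # it must cover the filter half-length, measured in input samples
  ext <- min(ceiling((ntaps - 1) / 2 / p), n - 1)
  xe <- if (ext > 0)
    c(2 * x[1] - x[(ext + 1):2], x, 2 * x[n] - x[(n - 1):(n - ext)])
  else x
  up <- numeric(length(xe) * p)
  up[seq(1, length(up), by = p)] <- xe
  y <- lin_conv(up, f)
  delay <- (ntaps - 1) / 2
  y <- y[(delay + ext * p + 1):(delay + ext * p + n * p)]
  y[seq(1, by = q, length.out = ceiling(n * p / q))]
}

#' Condition an ECG trace for R-wave detection
#'
#' Resamples the trace to the 200 Hz detection rate, removes baseline wander
#' and high-frequency noise with a zero-phase Butterworth band-pass
#' (0.5-40 Hz by default, adequate for R-wave timing), then resamples to the
#' common 10 kHz pipeline rate so ECG and PCG share a time base. Duration is
#' preserved to within one sample.
#'
#' @param trace An [ecg_trace()] with `fs >= 400` Hz.
#' @param band Band edges in Hz (length 2).
#' @param order Butterworth order (per pass).
#' @param fs_mid Intermediate detection rate, default 200 Hz.
#' @param fs_out Output rate, default 10 kHz.
#' @return Conditioned [ecg_trace()] at `fs_out`.
#' @export
preprocess_ecg <- function(trace, band = c(0.5, 40), order = 3,
                           fs_mid = 200, fs_out = 10000) {
  stopifnot(inherits(trace, "ecg_trace"))
  if (trace$fs < 2 * fs_mid)
    stop(sprintf("input fs = %g Hz must be at least %g Hz", trace$fs, 2 * fs_mid),
         call. = FALSE)
  if (length(trace$samples) < trace$fs)  # need ~1 s for the filter warm-up
    stop("trace shorter than the filter warm-up (< 1 s)", call. = FALSE)
  x <- resample_fir(trace$samples, fs_mid, trace$fs)
  bf <- signal::butter(order, band / (fs_mid / 2), type = "pass")
  x <- filtfilt_reflect(x, bf$b, bf$a, pad = ceiling(3 * fs_mid / band[1]))
  x <- resample_fir(x, fs_out, fs_mid)
  ecg_trace(x, fs_out)
}

# local maxima of x that exceed thr, separated by at least min_dist samples
find_peaks <- function(x, min_dist) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- logical(n)
  taken <- integer(0)
  for (i in cand) {
    if (!length(taken) || all(abs(taken - i) >= min_dist)) {
      keep[i] <- TRUE
      taken <- c(taken, i)
    }
  }
  sort(which(keep))
}

#' Pan-Tompkins R-wave detection
#'
#' Implements the classic detection stages: 5-15 Hz band-pass, five-point
#' derivative, squaring, 150 ms moving-window integration, and adaptive dual
#' thresholds with a 200 ms refractory period and search-back at half
#' threshold when an expected beat is missed. Detection runs at 200 Hz (the
#' algorithm's design rate); each detection is then refined to the local
#' extremum of the input trace within +/- 40 ms, and indices are returned at
#' the trace's own sampling rate.
#'
#' @param trace A (preferably [preprocess_ecg()]-conditioned) [ecg_trace()].
#' @return Integer vector of R-peak sample indices (possibly empty; a flat or
#'   all-noise trace yields no detections, not an error).
#' @export
detect_r_peaks <- function(trace) {
  stopifnot(inherits(trace, "ecg_trace"))
  fs_d <- 200
  x0 <- trace$samples
  if (length(x0) < fs_d || stats::sd(x0) == 0) return(integer(0))
  x <- if (trace$fs != fs_d) resample_fir(x0, fs_d, trace$fs) else x0

  bf <- signal::butter(3, c(5, 15) / (fs_d / 2), type = "pass")
  xb <- filtfilt_reflect(x, bf$b, bf$a, pad = 3 * fs_d)
  # five-point derivative, squaring, 150 ms moving-window integration
  dx <- as.numeric(stats::filter(xb, c(1, 2, 0, -2, -1) * fs_d / 8, sides = 2))
  dx[is.na(dx)] <- 0
  sq <- dx^2
  w <- round(0.150 * fs_d)
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  mwi[is.na(mwi)] <- 0

  refractory <- round(0.200 * fs_d)
  peaks <- find_peaks(mwi, refractory)
  if (!length(peaks)) return(integer(0))

  # adaptive dual thresholds (signal / noise running estimates)
  init <- mwi[seq_len(min(length(mwi), 2 * fs_d))]
  spki <- max(init) * 0.6
  npki <- mean(init) * 0.5
  thr1 <- npki + 0.25 * (spki - npki)
  accepted <- integer(0)
  rr_hist <- numeric(0)
  last <- -Inf
  for (p in peaks) {
    if (mwi[p] > thr1 && (p - last) >= refractory) {
      spki <- 0.125 * mwi[p] + 0.875 * spki
      if (length(accepted)) rr_hist <- c(rr_hist, p - last)
      accepted <- c(accepted, p)
      last <- p
    } else {
      npki <- 0.125 * mwi[p] + 0.875 * npki
    }
    thr1 <- npki + 0.25 * (spki - npki)
    # search-back: if a beat seems missed, accept the largest candidate
    # above half threshold in the overdue interval
    if (length(rr_hist) >= 2) {
      rr_avg <- mean(utils::tail(rr_hist, 8))
      if ((p - last) > 1.66 * rr_avg) {
        win <- peaks[peaks > last + refractory & peaks < p]
        win <- win[mwi[win] > 0.5 * thr1]
        if (length(win)) {
          pb <- win[which.max(mwi[win])]
          spki <- 0.25 * mwi[pb] + 0.75 * spki
          accepted <- sort(c(accepted, pb))
          rr_hist <- c(rr_hist, pb - last)
          last <- max(accepted)
        }
      }
    }
  }
  if (!length(accepted)) return(integer(0))

  # refine on the full-rate trace: local |max| within +/- 40 ms
  scale <- trace$fs / fs_d
  half <- round(0.040 * trace$fs)
  idx <- vapply(accepted, function(p) {
    c0 <- round((p - 1) * scale) + 1
    lo <- max(1, c0 - half); hi <- min(length(x0), c0 + half)
    as.integer(lo + which.max(abs(x0[lo:hi])) - 1L)
  }, integer(1))
  idx <- sort(unique(idx))
  # enforce refractory at full rate (dedup after refinement)
  if (length(idx) > 1) {
    keep <- c(TRUE, diff(idx) >= round(0.2 * trace$fs))
    idx <- idx[keep]
  }
  as.integer(idx)
}

#' Segment a trace into consecutive cardiac cycles
#'
#' Builds half-open R-to-R intervals `[r_k, r_{k+1})` from sorted R-peak
#' indices; partial leading/trailing segments are excluded.
#'
#' @param r_peaks Sorted R-peak sample indices.
#' @param n_samples Optional trace length; peaks beyond it are dropped.
#' @return List of length-2 integer vectors `c(start, end)` (end exclusive);
#'   empty when fewer than two peaks are available.
#' @export
segment_cycles <- function(r_peaks, n_samples = NULL) {
  r_peaks <- as.integer(r_peaks)
  if (is.unsorted(r_peaks, strictly = TRUE))
    stop("`r_peaks` must be strictly increasing", call. = FALSE)
  if (!is.null(n_samples)) r_peaks <- r_peaks[r_peaks <= n_samples]
  if (length(r_peaks) < 2) return(list())
  lapply(seq_len(length(r_peaks) - 1),
         function(k) c(r_peaks[k], r_peaks[k + 1]))
}
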