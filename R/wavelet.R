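# Orthogonal discrete wavelet transform with periodized boundary handling,
# plus universal-threshold shrinkage. Implemented in-package: the denoising
# chain needs only the coiflet-5 analysis/synthesis pair, soft thresholding
# and exact reconstruction, all of which follow from the standard orthogonal
# filter-bank recursion.

# Coiflet-5 scaling (low-pass decomposition) filter, 30 taps. These are the
# standard published coefficients (sum = sqrt(2), unit energy).
COIF5_DEC_LO <- c(
  -9.604010112767894e-08, -1.6237995172048338e-07,  2.0612203985788783e-06,
   3.7007277113394796e-06, -2.1270221672515614e-05, -4.1219861924265500e-05,
   1.4035632812373243e-04,  3.0185794166824480e-04, -6.3755892612588120e-04,
  -1.6616273039298788e-03,  2.4315754425382886e-03,  6.7615202206204170e-03,
  -9.1595073386761630e-03, -1.9758391600965465e-02,  3.2674799467057355e-02,
   4.1287530472117834e-02, -1.0556315130733723e-01, -6.2037751574981960e-02,
   4.3798230665916340e-01,  7.7429362286032740e-01,  4.2157126673075435e-01,
  -5.2046670253554764e-02, -9.1921588060086090e-02,  2.8169744270532353e-02,
   2.3408322118927783e-02, -1.0131584846900276e-02, -4.1593126275786400e-03,
   2.1782943778456947e-03,  3.5857774116175770e-04, -2.1208186206749400e-04)

#' Wavelet filter pair
#'
#' Returns the orthogonal low-pass/high-pass decomposition filter pair for a
#' named mother wavelet. The high-pass filter is the quadrature mirror of the
#' low-pass one: `g[n] = (-1)^n h[L - 1 - n]`.
#'
#' @param mother Wavelet name; `"coif5"` (the denoising default) or `"haar"`.
#' @return List with numeric vectors `lo` and `hi`.
#' @export
wavelet_filters <- function(mother = "coif5") {
  lo <- switch(mother,
               coif5 = COIF5_DEC_LO,
               haar  = c(1, 1) / sqrt(2),
               stop(sprintf("unsupported mother wavelet '%s'", mother),
                    call. = FALSE))
  L <- length(lo)
  hi <- rev(lo) * rep_len(c(1, -1), L)
  list(lo = lo, hi = hi)
}

# circular convolution / correlation via FFT; f shorter than x
circ_conv <- function(x, f) {
  N <- length(x)
  fp <- numeric(N); fp[seq_along(f)] <- f
  Re(stats::fft(stats::fft(x) * stats::fft(fp), inverse = TRUE)) / N
}
circ_corr <- function(x, f) {
  N <- length(x)
  fp <- numeric(N); fp[seq_along(f)] <- f
  Re(stats::fft(stats::fft(x) * Conj(stats::fft(fp)), inverse = TRUE)) / N
}

# one analysis level: a[k] = sum_m lo[m] x[(2k + m) mod N] (inner products
# with even circular translates of the filters)
dwt_step <- function(x, filt) {
  list(a = circ_corr(x, filt$lo)[seq(1, length(x), by = 2)],
       d = circ_corr(x, filt$hi)[seq(1, length(x), by = 2)])
}

idwt_step <- function(a, d, filt) {
  N <- 2 * length(a)
  ua <- numeric(N); ua[seq(1, N, by = 2)] <- a
  ud <- numeric(N); ud[seq(1, N, by = 2)] <- d
  circ_conv(ua, filt$lo) + circ_conv(ud, filt$hi)
}

#' Multilevel periodized wavelet decomposition
#'
#' Decomposes a signal into `level` detail bands plus a final approximation
#' using the orthogonal filter bank of the chosen mother wavelet with
#' periodized (circular) boundary handling, so that
#' [wavelet_reconstruct()] inverts it exactly. The signal length must be a
#' multiple of `2^level`, and the coarsest level must still be at least as
#' long as the filter (30 taps for coif5); [wavelet_denoise()] takes care of
#' the necessary padding.
#'
#' @param x Numeric signal whose length is a multiple of `2^level`.
#' @param mother Mother wavelet name (see [wavelet_filters()]).
#' @param level Number of decomposition levels (>= 1).
#' @return List with `approx` (coarsest approximation), `details` (list of
#'   detail coefficient vectors, level 1 = finest first), `mother`, `level`,
#'   and `n` (input length).
#' @export
wavelet_decompose <- function(x, mother = "coif5", level = 7) {
  if (level < 1 || level != round(level)) stop("`level` must be >= 1", call. = FALSE)
  filt <- wavelet_filters(mother)
  n <- length(x)
  if (n %% 2^level != 0)
    stop(sprintf("signal length %d is not a multiple of 2^%d", n, level),
         call. = FALSE)
  if (n / 2^level < length(filt$lo))
    stop(sprintf(paste0("signal too short: the level-%d band has %d samples, ",
                        "fewer than the %d-tap filter"),
                 level, n / 2^level, length(filt$lo)), call. = FALSE)
  a <- x
  details <- vector("list", level)
  for (k in seq_len(level)) {
    s <- dwt_step(a, filt)
    details[[k]] <- s$d
    a <- s$a
  }
  list(approx = a, details = details, mother = mother, level = level, n = n)
}

#' @rdname wavelet_decompose
#' @param w A decomposition produced by [wavelet_decompose()] (detail
#'   coefficients may have been modified in place, e.g. thresholded).
#' @export
wavelet_reconstruct <- function(w) {
  filt <- wavelet_filters(w$mother)
  a <- w$approx
  for (k in rev(seq_len(w$level))) a <- idwt_step(a, w$details[[k]], filt)
  a
}

#' Soft / hard threshold shrinkage
#'
#' Soft thresholding sets coefficients with `|x| < t` to zero and shrinks the
#' remainder toward zero by `t`; hard thresholding only zeroes.
#'
#' @param x Numeric vector of coefficients.
#' @param t Non-negative threshold.
#' @param rule `"soft"` (default) or `"hard"`.
#' @return Thresholded vector.
#' @export
threshold_shrink <- function(x, t, rule = c("soft", "hard")) {
  rule <- match.arg(rule)
  if (t < 0) stop("`t` must be >= 0", call. = FALSE)
  if (rule == "soft") sign(x) * pmax(abs(x) - t, 0) else x * (abs(x) >= t)
}

#' Wavelet denoising specification
#'
#' Parameters of the wavelet shrinkage stage. Defaults mirror the processing
#' chain the package implements: coiflet-5 mother wavelet, 7 decomposition
#' levels, the fixed "sqtwolog" (universal) threshold
#' `T = sigma * sqrt(2 * log(N))`, and soft shrinkage.
#'
#' @param mother Mother wavelet name.
#' @param level Decomposition depth (>= 1).
#' @param threshold_rule Currently `"sqtwolog"`.
#' @param shrinkage `"soft"` or `"hard"`.
#' @param sigma Noise-scale multiplier for the threshold: `"mad"` (default)
#'   estimates `sigma = median(|d1|) / 0.6745` from the finest detail band
#'   per channel (the usual companion of the universal threshold), or a fixed
#'   numeric value (`1` gives the bare `sqrt(2 log N)` threshold).
#' @return An object of class `wavelet_spec`.
#' @export
wavelet_spec <- function(mother = "coif5", level = 7,
                         threshold_rule = "sqtwolog",
                         shrinkage = c("soft", "hard"), sigma = "mad") {
  shrinkage <- match.arg(shrinkage)
  if (level < 1) stop("`level` must be >= 1", call. = FALSE)
  if (!identical(threshold_rule, "sqtwolog"))
    stop("only the 'sqtwolog' threshold rule is implemented", call. = FALSE)
  if (!(identical(sigma, "mad") || (is.numeric(sigma) && sigma >= 0)))
    stop("`sigma` must be \"mad\" or a non-negative number", call. = FALSE)
  structure(list(mother = mother, level = level,
                 threshold_rule = threshold_rule, shrinkage = shrinkage,
                 sigma = sigma), class = "wavelet_spec")
}

# reflect-pad x at the end to length m (symmetric, half-point)
reflect_pad_to <- function(x, m) {
  n <- length(x)
  if (m == n) return(x)
  extra <- m - n
  pad <- numeric(0)
  while (length(pad) < extra) pad <- c(pad, rev(x), x)
  c(x, pad[seq_len(extra)])
}

#' Wavelet denoising of a multichannel recording
#'
#' Per channel: decompose to `spec$level` levels with the chosen mother
#' wavelet, shrink every detail band with the universal threshold
#' `T = sigma_hat * sqrt(2 * log(N))` (`N` the channel length), reconstruct.
#' The channel is symmetrically reflect-padded to a multiple of `2^level`
#' before the periodized transform and trimmed back afterwards, so the output
#' has the input length.
#'
#' @param rec A [pcg_recording()].
#' @param spec A [wavelet_spec()].
#' @return The denoised [pcg_recording()].
#' @export
wavelet_denoise <- function(rec, spec = wavelet_spec()) {
  stopifnot(inherits(rec, "pcg_recording"), inherits(spec, "wavelet_spec"))
  n <- ncol(rec$data)
  block <- 2^spec$level
  m <- ceiling(n / block) * block
  flt_len <- length(wavelet_filters(spec$mother)$lo)
  if (m / block < flt_len)
    stop("signal shorter than the filter support at the deepest level",
         call. = FALSE)
  out <- rec$data
  for (i in seq_len(nrow(out))) {
    x <- reflect_pad_to(rec$data[i, ], m)
    w <- wavelet_decompose(x, spec$mother, spec$level)
    sig <- if (identical(spec$sigma, "mad"))
      stats::median(abs(w$details[[1]])) / 0.6745 else spec$sigma
    thr <- sig * sqrt(2 * log(n))
    w$details <- lapply(w$details, threshold_shrink, t = thr,
                        rule = spec$shrinkage)
    out[i, ] <- wavelet_reconstruct(w)[seq_len(n)]
  }
  pcg_recording(out, rec$fs, rec$channel_ids)
}
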