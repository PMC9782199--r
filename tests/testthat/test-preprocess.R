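test_that("ensemble normalization uses the global range and channel means", {
  r <- pcg_recording(rbind(c(0, 1), c(1, 3)), fs = 10)
  nz <- normalize_channels(r)
  expect_equal(nz$stats$d_max, 3)
  expect_equal(nz$stats$d_min, 0)
  expect_equal(unname(nz$stats$means), c(0.5, 2))
  expect_equal(unname(nz$rec$data),
               rbind(c(-1 / 6, 1 / 6), c(-1 / 3, 1 / 3)))
})

test_that("normalization always yields zero-mean channels", {
  set.seed(21)
  for (rep in 1:3) {
    r <- pcg_recording(matrix(rnorm(5 * 100, mean = rnorm(1)), 5), fs = 100)
    out <- normalize_channels(r)$rec
    expect_lt(max(abs(rowMeans(out$data))), 1e-12)
  }
})

test_that("constant ensembles are rejected as degenerate", {
  expect_error(normalize_channels(pcg_recording(matrix(2, 1, 50), 10)),
               "degenerate")
})

test_that("zero-phase band-pass removes DC and passes mid-band with no lag", {
  fs <- 10000
  n <- 2 * fs
  dc <- pcg_recording(matrix(1, 1, n), fs)
  ydc <- bandpass_zero_phase(dc)$data[1, ]
  expect_lt(max(abs(ydc[2000:(n - 2000)])), 1e-6)

  t <- (seq_len(n) - 1) / fs
  x <- sin(2 * pi * 100 * t)
  y <- bandpass_zero_phase(pcg_recording(x, fs))$data[1, ]
  mid <- 5000:15000
  expect_equal(max(abs(y[mid])), 1, tolerance = 0.01)
  cc <- ccf(x[mid], y[mid], lag.max = 25, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("stop-band attenuation doubles the single-pass response in dB", {
  fs <- 10000
  spec <- bandpass_spec(20, 200, 4)
  bf <- signal::butter(spec$order, c(20, 200) / (fs / 2), type = "pass")
  # single-pass magnitude from the transfer function evaluated on the unit
  # circle at 500 Hz (independent of the filtering code path)
  z <- exp(-1i * 2 * pi * 500 / fs)
  h1 <- abs(sum(bf$b * z^(seq_along(bf$b) - 1)) /
            sum(bf$a * z^(seq_along(bf$a) - 1)))
  single_pass_db <- 20 * log10(h1)

  n <- 4 * fs
  t <- (seq_len(n) - 1) / fs
  x <- sin(2 * pi * 500 * t)
  y <- bandpass_zero_phase(pcg_recording(x, fs), spec)$data[1, ]
  amp <- max(abs(y[10000:30000]))
  expect_equal(20 * log10(amp), 2 * single_pass_db, tolerance = 0.5)
})

test_that("band edges above Nyquist are rejected", {
  expect_error(bandpass_zero_phase(pcg_recording(rnorm(100), 300),
                                   bandpass_spec(20, 200)), "Nyquist")
})

test_that("detail bands follow the dyadic halving rule and tile the spectrum", {
  b <- detail_band_edges(10000, 8)
  expect_equal(b$low_hz[1], 2500)
  expect_equal(b$high_hz[1], 5000)
  expect_equal(b$low_hz[7], 39.0625)
  expect_equal(b$high_hz[7], 78.125)
  f <- 700
  b1 <- detail_band_edges(2 * f, 1)
  expect_equal(c(b1$low_hz, b1$high_hz), c(f / 2, f))
  # bands tile (fs/2^(L+1), fs/2) without gaps or overlaps
  expect_equal(b$low_hz[-nrow(b)], b$high_hz[-1])
})

test_that("the full conditioning chain preserves shape and channel order", {
  lay <- generate_sensor_layout(2, 2, 30)
  rec <- generate_pcg_array(lay, make_schedule(3), list(make_source(lay)),
                            fs = 4000, noise_sd = 0.02, seed = 5, duration = 4)
  out <- preprocess_pcg(rec, bandpass_spec(20, 200, 4), wavelet_spec(level = 5))
  expect_equal(dim(out$rec$data), dim(rec$data))
  expect_identical(out$rec$channel_ids, rec$channel_ids)
  expect_gt(out$stats$d_max, out$stats$d_min)
})
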