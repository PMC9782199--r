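test_that("sensor layout grids have the expected geometry", {
  # degenerate single sensor
  single <- generate_sensor_layout(1, 1, 10, c(0, 0))
  expect_equal(unname(single$coords), matrix(c(0, 0), 1, 2))

  # 2x2 grid is fully determined
  g22 <- generate_sensor_layout(2, 2, 10, c(0, 0))
  expect_setequal(split(unname(g22$coords), seq_len(4)),
                  list(c(0, 0), c(10, 0), c(0, 10), c(10, 10)))

  # 72-sensor grid: count and minimum pairwise spacing by direct enumeration
  g <- generate_sensor_layout(8, 9, 40, c(100, 100))
  expect_equal(nrow(g$coords), 72)
  expect_equal(min(dist(g$coords)), 40)

  expect_error(generate_sensor_layout(0, 3, 10), "positive integers")
  expect_error(generate_sensor_layout(2, 2, -1), "spacing")
})

test_that("pcg generator is deterministic and spatially monotone", {
  lay <- generate_sensor_layout(3, 4, 30, c(50, 50))
  sch <- make_schedule(2)
  src <- list(source_spec(lay$coords[6, ], decay_length = 60))

  r1 <- generate_pcg_array(lay, sch, src, fs = 2000, noise_sd = 0.05, seed = 42,
                           duration = 2)
  r2 <- generate_pcg_array(lay, sch, src, fs = 2000, noise_sd = 0.05, seed = 42,
                           duration = 2)
  expect_identical(r1$data, r2$data)

  # noise-free: channel co-located with the source has the largest peak, and
  # peak amplitude is non-increasing in distance to the source
  r0 <- generate_pcg_array(lay, sch, src, fs = 2000, noise_sd = 0, seed = 1,
                           duration = 2)
  peaks <- apply(abs(r0$data), 1, max)
  expect_equal(which.max(peaks), 6)
  d <- sqrt(rowSums(sweep(lay$coords, 2, lay$coords[6, ])^2))
  expect_true(all(diff(peaks[order(d)]) <= 1e-12))
})

test_that("infinite decay length yields identical channels", {
  lay <- generate_sensor_layout(2, 3, 25)
  sch <- make_schedule(2)
  src <- list(source_spec(c(0, 0), decay_length = 1e12))
  r <- generate_pcg_array(lay, sch, src, fs = 2000, noise_sd = 0, duration = 2)
  for (i in 2:nrow(r$data))
    expect_equal(r$data[i, ], r$data[1, ], tolerance = 1e-9)
})

test_that("pcg generator rejects bad inputs", {
  lay <- generate_sensor_layout(2, 2, 10)
  sch <- make_schedule(1)
  expect_error(generate_pcg_array(lay, sch, list()), "non-empty")
  expect_error(generate_pcg_array(lay, sch, list(source_spec(c(0, 0),
                                                             center_freq = 90)),
                                  fs = 100), "Nyquist")
})

test_that("S1 bursts are phase-locked to the beat schedule", {
  lay <- generate_sensor_layout(1, 1, 10)
  sch <- beat_schedule(c(0.5, 1.5), s1_delay = 0.04, s2_delay = 0.31)
  src <- list(source_spec(c(0, 0), component = "s1"))
  r <- generate_pcg_array(lay, sch, src, fs = 2000, noise_sd = 0, duration = 2.2)
  t_peak <- (which.max(abs(r$data[1, 1:2000])) - 1) / r$fs
  expect_equal(t_peak, 0.5 + 0.04, tolerance = 1e-3)
})

test_that("synthetic ECG carries ground-truth R indices", {
  sch <- make_schedule(10, start = 1)
  e <- generate_ecg(sch, fs = 1000, noise_sd = 0)
  expect_equal(e$r_peaks, round(sch$beat_times * 1000) + 1)
  # the R spike dominates the noise-free trace
  expect_true(which.max(e$samples) %in% e$r_peaks)

  # different seeds change the noise but not the ground truth
  e1 <- generate_ecg(sch, fs = 500, noise_sd = 0.05, seed = 1)
  e2 <- generate_ecg(sch, fs = 500, noise_sd = 0.05, seed = 2)
  expect_false(isTRUE(all.equal(e1$samples, e2$samples)))
  expect_identical(e1$r_peaks, e2$r_peaks)

  # empty schedule: empty trace, not an error
  empty <- generate_ecg(beat_schedule(numeric(0)), fs = 100)
  expect_length(empty$samples, 0)
  expect_length(empty$r_peaks, 0)
})

test_that("marker images render discs inside bounds only", {
  blank <- render_marker_image(40, 30)
  expect_equal(dim(blank), c(30, 40, 3))
  expect_equal(length(unique(as.vector(blank))), 1)

  img <- render_marker_image(60, 60, list(
    list(center = c(30, 30), radius = 5, color = "green")))
  expect_false(all(img == img[1, 1, 1]))

  expect_error(render_marker_image(60, 60, list(
    list(center = c(2, 30), radius = 5, color = "red"))), "outside")
  expect_error(render_marker_image(60, 60, list(
    list(center = c(30, 30), radius = 5, color = "teal"))), "unknown")
})
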