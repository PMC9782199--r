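test_that("modulus is the element-wise absolute value", {
  r <- pcg_recording(matrix(c(-0.5, 0, 0.25), 1), fs = 10)
  expect_equal(compute_modulus(r)$data[1, ], c(0.5, 0, 0.25))
  set.seed(2)
  r2 <- pcg_recording(matrix(rnorm(60), 3), fs = 10)
  neg <- r2; neg$data <- -neg$data
  expect_equal(compute_modulus(neg)$data, compute_modulus(r2)$data)
})

test_that("frame interpolation is exact at nodes and reproduces planes", {
  lay <- make_grid72()
  plane <- 2 + 0.01 * lay$coords[, 1] - 0.003 * lay$coords[, 2]
  for (method in c("tps", "bicubic")) {
    fr <- interpolate_frame(lay, plane, grid_step = 4, method = method)
    expect_lt(max(abs(fr$predict(lay$coords) - plane)), 1e-9)
    gg <- expand.grid(x = fr$x, y = fr$y)
    want <- matrix(2 + 0.01 * gg$x - 0.003 * gg$y,
                   nrow = length(fr$y), byrow = TRUE)
    expect_lt(max(abs(fr$values - want)[fr$mask]), 1e-6)
    expect_true(all(is.na(fr$values[!fr$mask])))
  }
})

test_that("constant fields interpolate to the constant inside the hull", {
  lay <- sensor_layout(rbind(c(0, 0), c(10, 1), c(4, 9), c(7, 5)))
  fr <- interpolate_frame(lay, rep(3, 4), grid_step = 1)
  expect_equal(range(fr$values[fr$mask]), c(3, 3), tolerance = 1e-9)
})

test_that("degenerate layouts are rejected", {
  line <- sensor_layout(cbind(1:5, 2 * (1:5)))
  expect_error(interpolate_frame(line, rnorm(5)), "collinear")
  lay <- make_grid72()
  expect_error(interpolate_frame(lay, 1:3), "one value per sensor")
  scattered <- sensor_layout(rbind(c(0, 0), c(9, 2), c(4, 8), c(1, 6)))
  expect_error(interpolate_frame(scattered, rep(1, 4), method = "bicubic"),
               "grid")
})

test_that("frames are invariant to consistent channel permutations", {
  lay <- make_grid72()
  set.seed(5)
  e <- runif(72)
  p <- sample(72)
  fr1 <- interpolate_frame(lay, e, grid_step = 8)
  fr2 <- interpolate_frame(sensor_layout(lay$coords[p, ]), e[p], grid_step = 8)
  expect_equal(fr1$values, fr2$values, tolerance = 1e-8)
})

test_that("the hue map runs linearly from blue at zero to red at Em", {
  spec <- colormap_spec(em = 2)
  expect_equal(modulus_to_hue(0, spec), 240)
  expect_equal(modulus_to_hue(2, spec), 0)
  expect_equal(modulus_to_hue(1, spec), 120)
  # overshoot clipping
  expect_equal(modulus_to_hue(3, spec), 0)
  expect_equal(modulus_to_hue(-0.1, spec), 240)
  expect_error(modulus_to_hue(1, colormap_spec(em = NULL)), "positive")
  # monotone: higher modulus, lower (or equal) hue
  x <- sort(runif(50, 0, 2.5))
  expect_true(all(diff(modulus_to_hue(x, spec)) <= 0))
})

test_that("HSL to RGB matches the canonical primary colors", {
  expect_equal(as.numeric(hsl_to_rgb(0, 1, 0.5)), c(255, 0, 0))
  expect_equal(as.numeric(hsl_to_rgb(120, 1, 0.5)), c(0, 255, 0))
  expect_equal(as.numeric(hsl_to_rgb(240, 1, 0.5)), c(0, 0, 255))
  expect_equal(as.numeric(hsl_to_rgb(0, 0, 0.5)), c(128, 128, 128))
  expect_error(hsl_to_rgb(400), "hue")
  expect_error(hsl_to_rgb(10, 2, 0.5), "saturation")
})

test_that("frame sequences have the window-arithmetic frame count", {
  lay <- generate_sensor_layout(3, 3, 30, c(20, 20))
  rec <- generate_pcg_array(lay, beat_schedule(0.2), list(make_source(lay)),
                            fs = 2000, noise_sd = 0, duration = 0.6)
  bg <- array(0.9, dim = c(140, 140, 3))
  out <- render_sequence(rec, lay, bg, 0.204, 0.228, 0.002, grid_step = 2)
  expect_length(out$frames, 13)
  expect_equal(out$times[1], 0.204)
  # one frame per sample at frame_interval = 1/fs
  out1 <- render_sequence(rec, lay, bg, 0.2, 0.2 + 9 / 2000, 1 / 2000,
                          grid_step = 4)
  expect_length(out1$frames, 10)
  expect_error(render_sequence(rec, lay, bg, 0.3, 0.2, 0.002), "empty")
  expect_error(render_sequence(rec, lay, bg, 0.1, 5, 0.1), "outside")
})

test_that("global Em keeps colors comparable across frames", {
  lay <- generate_sensor_layout(3, 3, 30, c(20, 20))
  rec <- generate_pcg_array(lay, beat_schedule(0.2), list(make_source(lay)),
                            fs = 2000, noise_sd = 0, duration = 0.6)
  bg <- array(0.9, dim = c(140, 140, 3))
  out <- render_sequence(rec, lay, bg, 0.2, 0.22, 0.002, grid_step = 2)
  expect_true(all(out$em == out$em[1]))
  expect_gt(out$em[1], 0)
})

test_that("the rendered S1 frame peaks near the configured source", {
  lay <- make_grid72()
  sch <- beat_schedule(0.3)
  src <- make_source(lay)
  rec <- generate_pcg_array(lay, sch, list(src), fs = 4000, noise_sd = 0.005,
                            seed = 9, duration = 0.8)
  cond <- preprocess_pcg(rec, wavelet = NULL)$rec
  # burst-center sample: maximal ensemble energy near the scheduled S1 time
  n0 <- round((sch$beat_times[1] + sch$s1_delay) * rec$fs) + 1
  win <- (n0 - 100):(n0 + 100)
  idx <- win[which.max(colSums(abs(cond$data[, win])))]
  fr <- interpolate_frame(lay, abs(cond$data[, idx]), grid_step = 2)
  pk <- which(fr$values == max(fr$values, na.rm = TRUE), arr.ind = TRUE)[1, ]
  peak_xy <- c(fr$x[pk[2]], fr$y[pk[1]])
  expect_lt(sqrt(sum((peak_xy - src$position)^2)), 40)  # one sensor spacing
})
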