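test_that("marker extraction recovers disc centers to sub-pixel accuracy", {
  blank <- render_marker_image(80, 60)
  expect_equal(nrow(extract_markers(blank, color_spec_preset("red-disc"))), 0)

  centers <- rbind(c(40, 40), c(150, 45), c(60, 120), c(170, 115))
  discs <- lapply(seq_len(4), function(i)
    list(center = centers[i, ], radius = 8, color = "red"))
  img <- render_marker_image(220, 160, discs)
  found <- extract_markers(img, color_spec_preset("red-disc"))
  expect_equal(nrow(found), 4)
  for (i in seq_len(4)) {
    d <- sqrt(rowSums(sweep(found, 2, centers[i, ])^2))
    expect_lt(min(d), 1)
  }
})

test_that("color selection separates green sensors from red landmarks", {
  lay <- generate_sensor_layout(8, 9, 30, c(60, 60))
  sens <- lapply(seq_len(72), function(i)
    list(center = lay$coords[i, ], radius = 6, color = "green"))
  lm <- lapply(list(c(200, 20), c(120, 340), c(25, 200), c(375, 200)),
               function(p) list(center = p, radius = 9, color = "red"))
  img <- render_marker_image(400, 360, c(sens, lm))
  greens <- extract_markers(img, color_spec_preset("green-disc"))
  reds <- extract_markers(img, color_spec_preset("red-disc"))
  expect_equal(nrow(greens), 72)
  expect_equal(nrow(reds), 4)
  # no cross-color contamination: every green center is near a true sensor
  dmin <- apply(greens, 1, function(p)
    min(sqrt(rowSums(sweep(lay$coords, 2, p)^2))))
  expect_lt(max(dmin), 1)
})

test_that("transform estimation recovers identity, scale, and rotation", {
  pts <- rbind(c(100, 20), c(90, 200), c(40, 120), c(160, 120))
  chest <- landmark_set(pts, "chest")

  ident <- estimate_transform(chest, landmark_set(pts, "skeleton"))
  expect_equal(ident$theta2 - ident$theta1, 0)
  expect_equal(ident$eta_x, 1)
  expect_equal(ident$eta_y, 1)
  expect_equal(ident$phi_x, 0)
  expect_equal(ident$phi_y, 0)

  sc <- estimate_transform(chest, landmark_set(pts * 2, "skeleton"))
  expect_equal(sc$eta_x, 2)
  expect_equal(sc$eta_y, 2)
  expect_equal(sc$theta2 - sc$theta1, 0)

  th <- 10 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  moved <- sweep(pts %*% t(R), 2, c(30, -20), `+`)
  tr <- estimate_transform(chest, landmark_set(moved, "skeleton"))
  expect_equal(tr$theta2 - tr$theta1, th, tolerance = 1e-9)
  got <- transform_points(pts, tr)
  expect_lt(max(abs(got - moved)), 1e-6)
})

test_that("degenerate landmark geometry is rejected", {
  pts <- rbind(c(100, 20), c(90, 200), c(40, 120), c(160, 120))
  bad <- pts; bad[4, ] <- bad[3, ]
  expect_error(landmark_set(bad), "coincide")
  expect_error(estimate_transform(landmark_set(pts),
                                  landmark_set(rbind(c(100, 20), c(90, 200),
                                                     c(40, 120), c(40, 121)),
                                               "skeleton")),
               "scale")
})

test_that("a known similarity round-trips 72 grid points within 0.5 px", {
  lay <- make_grid72()
  pts <- rbind(c(280, 40), c(180, 460), c(60, 280), c(500, 280))
  th <- 7 * pi / 180
  A <- 1.25 * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  fwd <- function(p) sweep(as.matrix(p) %*% t(A), 2, c(40, -25), `+`)
  tr <- estimate_transform(landmark_set(pts), landmark_set(fwd(pts), "skeleton"))
  got <- transform_points(lay$coords, tr)
  expect_lt(max(abs(got - fwd(lay$coords))), 0.5)
})

test_that("consistent-mode transforms are exactly invertible", {
  pts <- rbind(c(100, 20), c(90, 200), c(40, 120), c(160, 120))
  moved <- sweep(pts %*% t(1.4 * pcgmap:::rot2(0.2)), 2, c(-15, 60), `+`)
  tr <- estimate_transform(landmark_set(pts), landmark_set(moved, "skeleton"))
  inv <- invert_transform(tr)
  set.seed(31)
  q <- matrix(runif(40, 0, 300), ncol = 2)
  expect_lt(max(abs(inv(transform_points(q, tr)) - q)), 1e-9)
})

test_that("literal mode evaluates its transcribed arithmetic exactly", {
  # equal angles: w' = w cos^2(theta), h' = h sin^2(theta)
  pts <- rbind(c(100, 20), c(90, 200), c(40, 120), c(160, 150))
  tr <- estimate_transform(landmark_set(pts), landmark_set(pts, "skeleton"),
                           mode = "literal")
  expect_equal(tr$theta1, tr$theta2)
  p <- c(7, 11)
  got <- pcgmap:::rotate_stage(matrix(p, 1), tr)
  expect_equal(as.numeric(got),
               c(7 * cos(tr$theta1)^2, 11 * sin(tr$theta1)^2))
  # ... which is not the identity even for identical landmark sets
  expect_false(isTRUE(all.equal(as.numeric(got), p)))
  expect_error(transform_affine(tr), "consistent")
})

test_that("end-to-end channel location lands within 1 px per channel", {
  lay <- make_grid72()
  pair <- synthetic_registration_pair(lay)
  reg <- locate_channels(pair$chest, pair$skeleton)
  expect_equal(nrow(reg$coords), 72)
  err <- sqrt(rowSums((reg$coords - pair$skeleton_coords)^2))
  expect_lt(max(err), 1)
  # row-major channel-id convention: ids follow y-then-x order
  expect_equal(order(reg$coords[, 2], reg$coords[, 1]) ,
               seq_len(72), tolerance = 0)
})

test_that("missing landmarks produce named diagnostics", {
  lay <- generate_sensor_layout(2, 2, 40, c(80, 80))
  pair <- synthetic_registration_pair(lay)
  # skeleton image without landmarks
  blank <- render_marker_image(dim(pair$skeleton)[2], dim(pair$skeleton)[1])
  expect_error(locate_channels(pair$chest, blank), "skeleton image.*found 0")
  expect_error(locate_channels(blank, pair$skeleton), "chest photo")
})

test_that("registration degrades gracefully under landmark jitter", {
  lay <- make_grid72()
  pts <- rbind(c(280, 40), c(180, 460), c(60, 280), c(500, 280))
  fwd <- function(p) sweep(as.matrix(p) %*% t(1.2 * pcgmap:::rot2(0.1)),
                           2, c(10, 5), `+`)
  set.seed(17)
  jit <- matrix(runif(8, -1, 1), ncol = 2)
  tr <- estimate_transform(landmark_set(pts + jit),
                           landmark_set(fwd(pts), "skeleton"))
  err <- sqrt(rowSums((transform_points(lay$coords, tr) - fwd(lay$coords))^2))
  expect_lt(max(err), 4.5)  # half the 9 px landmark disc radius
})
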