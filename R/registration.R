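# Colored-marker extraction (HSV threshold + circle Hough) and the
# landmark-based rotate/scale/translate chain that maps sensor positions
# from the chest photograph into skeleton-image coordinates.

#' Color specification for marker extraction
#'
#' HSV thresholds selecting one marker color, plus the circle radius range
#' for the Hough stage. The hue window may wrap across 0 degrees (as the red
#' preset does).
#'
#' @param hue Length-2 hue window in degrees, `[0, 360)`; `hue[1] > hue[2]`
#'   denotes a window wrapping through 0.
#' @param s_min,v_min Saturation and value floors in `[0, 1]`.
#' @param radius Length-2 circle radius range in pixels.
#' @return An object of class `color_spec`.
#' @export
color_spec <- function(hue, s_min = 0.35, v_min = 0.25, radius = c(4, 15)) {
  if (length(hue) != 2 || any(hue < 0) || any(hue >= 360))
    stop("`hue` must be two degrees values in [0, 360)", call. = FALSE)
  if (any(radius <= 0) || radius[2] < radius[1])
    stop("`radius` must be a positive increasing range", call. = FALSE)
  structure(list(hue = hue, s_min = s_min, v_min = v_min,
                 radius = radius), class = "color_spec")
}

#' @rdname color_spec
#' @param preset `"green-disc"` or `"red-disc"`.
#' @export
color_spec_preset <- function(preset = c("green-disc", "red-disc")) {
  preset <- match.arg(preset)
  switch(preset,
         "green-disc" = color_spec(hue = c(70, 170)),
         "red-disc"   = color_spec(hue = c(335, 25)))
}

# binary mask of pixels matching the color spec
hsv_mask <- function(image, spec) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] >= 3)
  h <- dim(image)[1]; w <- dim(image)[2]
  rgb <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
               as.vector(image[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  hue <- hsv[1, ] * 360
  in_hue <- if (spec$hue[1] <= spec$hue[2])
    hue >= spec$hue[1] & hue <= spec$hue[2]
  else hue >= spec$hue[1] | hue <= spec$hue[2]
  m <- in_hue & hsv[2, ] >= spec$s_min & hsv[3, ] >= spec$v_min
  matrix(m, nrow = h, ncol = w)
}

# Circle Hough transform on a binary mask. Edge pixels vote for candidate
# centers along circles of each radius; per-radius accumulators are
# normalized by the vote count a perfect circle would produce, and the best
# radius per center is kept. Centers are then refined to the centroid of the
# mask pixels inside the accepted circle (sub-pixel).
hough_circles <- function(mask, radii, score_min = 0.5) {
  h <- nrow(mask); w <- ncol(mask)
  if (!any(mask)) return(matrix(numeric(0), ncol = 2,
                                dimnames = list(NULL, c("x", "y"))))
  # edge pixels: mask pixels with at least one 4-neighbour outside the mask
  pad <- matrix(FALSE, h + 2, w + 2); pad[2:(h + 1), 2:(w + 1)] <- mask
  interior <- pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
              pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  edge <- which(mask & !interior, arr.ind = TRUE)  # (row, col)
  ey <- edge[, 1]; ex <- edge[, 2]
  radii <- seq(floor(radii[1]), ceiling(radii[2]))
  best_score <- matrix(0, h, w)
  best_r <- matrix(0, h, w)
  for (r in radii) {
    acc <- numeric(h * w)
    nang <- max(16L, ceiling(2 * pi * r))
    ang <- 2 * pi * seq_len(nang) / nang
    for (a in ang) {
      cx <- round(ex - r * cos(a)); cy <- round(ey - r * sin(a))
      ok <- cx >= 1 & cx <= w & cy >= 1 & cy <= h
      if (!any(ok)) next
      lin <- cy[ok] + (cx[ok] - 1L) * h
      cnt <- tabulate(lin, nbins = h * w)
      acc <- acc + cnt
    }
    # votes from a true circle spread over adjacent pixels through rounding;
    # score a center by its 3x3 neighbourhood sum
    am <- matrix(acc, h, w)
    ap <- matrix(0, h + 2, w + 2); ap[2:(h + 1), 2:(w + 1)] <- am
    nb <- ap[1:h, 1:w] + ap[1:h, 2:(w + 1)] + ap[1:h, 3:(w + 2)] +
          ap[2:(h + 1), 1:w] + ap[2:(h + 1), 2:(w + 1)] + ap[2:(h + 1), 3:(w + 2)] +
          ap[3:(h + 2), 1:w] + ap[3:(h + 2), 2:(w + 1)] + ap[3:(h + 2), 3:(w + 2)]
    score <- nb / nang
    upd <- score > best_score
    best_score[upd] <- score[upd]
    best_r[upd] <- r
  }
  # candidate centers: non-max suppression over the normalized score
  cand <- which(best_score >= score_min, arr.ind = TRUE)
  if (!nrow(cand)) return(matrix(numeric(0), ncol = 2,
                                 dimnames = list(NULL, c("x", "y"))))
  # validate candidates against the mask: a disc center is the point
  # supporting the largest fully-covered circle. coverage(r) = fraction of
  # mask pixels inside the circle of radius r.
  coverage_radius <- function(cy, cx) {
    rbest <- 0
    for (r in rev(radii)) {
      ys <- max(1, cy - r):min(h, cy + r)
      xs <- max(1, cx - r):min(w, cx + r)
      yy <- matrix(ys, length(ys), length(xs))
      xx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
      inside <- (xx - cx)^2 + (yy - cy)^2 <= r^2
      if (mean(mask[ys, xs][inside]) >= 0.9) { rbest <- r; break }
    }
    rbest
  }
  rstar <- vapply(seq_len(nrow(cand)),
                  function(i) coverage_radius(cand[i, 1], cand[i, 2]),
                  numeric(1))
  keep <- rstar > 0
  cand <- cand[keep, , drop = FALSE]
  rstar <- rstar[keep]
  sc <- best_score[cand]
  ord <- order(-rstar, -sc)
  cand <- cand[ord, , drop = FALSE]
  rstar <- rstar[ord]
  centers <- matrix(numeric(0), ncol = 3)
  for (i in seq_len(nrow(cand))) {
    cy <- cand[i, 1]; cx <- cand[i, 2]
    # largest-disc-first greedy: anything inside an accepted circle is the
    # same disc
    if (nrow(centers) &&
        any((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2 <
            (centers[, 3] + 2)^2)) next
    centers <- rbind(centers, c(cx, cy, rstar[i]))
  }
  # sub-pixel refinement: centroid of mask pixels within the fitted circle
  out <- t(apply(centers, 1, function(cc) {
    r <- cc[3] + 1
    ys <- max(1, round(cc[2] - r)):min(h, round(cc[2] + r))
    xs <- max(1, round(cc[1] - r)):min(w, round(cc[1] + r))
    sub <- mask[ys, xs, drop = FALSE]
    yy <- matrix(ys, length(ys), length(xs))
    xx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
    inside <- sub & ((xx - cc[1])^2 + (yy - cc[2])^2 <= r^2)
    if (!any(inside)) return(c(cc[1], cc[2]))
    c(mean(xx[inside]), mean(yy[inside]))
  }))
  colnames(out) <- c("x", "y")
  out[order(out[, 2], out[, 1]), , drop = FALSE]
}

#' Extract colored disc markers from an image
#'
#' Thresholds the image in HSV space to a binary mask for the requested
#' color, then detects filled discs with a circle Hough transform over the
#' spec's radius range. Centers are refined to sub-pixel accuracy from the
#' mask centroid of each accepted circle.
#'
#' @param image RGB array (`height x width x 3`, values in `[0, 1]`).
#' @param spec A [color_spec()].
#' @return Numeric matrix with columns `x`, `y`, one row per detected
#'   marker (zero rows when nothing matches).
#' @export
extract_markers <- function(image, spec) {
  stopifnot(inherits(spec, "color_spec"))
  hough_circles(hsv_mask(image, spec), spec$radius)
}

#' Labelled registration landmarks
#'
#' The four anatomical registration markers in a fixed order:
#' 1 sternoclavicular joint, 2 right 10th rib, 3 right 6th rib,
#' 4 left 6th rib.
#'
#' @param points 4-by-2 matrix of `(x, y)` pixel coordinates in the order
#'   above.
#' @param source `"chest"` or `"skeleton"`.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(points, source = c("chest", "skeleton")) {
  source <- match.arg(source)
  points <- as.matrix(points)
  if (nrow(points) != 4 || ncol(points) != 2)
    stop("`points` must be a 4-by-2 matrix", call. = FALSE)
  if (all(points[3, ] == points[4, ]))
    stop("left/right 6th-rib landmarks coincide", call. = FALSE)
  colnames(points) <- c("x", "y")
  structure(list(points = points, source = source), class = "landmark_set")
}

#' Assign anatomical roles to four detected landmark centers
#'
#' Orders unlabelled landmark detections by the geometry of an anterior
#' chest view: the sternoclavicular joint is the topmost point, the right
#' 10th rib the bottommost, and of the remaining two 6th-rib points the
#' subject's right rib appears at smaller image x (mirrored view). The same
#' rule applied to both images yields consistent correspondences.
#'
#' @param centers 4-by-2 matrix of detected `(x, y)` centers.
#' @inheritParams landmark_set
#' @return A [landmark_set()].
#' @export
label_landmarks <- function(centers, source = c("chest", "skeleton")) {
  centers <- as.matrix(centers)
  if (nrow(centers) != 4)
    stop(sprintf("expected 4 landmark markers, found %d", nrow(centers)),
         call. = FALSE)
  i1 <- which.min(centers[, 2])
  i2 <- which.max(centers[, 2])
  rest <- setdiff(1:4, c(i1, i2))
  rest <- rest[order(centers[rest, 1])]
  landmark_set(centers[c(i1, i2, rest[1], rest[2]), , drop = FALSE],
               source = match.arg(source))
}

rot2 <- function(theta)
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)

#' Estimate the chest-to-skeleton similarity transform
#'
#' From the four chest-photo landmarks and their skeleton-image counterparts,
#' recovers the rotation, anisotropic scale, and translation that carry chest
#' coordinates into skeleton coordinates. The baseline angles are those of
#' the line joining the two 6th-rib landmarks (3 -> 4) against the
#' horizontal; the x scale comes from that baseline's horizontal span, the
#' y scale from the vertical span of landmarks 1-2, and the translation
#' anchors landmark 3 in x and landmark 1 in y.
#'
#' In `"consistent"` mode (default) the rotation is a true planar rotation by
#' `theta2 - theta1` about chest landmark 3. `"literal"` mode instead
#' evaluates an alternative transcription of the transform arithmetic
#' (`theta = cot(slope)`, `w' = w cos(theta1) cos(theta2)`,
#' `h' = h sin(theta1) sin(theta2)`), preserved for comparison; it is not a
#' rotation and does not reduce to the identity for aligned images.
#'
#' @param chest,skeleton [landmark_set()]s from the two images.
#' @param mode `"consistent"` or `"literal"`.
#' @return An object of class `similarity_transform` with fields `theta1`,
#'   `theta2`, `eta_x`, `eta_y`, `phi_x`, `phi_y`, `mode`, `center`.
#' @export
estimate_transform <- function(chest, skeleton,
                               mode = c("consistent", "literal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(chest, "landmark_set"), inherits(skeleton, "landmark_set"))
  p <- chest$points; v <- skeleton$points
  if (p[4, 1] == p[3, 1] && p[4, 2] == p[3, 2])
    stop("degenerate chest landmarks: 6th-rib baseline has zero length",
         call. = FALSE)
  if (mode == "consistent") {
    theta1 <- atan2(p[4, 2] - p[3, 2], p[4, 1] - p[3, 1])
    theta2 <- atan2(v[4, 2] - v[3, 2], v[4, 1] - v[3, 1])
  } else {
    s1 <- (p[4, 2] - p[3, 2]) / (p[4, 1] - p[3, 1])
    s2 <- (v[4, 2] - v[3, 2]) / (v[4, 1] - v[3, 1])
    if (tan(s1) == 0 || tan(s2) == 0)
      stop("literal cot() undefined for this landmark geometry", call. = FALSE)
    theta1 <- 1 / tan(s1)
    theta2 <- 1 / tan(s2)
  }
  tr <- list(theta1 = unname(theta1), theta2 = unname(theta2), mode = mode,
             center = unname(p[3, ]))
  pa <- rotate_stage(p, tr)
  eta_x <- (v[4, 1] - v[3, 1]) / (pa[4, 1] - pa[3, 1])
  eta_y <- (v[2, 2] - v[1, 2]) / (pa[2, 2] - pa[1, 2])
  if (!is.finite(eta_x) || !is.finite(eta_y) || eta_x <= 0 || eta_y <= 0)
    stop(sprintf("non-positive or undefined scale (eta_x = %g, eta_y = %g)",
                 eta_x, eta_y), call. = FALSE)
  pb <- cbind(pa[, 1] * eta_x, pa[, 2] * eta_y)
  tr$eta_x <- unname(eta_x); tr$eta_y <- unname(eta_y)
  tr$phi_x <- unname(v[3, 1] - pb[3, 1])
  tr$phi_y <- unname(v[1, 2] - pb[1, 2])
  structure(tr, class = "similarity_transform")
}

# rotation stage of the transform chain, honoring the mode
rotate_stage <- function(pts, tr) {
  pts <- as.matrix(pts)
  if (tr$mode == "consistent") {
    d <- sweep(pts, 2, tr$center)
    sweep(d %*% t(rot2(tr$theta2 - tr$theta1)), 2, tr$center, `+`)
  } else {
    cbind(pts[, 1] * cos(tr$theta1) * cos(tr$theta2),
          pts[, 2] * sin(tr$theta1) * sin(tr$theta2))
  }
}

#' Apply a similarity transform to points
#'
#' Runs the rotate, scale, translate chain of [estimate_transform()] on a
#' set of `(x, y)` points.
#'
#' @param points n-by-2 matrix (or length-2 vector) of pixel coordinates.
#' @param transform A `similarity_transform`.
#' @return n-by-2 matrix of transformed coordinates.
#' @export
transform_points <- function(points, transform) {
  stopifnot(inherits(transform, "similarity_transform"))
  pts <- if (is.null(dim(points))) matrix(points, ncol = 2) else as.matrix(points)
  pa <- rotate_stage(pts, transform)
  cbind(x = pa[, 1] * transform$eta_x + transform$phi_x,
        y = pa[, 2] * transform$eta_y + transform$phi_y)
}

#' Affine form and analytic inverse of a consistent-mode transform
#'
#' Expresses the rotate-scale-translate chain as `x' = A x + b`, or returns
#' the exact inverse transform function. Only defined for `"consistent"`
#' mode (the literal-mode arithmetic is not invertible in general).
#'
#' @param transform A consistent-mode `similarity_transform`.
#' @return `transform_affine()`: list with 2x2 matrix `A` and length-2 `b`.
#'   `invert_transform()`: a function mapping n-by-2 points back.
#' @export
transform_affine <- function(transform) {
  if (transform$mode != "consistent")
    stop("affine form defined only for consistent mode", call. = FALSE)
  R <- rot2(transform$theta2 - transform$theta1)
  S <- diag(c(transform$eta_x, transform$eta_y))
  A <- S %*% R
  cen <- as.numeric(transform$center)
  b <- S %*% (cen - R %*% cen) + c(transform$phi_x, transform$phi_y)
  list(A = A, b = as.numeric(b))
}

#' @rdname transform_affine
#' @export
invert_transform <- function(transform) {
  af <- transform_affine(transform)
  Ainv <- solve(af$A)
  function(points) {
    pts <- if (is.null(dim(points))) matrix(points, ncol = 2) else as.matrix(points)
    out <- sweep(pts, 2, af$b) %*% t(Ainv)
    colnames(out) <- c("x", "y")
    out
  }
}

# row-major channel-id assignment: cluster rows by y with tolerance half the
# median nearest-neighbour distance, then order left-to-right within rows
order_row_major <- function(centers) {
  n <- nrow(centers)
  if (n <= 1) return(seq_len(n))
  dmat <- as.matrix(stats::dist(centers))
  diag(dmat) <- Inf
  tol <- stats::median(apply(dmat, 1, min)) / 2
  ord <- order(centers[, 2])
  row_id <- integer(n)
  current <- 0
  ref_y <- -Inf
  for (i in ord) {
    if (centers[i, 2] - ref_y > tol) {
      current <- current + 1
      ref_y <- centers[i, 2]
    }
    row_id[i] <- current
  }
  order(row_id, centers[, 1])
}

#' Locate sensor channels on the skeleton image
#'
#' End-to-end channel location: extract the sensor markers and the four
#' registration landmarks from the chest photograph, extract the four
#' skeleton registration landmarks, estimate the chest-to-skeleton transform,
#' and map every sensor marker into skeleton-image coordinates. Channel ids
#' are assigned row-major over the detected chest positions (top row first,
#' left to right).
#'
#' @param chest_photo,skeleton_image RGB arrays.
#' @param sensor_spec [color_spec()] of the sensor markers on the chest.
#' @param landmark_spec [color_spec()] of the chest registration landmarks.
#' @param skeleton_landmark_spec [color_spec()] of the skeleton landmarks
#'   (defaults to `landmark_spec`).
#' @param mode Transform mode, see [estimate_transform()].
#' @return A [sensor_layout()] in skeleton-image pixel coordinates.
#' @export
locate_channels <- function(chest_photo, skeleton_image,
                            sensor_spec = color_spec_preset("green-disc"),
                            landmark_spec = color_spec_preset("red-disc"),
                            skeleton_landmark_spec = landmark_spec,
                            mode = c("consistent", "literal")) {
  mode <- match.arg(mode)
  chest_lm <- extract_markers(chest_photo, landmark_spec)
  if (nrow(chest_lm) != 4)
    stop(sprintf("chest photo: expected 4 landmark markers, found %d",
                 nrow(chest_lm)), call. = FALSE)
  skel_lm <- extract_markers(skeleton_image, skeleton_landmark_spec)
  if (nrow(skel_lm) != 4)
    stop(sprintf("skeleton image: expected 4 landmark markers, found %d",
                 nrow(skel_lm)), call. = FALSE)
  sensors <- extract_markers(chest_photo, sensor_spec)
  if (nrow(sensors) == 0)
    stop("chest photo: no sensor markers detected", call. = FALSE)
  tr <- estimate_transform(label_landmarks(chest_lm, "chest"),
                           label_landmarks(skel_lm, "skeleton"),
                           mode = mode)
  sensors <- sensors[order_row_major(sensors), , drop = FALSE]
  sensor_layout(transform_points(sensors, tr))
}
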