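# Cardiac acoustic mapping: signal modulus -> scattered spatial
# interpolation over the registered sensor positions -> HSL colormap ->
# composited frames over the skeleton background.

#' Heart sound modulus
#'
#' The quantity mapped to color is the absolute value of the conditioned
#' heart sound sample, `e_i(n) = |s_i(n)|`.
#'
#' @param rec A (preprocessed) [pcg_recording()].
#' @return An object of class `modulus_series`: list with non-negative
#'   matrix `data` (channels x samples), `fs`, `channel_ids`.
#' @export
compute_modulus <- function(rec) {
  stopifnot(inherits(rec, "pcg_recording"))
  structure(list(data = abs(rec$data), fs = rec$fs,
                 channel_ids = rec$channel_ids), class = "modulus_series")
}

# Thin-plate spline scattered interpolant: exact at nodes, C1, and exactly
# reproduces affine fields through its polynomial part. Returns the
# factorized system so a fixed layout can be re-solved cheaply per frame.
tps_factor <- function(coords) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  K <- ifelse(d > 0, d^2 * log(d), 0)
  P <- cbind(1, coords)
  M <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  list(lu = M, coords = coords, n = n)
}

tps_solve <- function(fac, values) {
  rhs <- c(values, 0, 0, 0)
  solve(fac$lu, rhs)
}

tps_eval <- function(fac, coef, pts) {
  pts <- as.matrix(pts)
  dx <- outer(pts[, 1], fac$coords[, 1], `-`)
  dy <- outer(pts[, 2], fac$coords[, 2], `-`)
  r <- sqrt(dx^2 + dy^2)
  B <- ifelse(r > 0, r^2 * log(r), 0)
  as.numeric(B %*% coef[seq_len(fac$n)] +
             coef[fac$n + 1] + pts[, 1] * coef[fac$n + 2] +
             pts[, 2] * coef[fac$n + 3])
}

# is the layout a complete rectilinear grid? (allows tensor bicubic path)
grid_complete <- function(coords, tol = 1e-6) {
  ux <- sort(unique(round(coords[, 1] / tol) * tol))
  uy <- sort(unique(round(coords[, 2] / tol) * tol))
  length(ux) * length(uy) == nrow(coords) &&
    length(ux) >= 4 && length(uy) >= 4
}

# tensor-product natural cubic spline over a complete grid
bicubic_eval <- function(coords, values, xs, ys) {
  ux <- sort(unique(coords[, 1]))
  uy <- sort(unique(coords[, 2]))
  V <- matrix(NA_real_, length(uy), length(ux))
  iy <- match(coords[, 2], uy); ix <- match(coords[, 1], ux)
  V[cbind(iy, ix)] <- values
  # interpolate along x for each node row, then along y for each grid column
  mid <- matrix(NA_real_, length(uy), length(xs))
  for (i in seq_along(uy))
    mid[i, ] <- stats::splinefun(ux, V[i, ], method = "natural")(xs)
  out <- matrix(NA_real_, length(ys), length(xs))
  for (j in seq_along(xs))
    out[, j] <- stats::splinefun(uy, mid[, j], method = "natural")(ys)
  out
}

#' Interpolate one acoustic frame over the sensor region
#'
#' Builds a smooth spatial interpolant of the per-channel moduli at one time
#' instant and samples it on a pixel grid spanning the sensor bounding box.
#' The interpolant is exact at the sensor positions and at least C1 between
#' them; values outside the convex hull of the sensors are masked out
#' (`NA`), since extrapolated color there would be unsupported by data.
#'
#' Scattered layouts use thin-plate spline interpolation; layouts that form
#' a complete rectilinear grid may use a tensor-product cubic spline
#' (`method = "bicubic"`, or `"auto"` which prefers it when available).
#'
#' @param layout A [sensor_layout()] with at least 3 non-collinear sensors.
#' @param moduli Numeric vector of per-channel modulus values, aligned with
#'   `layout`.
#' @param grid_step Grid resolution in pixels.
#' @param method `"auto"`, `"tps"`, or `"bicubic"`.
#' @return An object of class `acoustic_frame`: list with `values`
#'   (`length(y)` x `length(x)` matrix, `NA` outside the mask), `x`, `y`
#'   (grid coordinates), `mask`, `layout`, `moduli`, and `predict`
#'   (function evaluating the interpolant at arbitrary `(x, y)` points).
#' @export
interpolate_frame <- function(layout, moduli, grid_step = 1,
                              method = c("auto", "tps", "bicubic")) {
  method <- match.arg(method)
  stopifnot(inherits(layout, "sensor_layout"))
  coords <- layout$coords
  if (length(moduli) != nrow(coords))
    stop("`moduli` must have one value per sensor", call. = FALSE)
  if (nrow(coords) < 3 ||
      qr(sweep(coords, 2, colMeans(coords)))$rank < 2)
    stop("layout degenerate: need >= 3 non-collinear sensor positions",
         call. = FALSE)
  use_bicubic <- switch(method,
                        bicubic = TRUE,
                        tps = FALSE,
                        auto = grid_complete(coords))
  if (use_bicubic && !grid_complete(coords))
    stop("bicubic method requires a complete rectilinear grid layout",
         call. = FALSE)
  xs <- seq(min(coords[, 1]), max(coords[, 1]), by = grid_step)
  ys <- seq(min(coords[, 2]), max(coords[, 2]), by = grid_step)
  if (use_bicubic) {
    vals <- bicubic_eval(coords, moduli, xs, ys)
    predict_fun <- function(pts) {
      pts <- as.matrix(pts)
      vapply(seq_len(nrow(pts)), function(i)
        bicubic_eval(coords, moduli, pts[i, 1], pts[i, 2]), numeric(1))
    }
  } else {
    fac <- tps_factor(coords)
    coef <- tps_solve(fac, moduli)
    gg <- expand.grid(x = xs, y = ys)
    vals <- matrix(tps_eval(fac, coef, as.matrix(gg)),
                   nrow = length(ys), ncol = length(xs), byrow = TRUE)
    predict_fun <- function(pts) tps_eval(fac, coef, pts)
  }
  hull <- grDevices::chull(coords)
  gg <- expand.grid(x = xs, y = ys)
  inp <- pracma::inpolygon(gg$x, gg$y,
                           coords[hull, 1], coords[hull, 2],
                           boundary = TRUE)
  mask <- matrix(inp, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  vals[!mask] <- NA_real_
  structure(list(values = vals, x = xs, y = ys, mask = mask,
                 layout = layout, moduli = moduli, predict = predict_fun),
            class = "acoustic_frame")
}

#' Colormap specification for acoustic maps
#'
#' The modulus-to-color rule: hue runs linearly from 240 degrees (blue, zero
#' modulus) down to 0 degrees (red, maximal modulus) at full saturation and
#' 50% lightness, so low moduli render blue/green and high moduli
#' yellow/red.
#'
#' @param em Normalization maximum `Em` (> 0), or `NULL` to derive it from
#'   the rendered data per `em_scope`.
#' @param em_scope `"global"` (one `Em` over the whole rendered window, so a
#'   given modulus has the same color in every frame) or `"per_frame"`.
#' @param saturation,lightness HSL saturation and lightness.
#' @return An object of class `colormap_spec`.
#' @export
colormap_spec <- function(em = NULL, em_scope = c("global", "per_frame"),
                          saturation = 1, lightness = 0.5) {
  em_scope <- match.arg(em_scope)
  if (!is.null(em) && em <= 0) stop("`em` must be > 0", call. = FALSE)
  structure(list(em = em, em_scope = em_scope, saturation = saturation,
                 lightness = lightness), class = "colormap_spec")
}

#' Map modulus values to hue
#'
#' Normalizes the modulus by `Em`, clips to `[0, 1]` (interpolation can
#' overshoot the node values), and maps linearly to hue
#' `240 * (1 - E/Em)` degrees: 0 modulus is blue (240), `Em` is red (0).
#'
#' @param frame An [interpolate_frame()] result, or a numeric vector/matrix
#'   of modulus values.
#' @param spec A [colormap_spec()]; `spec$em` must be set (positive).
#' @return Hue values in degrees, same shape as the input (NA preserved).
#' @export
modulus_to_hue <- function(frame, spec = colormap_spec(em = 1)) {
  vals <- if (inherits(frame, "acoustic_frame")) frame$values else frame
  if (is.null(spec$em) || spec$em <= 0)
    stop("`spec$em` must be a positive normalization maximum", call. = FALSE)
  eg <- pmin(pmax(vals / spec$em, 0), 1)
  240 * (1 - eg)
}

#' Convert HSL colors to 8-bit RGB
#'
#' Standard HSL (hue, saturation, lightness) to RGB conversion.
#'
#' @param hue Hue in degrees `[0, 360)`; vector, matrix, or the hue field of
#'   a frame. `NA` entries give `NA` output.
#' @param saturation,lightness Values in `[0, 1]` (scalars or shaped like
#'   `hue`).
#' @return Integer RGB values in 0-255. For vector input an n-by-3 matrix;
#'   for matrix input an `nrow x ncol x 3` array.
#' @examples
#' hsl_to_rgb(240, 1, 0.5)  # pure blue: 0 0 255
#' @export
hsl_to_rgb <- function(hue, saturation = 1, lightness = 0.5) {
  dims <- dim(hue)
  h <- as.numeric(hue); s <- as.numeric(saturation); l <- as.numeric(lightness)
  ok <- !is.na(h)
  if (any(h[ok] < 0 | h[ok] >= 360)) stop("hue must be in [0, 360)", call. = FALSE)
  if (any(s < 0 | s > 1) || any(l < 0 | l > 1))
    stop("saturation and lightness must be in [0, 1]", call. = FALSE)
  s <- rep_len(s, length(h)); l <- rep_len(l, length(h))
  C <- (1 - abs(2 * l - 1)) * s
  hp <- h / 60
  X <- C * (1 - abs(hp %% 2 - 1))
  m <- l - C / 2
  r <- g <- b <- rep(NA_real_, length(h))
  seg <- floor(hp) %% 6
  set <- function(idx, rv, gv, bv) {
    r[idx] <<- rv[idx]; g[idx] <<- gv[idx]; b[idx] <<- bv[idx]
  }
  zero <- numeric(length(h))
  set(which(ok & seg == 0), C, X, zero)
  set(which(ok & seg == 1), X, C, zero)
  set(which(ok & seg == 2), zero, C, X)
  set(which(ok & seg == 3), zero, X, C)
  set(which(ok & seg == 4), X, zero, C)
  set(which(ok & seg == 5), C, zero, X)
  out <- round(255 * (cbind(r, g, b) + m))
  if (is.null(dims)) {
    colnames(out) <- c("r", "g", "b")
    return(out)
  }
  array(out, dim = c(dims, 3))
}

#' Render a sequence of cardiac acoustic map frames
#'
#' For each sample step of `frame_interval` in `[t_start, t_end]`
#' (inclusive), interpolates the channel moduli over the registered sensor
#' positions, colors the field with the blue-to-red HSL map, and
#' alpha-blends it over the skeleton background inside the sensor hull.
#'
#' @param rec Conditioned [pcg_recording()] (moduli are taken as `|data|`).
#' @param layout Registered [sensor_layout()] in background pixel
#'   coordinates; must lie within the background bounds.
#' @param background RGB array (`height x width x 3`) used as backdrop.
#' @param t_start,t_end Window in seconds (`t_end >= t_start`).
#' @param frame_interval Time between frames in seconds.
#' @param spec A [colormap_spec()]. When `spec$em` is `NULL` it is set to
#'   the maximum modulus over the whole rendered window (global scope) or
#'   per frame.
#' @param alpha Blending factor of the color layer (default 0.6).
#' @param grid_step Interpolation grid step in pixels.
#' @param out_dir Optional directory; when given, frames are written as
#'   numbered PNG files.
#' @return List with `frames` (list of RGB arrays), `times`, `em`, and
#'   `files` (paths or `NULL`).
#' @export
render_sequence <- function(rec, layout, background, t_start, t_end,
                            frame_interval, spec = colormap_spec(),
                            alpha = 0.6, grid_step = 1, out_dir = NULL) {
  stopifnot(inherits(rec, "pcg_recording"), inherits(layout, "sensor_layout"))
  if (t_end < t_start) stop("empty time window", call. = FALSE)
  H <- dim(background)[1]; W <- dim(background)[2]
  if (any(layout$coords[, 1] < 1) || any(layout$coords[, 1] > W) ||
      any(layout$coords[, 2] < 1) || any(layout$coords[, 2] > H))
    stop("layout coordinates fall outside the background image", call. = FALSE)
  times <- seq(t_start, t_end, by = frame_interval)
  idx <- round(times * rec$fs) + 1L
  if (any(idx < 1L) || any(idx > ncol(rec$data)))
    stop("time window extends outside the recording", call. = FALSE)
  mod <- abs(rec$data[, idx, drop = FALSE])
  em_global <- if (!is.null(spec$em)) spec$em else max(mod)
  if (em_global <= 0) stop("window contains no signal (Em = 0)", call. = FALSE)

  # one TPS factorization serves every frame
  fac <- tps_factor(layout$coords)
  xs <- seq(min(layout$coords[, 1]), max(layout$coords[, 1]), by = grid_step)
  ys <- seq(min(layout$coords[, 2]), max(layout$coords[, 2]), by = grid_step)
  gg <- as.matrix(expand.grid(x = xs, y = ys))
  hull <- grDevices::chull(layout$coords)
  inp <- pracma::inpolygon(gg[, 1], gg[, 2],
                           layout$coords[hull, 1], layout$coords[hull, 2],
                           boundary = TRUE)
  px <- round(gg[inp, 1]); py <- round(gg[inp, 2])
  dx <- outer(gg[inp, 1], fac$coords[, 1], `-`)
  dy <- outer(gg[inp, 2], fac$coords[, 2], `-`)
  r <- sqrt(dx^2 + dy^2)
  B <- cbind(ifelse(r > 0, r^2 * log(r), 0), 1, gg[inp, 1], gg[inp, 2])

  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  frames <- vector("list", length(idx))
  files <- if (is.null(out_dir)) NULL else character(length(idx))
  ems <- numeric(length(idx))
  for (k in seq_along(idx)) {
    coef <- tps_solve(fac, mod[, k])
    vals <- as.numeric(B %*% coef)
    em_k <- if (spec$em_scope == "per_frame" && is.null(spec$em))
      max(mod[, k]) else em_global
    ems[k] <- em_k
    hue <- 240 * (1 - pmin(pmax(vals / em_k, 0), 1))
    rgb <- hsl_to_rgb(hue, spec$saturation, spec$lightness) / 255
    frame <- background
    lin <- cbind(py, px)
    for (ch in 1:3) {
      plane <- frame[, , ch]
      plane[lin] <- (1 - alpha) * plane[lin] + alpha * rgb[, ch]
      frame[, , ch] <- plane
    }
    frames[[k]] <- frame
    if (!is.null(out_dir)) {
      files[k] <- file.path(out_dir, sprintf("frame_%04d.png", k))
      png::writePNG(frame, files[k])
    }
  }
  list(frames = frames, times = times, em = ems, files = files)
}
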