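#' @useDynLib romvision, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median rnorm runif sd setNames
#' @importFrom utils head tail
NULL

# Pixel convention used throughout: (u, v) are continuous coordinates with the
# origin at the CENTER of the top-left pixel, u along image width (columns),
# v along image height (rows). Matrix element [v + 1, u + 1] holds pixel (u, v).
# Depth is metric (meters); 0 or NA marks an invalid measurement.

#' Camera intrinsic parameters
#'
#' The intrinsic matrix K collects the focal lengths expressed in pixel units
#' (`fx`, `fy`) and the principal point (`u0`, `v0`); it maps normalized camera
#' coordinates (X/Z, Y/Z) to pixel coordinates.
#'
#' @param fx,fy Focal length times pixel scale along u and v (pixels), > 0.
#' @param u0,v0 Principal point (pixels), inside the image.
#' @param width,height Image size in pixels.
#' @return An object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(fx, fy, u0, v0, width, height) {
  stopifnot(is.finite(fx), is.finite(fy), fx > 0, fy > 0)
  if (u0 < 0 || u0 >= width || v0 < 0 || v0 >= height)
    stop("principal point (u0, v0) must lie inside the image")
  structure(list(fx = fx, fy = fy, u0 = u0, v0 = v0,
                 width = as.integer(width), height = as.integer(height)),
            class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("camera_intrinsics: %dx%d, fx=%.6g fy=%.6g, pp=(%.6g, %.6g)\n",
              x$width, x$height, x$fx, x$fy, x$u0, x$v0))
  invisible(x)
}

#' Lens distortion coefficients
#'
#' Radial (`k1`, `k2`, `k3`) and tangential (`p1`, `p2`) correction
#' coefficients of the polynomial distortion model on the normalized plane.
#' All-zero coefficients give the identity model.
#'
#' @param k1,k2,k3 Radial coefficients (dimensionless).
#' @param p1,p2 Tangential coefficients (dimensionless).
#' @return An object of class `distortion_coefficients`.
#' @export
distortion_coefficients <- function(k1 = 0, k2 = 0, k3 = 0, p1 = 0, p2 = 0) {
  v <- c(k1 = k1, k2 = k2, k3 = k3, p1 = p1, p2 = p2)
  if (!all(is.finite(v))) stop("distortion coefficients must be finite")
  structure(as.list(v), class = "distortion_coefficients")
}

is_identity_distortion <- function(d) {
  is.null(d) || all(abs(unlist(d)) == 0)
}

#' Rigid depth-to-color registration
#'
#' Rotation `R` and translation `t` carrying points from the depth-camera
#' coordinate system into the color-camera coordinate system.
#'
#' @param R 3x3 rotation matrix (orthonormal, det +1 within 1e-9).
#' @param t Translation vector, meters.
#' @return An object of class `extrinsic_registration`.
#' @export
extrinsic_registration <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- matrix(as.numeric(R), 3, 3)
  t <- as.numeric(t)
  stopifnot(length(t) == 3)
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    stop("R is not orthonormal (R'R differs from identity by more than 1e-9)")
  if (abs(det(R) - 1) > 1e-9)
    stop("R must be a proper rotation (det(R) = 1)")
  structure(list(R = R, t = t), class = "extrinsic_registration")
}

#' RGB-D camera rig
#'
#' Bundles the color and depth intrinsics, their distortion models, and the
#' depth-to-color extrinsic registration.
#'
#' @param color,depth `camera_intrinsics` for the two sensors.
#' @param color_dist,depth_dist `distortion_coefficients` (NULL = none).
#' @param registration `extrinsic_registration` from depth to color frame.
#' @return An object of class `camera_rig`.
#' @export
camera_rig <- function(color, depth = color,
                       color_dist = distortion_coefficients(),
                       depth_dist = distortion_coefficients(),
                       registration = extrinsic_registration()) {
  stopifnot(inherits(color, "camera_intrinsics"),
            inherits(depth, "camera_intrinsics"),
            inherits(registration, "extrinsic_registration"))
  structure(list(color = color, depth = depth,
                 color_dist = color_dist, depth_dist = depth_dist,
                 registration = registration),
            class = "camera_rig")
}

#' One color + depth frame
#'
#' @param color H x W x 3 array of 8-bit RGB values; numeric/integer 0..255 or
#'   raw. Stored internally as raw.
#' @param depth H x W numeric matrix of metric depth in meters; 0 or NA marks
#'   an invalid pixel.
#' @param timestamp Acquisition time, seconds.
#' @param frame_index Ordinal index of the frame in its sequence.
#' @return An object of class `rgbd_frame`.
#' @export
rgbd_frame <- function(color, depth, timestamp = NA_real_, frame_index = NA_integer_) {
  color <- as_raw_image(color)
  depth <- as.matrix(depth)
  if (any(depth < 0, na.rm = TRUE)) stop("all valid depths must be > 0")
  structure(list(color = color, depth = depth,
                 timestamp = as.numeric(timestamp),
                 frame_index = as.integer(frame_index)),
            class = "rgbd_frame")
}

# Coerce an RGB image to a raw H x W x 3 array (values 0..255).
as_raw_image <- function(color) {
  if (is.raw(color)) {
    stopifnot(length(dim(color)) == 3, dim(color)[3] == 3)
    return(color)
  }
  stopifnot(length(dim(color)) == 3, dim(color)[3] == 3)
  v <- round(as.numeric(color))
  if (any(v < 0 | v > 255, na.rm = TRUE)) stop("color values must be in 0..255")
  array(as.raw(v), dim = dim(color))
}

# Numeric view of a raw image, one channel: H x W matrix of 0..255.
image_channel <- function(color, ch) {
  d <- dim(color)
  matrix(as.integer(color[, , ch]), d[1], d[2])
}

#' Back-project pixels to camera coordinates
#'
#' Lifts pixel coordinates with metric depth to 3-D points in the camera
#' coordinate system: X = z (u - u0)/fx, Y = z (v - v0)/fy, Z = z. When a
#' distortion model is given, the normalized coordinates are undistorted
#' before scaling by depth (the pixel grid observes distorted coordinates).
#'
#' @param u,v Pixel coordinates (vectors).
#' @param z Metric depth, meters; all > 0.
#' @param intr `camera_intrinsics`.
#' @param dist Optional `distortion_coefficients`.
#' @return n x 3 matrix of (X, Y, Z).
#' @export
pixel_to_camera <- function(u, v, z, intr, dist = NULL) {
  stopifnot(inherits(intr, "camera_intrinsics"))
  if (any(!is.finite(z)) || any(z <= 0))
    stop("invalid depth: depth values must be finite and > 0")
  x <- (u - intr$u0) / intr$fx
  y <- (v - intr$v0) / intr$fy
  if (!is_identity_distortion(dist)) {
    und <- undistort(x, y, dist)
    x <- und[, 1]; y <- und[, 2]
  }
  cbind(X = x * z, Y = y * z, Z = z)
}

#' Project camera-coordinate points to pixels
#'
#' Forward pinhole projection u = fx X/Z + u0, v = fy Y/Z + v0 (after the
#' distortion model, when given). No clipping to the image bounds is applied.
#'
#' @param points n x 3 matrix (or length-3 vector) of camera coordinates, Z > 0.
#' @param intr `camera_intrinsics`.
#' @param dist Optional `distortion_coefficients` applied on the normalized
#'   plane before pixel scaling.
#' @return n x 2 matrix of continuous (u, v).
#' @export
camera_to_pixel <- function(points, intr, dist = NULL) {
  stopifnot(inherits(intr, "camera_intrinsics"))
  p <- rbind3(points)
  if (any(p[, 3] <= 0)) stop("behind-camera: all points must have Z > 0")
  x <- p[, 1] / p[, 3]
  y <- p[, 2] / p[, 3]
  if (!is_identity_distortion(dist)) {
    dd <- apply_distortion(x, y, dist)
    x <- dd[, 1]; y <- dd[, 2]
  }
  cbind(u = intr$fx * x + intr$u0, v = intr$fy * y + intr$v0)
}

rbind3 <- function(points) {
  if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
}

#' Apply the lens distortion model
#'
#' Polynomial radial + tangential distortion on normalized coordinates, with
#' r^2 = x^2 + y^2:
#' x_d = x (1 + k1 r^2 + k2 r^4 + k3 r^6) + 2 p1 x y + p2 (r^2 + 2 x^2),
#' y_d = y (1 + k1 r^2 + k2 r^4 + k3 r^6) + 2 p2 x y + p1 (r^2 + 2 y^2).
#'
#' @param x,y Normalized coordinates (vectors).
#' @param d `distortion_coefficients`.
#' @return n x 2 matrix of distorted coordinates.
#' @export
apply_distortion <- function(x, y, d) {
  r2 <- x * x + y * y
  radial <- 1 + d$k1 * r2 + d$k2 * r2^2 + d$k3 * r2^3
  xd <- x * radial + 2 * d$p1 * x * y + d$p2 * (r2 + 2 * x * x)
  yd <- y * radial + 2 * d$p2 * x * y + d$p1 * (r2 + 2 * y * y)
  cbind(x = xd, y = yd)
}

#' Invert the lens distortion model
#'
#' Numerical inverse of [apply_distortion()] by fixed-point iteration,
#' initialized at the distorted point. Converges for the mild distortion of
#' consumer RGB-D optics.
#'
#' @param xd,yd Distorted normalized coordinates (vectors).
#' @param d `distortion_coefficients`.
#' @param tol Convergence tolerance on the forward-model residual.
#' @param max_iter Maximum fixed-point iterations.
#' @return n x 2 matrix of undistorted coordinates.
#' @export
undistort <- function(xd, yd, d, tol = 1e-9, max_iter = 50L) {
  if (is_identity_distortion(d)) return(cbind(x = xd, y = yd))
  x <- xd; y <- yd
  for (i in seq_len(max_iter)) {
    r2 <- x * x + y * y
    radial <- 1 + d$k1 * r2 + d$k2 * r2^2 + d$k3 * r2^3
    dx <- 2 * d$p1 * x * y + d$p2 * (r2 + 2 * x * x)
    dy <- 2 * d$p2 * x * y + d$p1 * (r2 + 2 * y * y)
    x_new <- (xd - dx) / radial
    y_new <- (yd - dy) / radial
    delta <- max(abs(x_new - x), abs(y_new - y))
    x <- x_new; y <- y_new
    if (delta < tol / 10) break
  }
  fwd <- apply_distortion(x, y, d)
  resid <- max(abs(fwd[, 1] - xd), abs(fwd[, 2] - yd))
  if (resid > tol)
    stop(sprintf("undistort did not converge: residual %.3g > tol %.3g", resid, tol))
  cbind(x = x, y = y)
}

#' Register a depth image into the color-camera geometry
#'
#' Each valid depth pixel (u_d, v_d, z_d) is back-projected through the depth
#' intrinsics, carried into the color frame by the rigid registration
#' (R, t), and forward-projected through the color intrinsics. A depth pixel
#' is not a point: its footprint covers a block of color pixels when the
#' color sensor is the finer grid, and its Z is written to every color pixel
#' whose center falls inside the projected footprint (with equal intrinsics
#' the footprint is exactly one pixel). The returned map holds, at each
#' color pixel, the Z coordinate (in the color frame) of the nearest point
#' that landed there (z-buffer); pixels receiving no point are NA.
#'
#' @param depth H x W depth matrix (meters, depth-camera geometry) or an
#'   `rgbd_frame`.
#' @param rig `camera_rig`.
#' @return H_c x W_c numeric matrix of depth in the color geometry (NA =
#'   no measurement).
#' @export
register_depth_to_color <- function(depth, rig) {
  stopifnot(inherits(rig, "camera_rig"))
  if (inherits(depth, "rgbd_frame")) depth <- depth$depth
  di <- rig$depth; ci <- rig$color
  if (nrow(depth) != di$height || ncol(depth) != di$width)
    stop(sprintf("depth image is %dx%d but depth intrinsics declare %dx%d",
                 ncol(depth), nrow(depth), di$width, di$height))
  ok <- which(is.finite(depth) & depth > 0)
  out <- matrix(NA_real_, ci$height, ci$width)
  if (length(ok) == 0) return(out)
  # matrix is column-major: index = (col-1)*H + row; pixel u = col-1, v = row-1
  z_d <- depth[ok]
  xn <- (((ok - 1) %/% nrow(depth)) - di$u0) / di$fx
  yn <- (((ok - 1) %% nrow(depth)) - di$v0) / di$fy
  if (!is_identity_distortion(rig$depth_dist)) {
    und <- undistort(xn, yn, rig$depth_dist)
    xn <- und[, 1]; yn <- und[, 2]
  }
  X <- xn * z_d; Y <- yn * z_d
  R <- rig$registration$R; t <- rig$registration$t
  Xc <- R[1, 1] * X + R[1, 2] * Y + R[1, 3] * z_d + t[1]
  Yc <- R[2, 1] * X + R[2, 2] * Y + R[2, 3] * z_d + t[2]
  Zc <- R[3, 1] * X + R[3, 2] * Y + R[3, 3] * z_d + t[3]
  front <- Zc > 0
  if (!any(front)) return(out)
  if (!all(front)) {
    Xc <- Xc[front]; Yc <- Yc[front]; Zc <- Zc[front]
  }
  xc <- Xc / Zc; yc <- Yc / Zc
  if (!is_identity_distortion(rig$color_dist)) {
    dd <- apply_distortion(xc, yc, rig$color_dist)
    xc <- dd[, 1]; yc <- dd[, 2]
  }
  uc <- ci$fx * xc + ci$u0
  vc <- ci$fy * yc + ci$v0
  cpp_zbuffer_splat(uc, vc, Zc,
                    0.5 * ci$fx / di$fx, 0.5 * ci$fy / di$fy,
                    ci$height, ci$width)
}
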