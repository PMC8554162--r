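# Constrained total-least-squares fits and the angle formulas.
#
# All fits are closed-form eigendecompositions of the centered scatter matrix:
# the plane normal is the smallest-eigenvalue eigenvector, the 3-D line
# direction the largest. Sign ambiguity is resolved lexicographically: the
# first nonzero component of the constrained vector is made positive.

# Flip v so that its first component above tol is positive.
fix_sign <- function(v, tol = 1e-12) {
  for (x in v) {
    if (abs(x) > tol) return(if (x < 0) -v else v)
  }
  v
}

#' Total-least-squares plane fit
#'
#' Fits the plane a x + b y + c z + d = 0 minimizing the sum of squared
#' orthogonal point-to-plane distances under the constraint
#' a^2 + b^2 + c^2 = 1. The normal is the eigenvector of the centered scatter
#' matrix with the smallest eigenvalue; the sign convention makes the first
#' nonzero normal component positive (a > 0, else b > 0, else c > 0).
#'
#' @param points n x 3 matrix, n >= 3, not all collinear.
#' @return An object of class `fitted_plane` with fields `normal` (a, b, c),
#'   `d`, `centroid`, `rms` (residual RMS distance) and `eigenvalues`.
#' @export
fit_plane <- function(points) {
  p <- rbind3(points)
  if (nrow(p) < 3) stop("degenerate geometry: plane fit needs >= 3 points")
  ctr <- colMeans(p)
  M <- crossprod(sweep(p, 2, ctr))
  e <- eigen(M, symmetric = TRUE)
  # eigenvalues descending; collinear iff the two smallest both vanish
  if (e$values[2] <= max(e$values[1], 1) * 1e-12)
    stop("degenerate geometry: points are collinear, plane is undetermined")
  n <- fix_sign(e$vectors[, 3])
  structure(list(normal = as.numeric(n),
                 d = -sum(n * ctr),
                 centroid = ctr,
                 rms = sqrt(max(e$values[3], 0) / nrow(p)),
                 eigenvalues = e$values),
            class = "fitted_plane")
}

#' Total-least-squares 3-D line fit
#'
#' Fits the line through the centroid minimizing the sum of squared
#' perpendicular distances, under a unit-norm direction constraint. The
#' direction is the largest-eigenvalue eigenvector of the centered scatter
#' matrix; sign convention: first nonzero component positive
#' (l > 0, else m > 0, else n > 0).
#'
#' @param points n x 3 matrix, n >= 2, not all identical.
#' @return An object of class `fitted_line3d` with fields `centroid`,
#'   `direction` and `rms` (residual RMS perpendicular distance).
#' @export
fit_line_3d <- function(points) {
  p <- rbind3(points)
  if (nrow(p) < 2) stop("degenerate geometry: line fit needs >= 2 points")
  ctr <- colMeans(p)
  M <- crossprod(sweep(p, 2, ctr))
  e <- eigen(M, symmetric = TRUE)
  if (e$values[1] <= 1e-24)
    stop("degenerate geometry: all points coincide, line is undetermined")
  d <- fix_sign(e$vectors[, 1])
  structure(list(centroid = ctr,
                 direction = as.numeric(d),
                 rms = sqrt(max(e$values[2] + e$values[3], 0) / nrow(p))),
            class = "fitted_line3d")
}

#' Total-least-squares 2-D line fit
#'
#' Fits a x - b y + c = 0 minimizing sum (a x_i - b y_i + c)^2 under
#' a^2 + b^2 = 1. The direction vector of the fitted line is e = (b, a);
#' sign convention: b >= 0, and a > 0 when b = 0.
#'
#' @param points n x 2 matrix, n >= 2, not all identical.
#' @return An object of class `fitted_line2d` with fields `a`, `b`, `c`,
#'   `e` (unit direction (b, a)) and `rms`.
#' @export
fit_line_2d <- function(points) {
  p <- if (is.null(dim(points))) matrix(points, ncol = 2) else as.matrix(points)
  if (nrow(p) < 2) stop("degenerate geometry: line fit needs >= 2 points")
  ctr <- colMeans(p)
  # a x - b y + c = 0 is the TLS line on coordinates (x, -y)
  q <- cbind(p[, 1] - ctr[1], -(p[, 2] - ctr[2]))
  M <- crossprod(q)
  e <- eigen(M, symmetric = TRUE)
  if (e$values[1] <= 1e-24)
    stop("degenerate geometry: all points coincide, line is undetermined")
  ab <- e$vectors[, 2]            # smallest eigenvalue: (a, b)
  dir <- fix_sign(c(ab[2], ab[1]))  # e = (b, a), first nonzero comp positive
  b <- dir[1]; a <- dir[2]
  structure(list(a = a, b = b, c = -(a * ctr[1] - b * ctr[2]),
                 e = as.numeric(dir),
                 rms = sqrt(max(e$values[2], 0) / nrow(p))),
            class = "fitted_line2d")
}

#' Working frame of the sagittal plane
#'
#' Builds the 2-D measurement frame inside the fitted sagittal plane: the
#' x-axis is the seat-marker line direction projected into the plane (the
#' zero reference of the hip angle), the y-axis is perpendicular to it in the
#' plane with its camera-frame v component non-negative, and the z-axis
#' follows the right-hand rule. The origin is `origin_hint` projected
#' orthogonally onto the plane.
#'
#' @param plane `fitted_plane` of the sagittal working plane.
#' @param seat_line `fitted_line3d` of the seat marker.
#' @param origin_hint 3-D point; defaults to the seat-line centroid.
#' @param max_tilt_deg Maximum allowed angle between the seat line and the
#'   plane (degrees); beyond it the configuration is rejected.
#' @return An object of class `sagittal_frame` with `origin`, `x_axis`,
#'   `y_axis`, `z_axis`.
#' @export
build_sagittal_frame <- function(plane, seat_line, origin_hint = seat_line$centroid,
                                 max_tilt_deg = 30) {
  stopifnot(inherits(plane, "fitted_plane"), inherits(seat_line, "fitted_line3d"))
  n <- plane$normal; d <- seat_line$direction
  tilt <- asin(min(1, abs(sum(n * d)))) * 180 / pi
  if (tilt >= max_tilt_deg)
    stop(sprintf(paste0("configuration geometry error: seat line is tilted %.1f",
                        " degrees out of the sagittal plane (limit %.1f)"),
                 tilt, max_tilt_deg))
  x <- d - sum(d * n) * n
  x <- x / sqrt(sum(x^2))
  y <- cross3(n, x)
  if (y[2] < 0) y <- -y
  z <- cross3(x, y)
  origin <- origin_hint - (sum(n * origin_hint) + plane$d) * n
  structure(list(origin = as.numeric(origin), x_axis = as.numeric(x),
                 y_axis = as.numeric(y), z_axis = as.numeric(z)),
            class = "sagittal_frame")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Project 3-D points into the sagittal working frame
#'
#' Orthogonally projects points onto the frame plane and expresses them in
#' the frame's in-plane axes; the out-of-plane component is dropped.
#'
#' @param points n x 3 matrix of camera-frame coordinates.
#' @param frame `sagittal_frame`.
#' @return n x 2 matrix of in-plane coordinates.
#' @export
project_to_frame <- function(points, frame) {
  stopifnot(inherits(frame, "sagittal_frame"))
  rel <- sweep(rbind3(points), 2, frame$origin)
  cbind(x = as.numeric(rel %*% frame$x_axis),
        y = as.numeric(rel %*% frame$y_axis))
}

#' Signed angle between two 2-D directions
#'
#' Magnitude from the arc cosine of the normalized dot product; sign from the
#' scalar 2-D cross product e_ref x e_tgt, with cross >= 0 giving a positive
#' angle. Result in degrees, in (-180, 180].
#'
#' @param e_ref,e_tgt Nonzero 2-D vectors.
#' @return Angle in degrees.
#' @export
signed_angle <- function(e_ref, e_tgt) {
  nr <- sqrt(sum(e_ref^2)); nt <- sqrt(sum(e_tgt^2))
  if (nr == 0 || nt == 0) stop("invalid input: zero-length direction vector")
  dotn <- min(1, max(-1, sum(e_ref * e_tgt) / (nr * nt)))
  ang <- acos(dotn) * 180 / pi
  cross <- e_ref[1] * e_tgt[2] - e_ref[2] * e_tgt[1]
  if (cross >= 0) ang else -ang
}

#' Acute angle between two plane normals
#'
#' Arc cosine of the absolute normalized dot product: antipodal normals give
#' 0, the result lies between 0 and 90 degrees.
#'
#' @param n_a,n_b Nonzero 3-D vectors.
#' @return Angle in degrees, between 0 and 90.
#' @export
plane_normal_angle <- function(n_a, n_b) {
  na <- sqrt(sum(n_a^2)); nb <- sqrt(sum(n_b^2))
  if (na == 0 || nb == 0) stop("invalid input: zero-length normal vector")
  acos(min(1, abs(sum(n_a * n_b)) / (na * nb))) * 180 / pi
}
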