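# Marker extraction: RGB-distance thresholding, 8-connected components,
# anatomical role assignment and median-depth representative sampling.

#' Segmentation configuration
#'
#' @param reference_color Length-3 RGB reference (0..255) used when all
#'   markers share one color.
#' @param threshold Euclidean RGB-distance threshold T; a pixel is foreground
#'   when its distance to the reference is <= T.
#' @param min_component_size Components smaller than this many pixels are
#'   discarded.
#' @param bin_count Number of bins along a component's dominant axis used by
#'   [sample_with_median_depth()]. `bin_count = 1` reproduces the
#'   one-representative-pixel-per-marker reading.
#' @param role_colors Optional named list (`seat`, `thigh`, `calf`) of RGB
#'   references; when given, each role is segmented with its own color and
#'   centroid tracking is bypassed.
#' @param role_gate Maximum image distance (pixels) between a role's prior
#'   centroid and its matched component; beyond it the role is reported
#'   missing.
#' @param depth_window Half-width (meters) of the depth-consistency window
#'   around the component's median depth; samples outside it are rejected
#'   before binning (guards against background depth bleeding through
#'   depth/color parallax). `Inf` disables the guard.
#' @param median_tol Depth tolerance (meters) within which pixels count as
#'   sharing the bin's median depth; among them the representative pixel is
#'   the one nearest the bin's pixel centroid. Keeps the selected pixel
#'   laterally centered on the strip instead of at whichever position the
#'   sensor noise put the exact median. Should sit between the sensor's
#'   depth quantization and its noise level.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(reference_color = c(0, 0, 255),
                                threshold = 60,
                                min_component_size = 40,
                                bin_count = 32,
                                role_colors = NULL,
                                role_gate = 80,
                                depth_window = 0.20,
                                median_tol = 0.002) {
  stopifnot(threshold > 0, length(reference_color) == 3,
            all(reference_color >= 0 & reference_color <= 255),
            bin_count >= 1, min_component_size >= 1)
  if (!is.null(role_colors))
    stopifnot(all(vapply(role_colors, length, 1L) == 3))
  structure(list(reference_color = as.numeric(reference_color),
                 threshold = threshold,
                 min_component_size = as.integer(min_component_size),
                 bin_count = as.integer(bin_count),
                 role_colors = role_colors,
                 role_gate = role_gate,
                 depth_window = depth_window,
                 median_tol = median_tol),
            class = "segmentation_config")
}

#' RGB-distance threshold mask
#'
#' Marks a pixel foreground (255) when the Euclidean distance between its
#' (R, G, B) value and the reference color is less than or equal to the
#' threshold, else background (0). The three-channel comparison and the
#' binarization are collapsed into a single-channel output.
#'
#' @param color H x W x 3 RGB image (raw or numeric 0..255).
#' @param cfg `segmentation_config`, or a length-3 reference color.
#' @param threshold Threshold T when `cfg` is a plain color.
#' @return H x W integer matrix with values 0/255.
#' @export
color_distance_mask <- function(color, cfg, threshold = NULL) {
  if (inherits(cfg, "segmentation_config")) {
    ref <- cfg$reference_color; T <- cfg$threshold
  } else {
    ref <- as.numeric(cfg)
    T <- if (is.null(threshold)) stop("threshold required") else threshold
  }
  img <- as_raw_image(color)
  d <- dim(img)
  matrix(cpp_color_mask(img, d[1] * d[2],
                        as.integer(round(ref[1])), as.integer(round(ref[2])),
                        as.integer(round(ref[3])), T),
         d[1], d[2])
}

#' Extract 8-connected marker components
#'
#' Labels 8-connected foreground components of a binary mask, discards those
#' smaller than `min_size`, and returns them sorted by size, largest first.
#'
#' @param mask H x W matrix; nonzero = foreground.
#' @param min_size Minimum pixel count.
#' @return List of `marker_component` objects, each with `pixels` (n x 2
#'   integer matrix of (u, v)), `centroid`, `size` and `role`
#'   (initially "unassigned").
#' @export
extract_components <- function(mask, min_size = 1) {
  fg <- which(mask != 0)
  if (length(fg) == 0) return(list())
  H <- nrow(mask)
  vf <- (fg - 1L) %% H
  uf <- (fg - 1L) %/% H
  # label only the foreground bounding box
  r0 <- min(vf); r1 <- max(vf); c0 <- min(uf); c1 <- max(uf)
  sub <- matrix(0L, r1 - r0 + 1L, c1 - c0 + 1L)
  sub[cbind(vf - r0 + 1L, uf - c0 + 1L)] <- 1L
  lab <- cpp_label_components(sub)
  idx <- which(lab != 0L)
  labs <- lab[idx]
  v <- (idx - 1L) %% nrow(lab) + r0
  u <- (idx - 1L) %/% nrow(lab) + c0
  comps <- lapply(split(seq_along(idx), labs), function(i) {
    if (length(i) < min_size) return(NULL)
    px <- cbind(u = u[i], v = v[i])
    structure(list(pixels = px,
                   centroid = c(u = mean(px[, 1]), v = mean(px[, 2])),
                   size = nrow(px),
                   role = "unassigned"),
              class = "marker_component")
  })
  comps <- comps[!vapply(comps, is.null, TRUE)]
  comps[order(vapply(comps, function(cp) cp$size, 1), decreasing = TRUE)]
}

#' Assign anatomical roles to components
#'
#' Greedy nearest-centroid matching: role/component pairs are taken in order
#' of ascending image distance between the component centroid and the role's
#' prior centroid (from the previous frame or an initial labeled frame), each
#' component used at most once. A role whose best available distance exceeds
#' `gate` is reported missing.
#'
#' @param components List of `marker_component`.
#' @param priors Named list of prior centroids, one `(u, v)` per expected role.
#' @param gate Maximum matching distance in pixels.
#' @return List with `assigned` (named list role -> component, role field
#'   filled) and `missing` (character vector of unmatched roles).
#' @export
assign_roles <- function(components, priors, gate = 80) {
  roles <- names(priors)
  if (length(components) == 0)
    return(list(assigned = list(), missing = roles))
  dmat <- matrix(Inf, length(roles), length(components),
                 dimnames = list(roles, NULL))
  for (r in seq_along(roles))
    for (k in seq_along(components))
      dmat[r, k] <- sqrt(sum((components[[k]]$centroid - priors[[r]])^2))
  assigned <- list()
  repeat {
    if (all(!is.finite(dmat))) break
    best <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
    if (dmat[best[1], best[2]] > gate) break
    role <- roles[best[1]]
    comp <- components[[best[2]]]
    comp$role <- role
    assigned[[role]] <- comp
    dmat[best[1], ] <- Inf
    dmat[, best[2]] <- Inf
  }
  list(assigned = assigned, missing = setdiff(roles, names(assigned)))
}

#' Representative marker samples with median depth
#'
#' Partitions a component's pixels into `bin_count` bins along its dominant
#' image-plane axis (largest-variance direction of the pixel coordinates) and
#' emits, per bin, a single representative pixel whose depth is the bin's
#' median: among the pixels within `median_tol` of the median depth (the
#' pixels indistinguishable from the median at sensor resolution), the one
#' nearest the bin's pixel centroid is taken. Bins without a valid depth are
#' skipped. Before binning, pixels whose depth deviates from the component's
#' median by more than `depth_window` are rejected.
#'
#' @param component `marker_component`.
#' @param depth H x W registered depth map in the color geometry (meters,
#'   NA/0 invalid).
#' @param bin_count Number of bins.
#' @param depth_window Depth-consistency half-width, meters (Inf disables).
#' @param median_tol Depth tolerance for median candidacy, meters.
#' @return n x 3 matrix of samples (u, v, z), n >= 2.
#' @export
sample_with_median_depth <- function(component, depth, bin_count = 32,
                                     depth_window = 0.20,
                                     median_tol = 0.002) {
  px <- component$pixels
  z <- depth[cbind(px[, 2] + 1L, px[, 1] + 1L)]
  ok <- is.finite(z) & z > 0
  if (sum(ok) < 2)
    stop("insufficient depth: component has fewer than 2 pixels with valid depth")
  if (is.finite(depth_window)) {
    zmed <- median(z[ok])
    ok <- ok & is.finite(z) & abs(z - zmed) <= depth_window
    if (sum(ok) < 2)
      stop("insufficient depth: component has fewer than 2 pixels with valid depth")
  }
  # bin geometry from the full (dense, symmetric) pixel set; depth statistics
  # from the valid pixels only — a registered depth map is sparse and its
  # valid-pixel lattice must not steer the bin centroids
  ctr <- colMeans(px)
  M <- crossprod(sweep(px, 2, ctr))
  ax <- eigen(M, symmetric = TRUE)$vectors[, 1]
  t <- as.numeric(sweep(px, 2, ctr) %*% ax)
  rng <- range(t)
  if (diff(rng) <= 0) {
    bins <- rep(1L, length(t))
  } else {
    bins <- pmin(bin_count, 1L + as.integer(floor(
      (t - rng[1]) / diff(rng) * bin_count)))
  }
  out <- lapply(split(seq_along(t), bins), function(i) {
    valid <- i[ok[i]]
    if (length(valid) == 0) return(NULL)
    zi <- z[valid]
    med <- median(zi)
    dev <- abs(zi - med)
    cand <- valid[dev <= max(min(dev), median_tol)]
    if (length(cand) > 1) {
      bctr <- colMeans(px[i, , drop = FALSE])
      d2 <- (px[cand, 1] - bctr[1])^2 + (px[cand, 2] - bctr[2])^2
      cand <- cand[which.min(d2)]
    } else cand <- cand[1]
    c(px[cand, 1], px[cand, 2], z[cand])
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) < min(2, bin_count))
    stop("insufficient depth: fewer than 2 bins with valid depth")
  s <- do.call(rbind, out)
  dimnames(s) <- list(NULL, c("u", "v", "z"))
  s
}

#' Segment one color frame into labeled markers
#'
#' With per-role reference colors, each role is segmented independently and
#' its largest component is taken (subject to the prior gate when priors are
#' given). With a single reference color, components are extracted once and
#' matched to the roles' prior centroids.
#'
#' @param color H x W x 3 RGB image.
#' @param cfg `segmentation_config`.
#' @param priors Named list of prior centroids per role (required for
#'   single-color tracking; optional gate check otherwise).
#' @param roles Roles to extract.
#' @return List with `markers` (named list role -> `marker_component`) and
#'   `missing` (character vector).
#' @export
segment_frame <- function(color, cfg, priors = NULL,
                          roles = c("seat", "thigh", "calf")) {
  stopifnot(inherits(cfg, "segmentation_config"))
  img <- as_raw_image(color)
  if (!is.null(cfg$role_colors)) {
    markers <- list(); missing <- character()
    for (role in roles) {
      ref <- cfg$role_colors[[role]]
      if (is.null(ref)) { missing <- c(missing, role); next }
      mask <- color_distance_mask(img, ref, cfg$threshold)
      comps <- extract_components(mask, cfg$min_component_size)
      if (length(comps) == 0) { missing <- c(missing, role); next }
      comp <- comps[[1]]
      if (!is.null(priors[[role]])) {
        d <- sqrt(sum((comp$centroid - priors[[role]])^2))
        if (d > cfg$role_gate) { missing <- c(missing, role); next }
      }
      comp$role <- role
      markers[[role]] <- comp
    }
    return(list(markers = markers, missing = missing))
  }
  if (is.null(priors))
    stop("single-color segmentation needs prior role centroids for tracking")
  mask <- color_distance_mask(img, cfg)
  comps <- extract_components(mask, cfg$min_component_size)
  res <- assign_roles(comps, priors[roles], cfg$role_gate)
  list(markers = res$assigned, missing = res$missing)
}
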