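# Per-frame orchestration: segmentation -> depth sampling -> 3-D lift ->
# planar projection -> 2-D line fits -> signed joint angles; plus filtering,
# ROM extraction, peak detection and comparison against reference traces.

lift_marker <- function(samples, rig) {
  pixel_to_camera(samples[, 1], samples[, 2], samples[, 3],
                  rig$color, rig$color_dist)
}

frame_markers <- function(frame, rig, seg, priors, roles) {
  depth_reg <- register_depth_to_color(frame$depth, rig)
  s <- segment_frame(frame$color, seg, priors, roles)
  samples <- list()
  for (role in names(s$markers)) {
    res <- tryCatch(
      sample_with_median_depth(s$markers[[role]], depth_reg,
                               seg$bin_count, seg$depth_window,
                               seg$median_tol),
      error = function(e) e)
    if (inherits(res, "error")) {
      s$missing <- c(s$missing, role)
      s$markers[[role]] <- NULL
    } else samples[[role]] <- res
  }
  list(markers = s$markers, samples = samples, missing = unique(s$missing))
}

#' Build the sagittal working frame from calibration frames
#'
#' The working plane is fitted to the calf-marker samples pooled across the
#' calibration frames (a knee sweep with the hip fixed); the in-plane x-axis
#' comes from a 3-D line fit of the seat marker in the first calibration
#' frame, and the origin is the seat-line centroid projected onto the plane.
#'
#' @param frames List of `rgbd_frame` calibration frames.
#' @param rig `camera_rig`.
#' @param seg `segmentation_config`.
#' @param priors Prior role centroids (single-color tracking only).
#' @return A `sagittal_frame`.
#' @export
build_reference_frame <- function(frames, rig, seg, priors = NULL) {
  if (length(frames) == 0) stop("empty input: no calibration frames")
  calf_pts <- list()
  seat_line <- NULL
  for (k in seq_along(frames)) {
    fm <- frame_markers(frames[[k]], rig, seg, priors,
                        roles = c("seat", "calf"))
    if (!is.null(fm$samples$calf))
      calf_pts[[length(calf_pts) + 1L]] <- lift_marker(fm$samples$calf, rig)
    if (is.null(seat_line) && !is.null(fm$samples$seat))
      seat_line <- fit_line_3d(lift_marker(fm$samples$seat, rig))
    if (!is.null(priors))
      for (role in names(fm$markers))
        priors[[role]] <- fm$markers[[role]]$centroid
  }
  if (length(calf_pts) == 0)
    stop("marker lost: no calf marker found in any calibration frame")
  if (is.null(seat_line))
    stop("marker lost: no seat marker found in the calibration frames")
  plane <- fit_plane(do.call(rbind, calf_pts))
  build_sagittal_frame(plane, seat_line)
}

new_series <- function(n, timestamps) {
  structure(data.frame(frame = seq_len(n), time_s = timestamps,
                       theta_k = NA_real_, theta_x = NA_real_,
                       theta_kg = NA_real_, flag = "",
                       stringsAsFactors = FALSE),
            class = c("joint_angle_series", "data.frame"))
}

series_times <- function(frames, fps) {
  ts <- vapply(frames, function(f) f$timestamp, 1)
  if (any(!is.finite(ts))) ts <- (seq_along(frames) - 1) / fps
  ts
}

#' Per-frame hip and knee angles in the sagittal plane
#'
#' For each frame: segment the seat, thigh and calf markers, sample their
#' depths from the registered depth map, lift the samples to camera
#' coordinates, project into the sagittal working frame, fit the three 2-D
#' marker lines, and compute the hip angle theta_k (seat line to thigh line)
#' and knee angle theta_x (thigh line to calf line) as signed angles. Frames
#' with a lost marker or insufficient depth get a flagged missing value
#' rather than aborting the sequence.
#'
#' @param frames List of `rgbd_frame`.
#' @param rig `camera_rig`.
#' @param seg `segmentation_config`.
#' @param frame_def `sagittal_frame` from [build_reference_frame()].
#' @param priors Initial role centroids (single-color tracking only).
#' @param fps Frame rate used when frames carry no timestamps.
#' @param filter_window Optional odd window for [median_average_filter()]
#'   applied to the sagittal channels (NULL = no filtering, as the angles in
#'   the sagittal plane are used unfiltered by default).
#' @return A `joint_angle_series` data frame with columns `frame`, `time_s`,
#'   `theta_k`, `theta_x`, `theta_kg`, `flag`.
#' @export
compute_sagittal_series <- function(frames, rig, seg, frame_def, priors = NULL,
                                    fps = 30, filter_window = NULL) {
  if (length(frames) == 0) stop("empty input: no frames to process")
  out <- new_series(length(frames), series_times(frames, fps))
  for (j in seq_along(frames)) {
    fm <- frame_markers(frames[[j]], rig, seg, priors,
                        roles = c("seat", "thigh", "calf"))
    if (length(fm$missing) > 0) {
      out$flag[j] <- paste0("marker-lost:", paste(fm$missing, collapse = "+"))
      next
    }
    e <- lapply(fm$samples, function(s)
      fit_line_2d(project_to_frame(lift_marker(s, rig), frame_def))$e)
    out$theta_k[j] <- signed_angle(e$seat, e$thigh)
    out$theta_x[j] <- signed_angle(e$thigh, e$calf)
    if (!is.null(priors))
      for (role in names(fm$markers))
        priors[[role]] <- fm$markers[[role]]$centroid
  }
  if (!is.null(filter_window)) {
    out$theta_k <- median_average_filter(out$theta_k, filter_window)
    out$theta_x <- median_average_filter(out$theta_x, filter_window)
  }
  out
}

#' Per-frame hip angle in the coronal plane
#'
#' Fits a plane to the pooled thigh + calf samples of each frame; the first
#' frame's normal is the zero reference (the leg plane is parallel to the
#' sagittal plane at the start), and the coronal hip angle theta_kg of frame
#' j is the acute angle between that frame's normal and the reference. The
#' knee must be bent so the two strips span a plane; a straight knee makes
#' the fit degenerate.
#'
#' @param frames List of `rgbd_frame`.
#' @param rig `camera_rig`.
#' @param seg `segmentation_config`.
#' @param priors Initial role centroids (single-color tracking only).
#' @param fps Frame rate used when frames carry no timestamps.
#' @param filter_window Odd window of the median-average filter applied to
#'   the coronal channel (the paper's impulse-noise guard); NULL disables.
#' @param min_aspect Minimum ratio between the second and first singular
#'   values of the pooled points' in-plane spread; below it the points are
#'   treated as collinear (straight knee).
#' @return A `joint_angle_series` with the `theta_kg` channel filled.
#' @export
compute_coronal_series <- function(frames, rig, seg, priors = NULL, fps = 30,
                                   filter_window = 5, min_aspect = 0.1) {
  if (length(frames) == 0) stop("empty input: no frames to process")
  out <- new_series(length(frames), series_times(frames, fps))
  ref_normal <- NULL
  for (j in seq_along(frames)) {
    fm <- frame_markers(frames[[j]], rig, seg, priors,
                        roles = c("thigh", "calf"))
    if (length(fm$missing) > 0) {
      out$flag[j] <- paste0("marker-lost:", paste(fm$missing, collapse = "+"))
      if (j == 1) stop("marker lost in the reference (first) frame: ",
                       paste(fm$missing, collapse = ", "))
      next
    }
    pts <- rbind(lift_marker(fm$samples$thigh, rig),
                 lift_marker(fm$samples$calf, rig))
    pl <- fit_plane(pts)
    # straight knee: the pooled points are nearly collinear
    aspect <- sqrt(max(pl$eigenvalues[2], 0) / max(pl$eigenvalues[1], 1e-300))
    if (aspect < min_aspect) {
      if (j == 1)
        stop(paste("degenerate geometry: thigh and calf markers are collinear",
                   "(knee straight); bend the knee to a comfortable angle"))
      out$flag[j] <- "degenerate-plane"
      next
    }
    if (is.null(ref_normal)) ref_normal <- pl$normal
    out$theta_kg[j] <- plane_normal_angle(pl$normal, ref_normal)
    if (!is.null(priors))
      for (role in names(fm$markers))
        priors[[role]] <- fm$markers[[role]]$centroid
  }
  if (!is.null(filter_window))
    out$theta_kg <- median_average_filter(out$theta_kg, filter_window)
  out
}

#' Median-average filter
#'
#' Sliding centered window: the window's single maximum and single minimum
#' are dropped and the remaining values averaged — an impulse-noise guard for
#' the angle traces. At the edges the window is truncated; when fewer than 3
#' values remain, a plain mean is used. Missing values are excluded from the
#' window and stay missing in the output only when their window is empty.
#'
#' @param x Numeric vector (may contain NA).
#' @param window Odd integer >= 3, <= length(x).
#' @return Filtered numeric vector, same length.
#' @export
median_average_filter <- function(x, window = 5) {
  n <- length(x)
  if (window %% 2 != 1 || window < 3 || window > n)
    stop("configuration error: window must be odd, >= 3 and <= series length")
  h <- (window - 1) %/% 2
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    w <- x[max(1, i - h):min(n, i + h)]
    w <- w[is.finite(w)]
    if (length(w) == 0) next
    out[i] <- if (length(w) >= 3)
      (sum(w) - max(w) - min(w)) / (length(w) - 2)
    else mean(w)
  }
  out
}

#' Range of motion per joint channel
#'
#' Maximum and minimum of each angle channel over the valid frames, with the
#' frame indices attaining them.
#'
#' @param series `joint_angle_series` (or data frame with the angle columns).
#' @param channels Channels to summarize; defaults to those with any valid
#'   sample.
#' @return An object of class `rom_result`: per channel `max`, `min`,
#'   `frame_max`, `frame_min`, plus `n_valid` per channel.
#' @export
extract_rom <- function(series, channels = NULL) {
  all_ch <- intersect(c("theta_k", "theta_x", "theta_kg"), names(series))
  if (is.null(channels)) {
    channels <- all_ch[vapply(all_ch, function(ch) any(is.finite(series[[ch]])), TRUE)]
    if (length(channels) == 0) stop("no valid data in any angle channel")
  }
  res <- list()
  for (ch in channels) {
    v <- series[[ch]]
    ok <- which(is.finite(v))
    if (length(ok) == 0)
      stop(sprintf("no valid data in channel %s", ch))
    imax <- ok[which.max(v[ok])]; imin <- ok[which.min(v[ok])]
    res[[ch]] <- list(max = v[imax], min = v[imin],
                      frame_max = series$frame[imax],
                      frame_min = series$frame[imin],
                      n_valid = length(ok))
  }
  structure(res, class = "rom_result")
}

#' @export
print.rom_result <- function(x, ...) {
  cat("Range of motion (degrees):\n")
  lbl <- c(theta_k = "hip, sagittal (theta_k)",
           theta_x = "knee, sagittal (theta_x)",
           theta_kg = "hip, coronal (theta_kg)")
  for (ch in names(x))
    cat(sprintf("  %-26s max %8.2f (frame %d)   min %8.2f (frame %d)   n=%d\n",
                lbl[[ch]], x[[ch]]$max, x[[ch]]$frame_max,
                x[[ch]]$min, x[[ch]]$frame_min, x[[ch]]$n_valid))
  invisible(x)
}

#' Detect alternating peaks in an angle trace
#'
#' Turning-point detection: a local extremum is committed once the trace has
#' reversed away from it by at least `min_prominence`, which yields strictly
#' alternating maxima and minima. Runs of exactly equal values (plateaus)
#' report their center sample. Series endpoints are not peaks; missing values
#' are skipped.
#'
#' @param x Numeric vector, or a `joint_angle_series` (then `channel` picks
#'   the trace).
#' @param min_prominence Minimum reversal, degrees.
#' @param times Optional timestamps (taken from the series when given one).
#' @param channel Channel used when `x` is a series.
#' @return Data frame with columns `index`, `time`, `value`, `type`
#'   ("max"/"min"); zero rows when no peak qualifies.
#' @export
detect_peaks <- function(x, min_prominence = 5, times = NULL, channel = NULL) {
  if (is.data.frame(x)) {
    if (is.null(channel)) {
      chs <- intersect(c("theta_kg", "theta_x", "theta_k"), names(x))
      channel <- chs[vapply(chs, function(ch) any(is.finite(x[[ch]])), TRUE)][1]
    }
    times <- x$time_s
    x <- x[[channel]]
  }
  n <- length(x)
  if (is.null(times)) times <- seq_len(n)
  ok <- which(is.finite(x))
  if (length(ok) < 3)
    return(data.frame(index = integer(), time = numeric(),
                      value = numeric(), type = character()))
  # compress runs of exactly equal consecutive values to their center
  vals <- x[ok]
  runs <- rle(vals)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  centers <- ok[floor((starts + ends) / 2)]
  v <- runs$values
  peaks <- list()
  dir <- 0L
  imax <- 1L; imin <- 1L
  for (i in seq_along(v)) {
    if (v[i] > v[imax]) imax <- i
    if (v[i] < v[imin]) imin <- i
    if (dir >= 0 && v[imax] - v[i] >= min_prominence) {
      if (dir != 0L)   # initial descent from the series start is not a peak
        peaks[[length(peaks) + 1L]] <- c(imax, 1)
      else if (imax > 1L)
        peaks[[length(peaks) + 1L]] <- c(imax, 1)
      dir <- -1L; imin <- i
    } else if (dir <= 0 && v[i] - v[imin] >= min_prominence) {
      if (dir != 0L)
        peaks[[length(peaks) + 1L]] <- c(imin, -1)
      else if (imin > 1L)
        peaks[[length(peaks) + 1L]] <- c(imin, -1)
      dir <- 1L; imax <- i
    }
  }
  if (length(peaks) == 0)
    return(data.frame(index = integer(), time = numeric(),
                      value = numeric(), type = character()))
  p <- do.call(rbind, peaks)
  idx <- centers[p[, 1]]
  data.frame(index = idx, time = times[idx], value = x[idx],
             type = ifelse(p[, 2] > 0, "max", "min"),
             stringsAsFactors = FALSE)
}

#' Compare peak angles against a reference trace
#'
#' Detects peaks in both the vision-measured and the reference angle traces,
#' matches peaks of the same type greedily by nearest timestamp within a
#' gate, and reports the per-peak differences delta = vision - reference and
#' their maximum absolute value.
#'
#' @param vision,reference Data frames with columns `time_s` and `angle_deg`
#'   (a `joint_angle_series` is accepted for `vision`; `channel` picks the
#'   trace).
#' @param min_prominence Peak prominence passed to [detect_peaks()].
#' @param gate_s Maximum timestamp difference for a match, seconds.
#' @param channel Channel used when `vision` is a series.
#' @return An object of class `peak_comparison`: data frame of matched peaks
#'   with `delta`, plus attributes `max_abs_delta` and counts of unmatched
#'   peaks. Zero matched rows (with a warning) when nothing matches.
#' @export
compare_with_reference <- function(vision, reference, min_prominence = 5,
                                   gate_s = 1, channel = NULL) {
  as_trace <- function(d, channel) {
    if (inherits(d, "joint_angle_series")) {
      if (is.null(channel)) {
        chs <- intersect(c("theta_kg", "theta_x", "theta_k"), names(d))
        channel <- chs[vapply(chs, function(ch) any(is.finite(d[[ch]])), TRUE)][1]
      }
      data.frame(time_s = d$time_s, angle_deg = d[[channel]])
    } else data.frame(time_s = d$time_s, angle_deg = d$angle_deg)
  }
  va <- as_trace(vision, channel); rf <- as_trace(reference, channel)
  pv <- detect_peaks(va$angle_deg, min_prominence, va$time_s)
  pr <- detect_peaks(rf$angle_deg, min_prominence, rf$time_s)
  rows <- list()
  for (tp in c("max", "min")) {
    a <- pv[pv$type == tp, ]; b <- pr[pr$type == tp, ]
    if (nrow(a) == 0 || nrow(b) == 0) next
    dt <- abs(outer(a$time, b$time, "-"))
    repeat {
      if (all(!is.finite(dt)) || min(dt) > gate_s) break
      hit <- which(dt == min(dt), arr.ind = TRUE)[1, ]
      rows[[length(rows) + 1L]] <- data.frame(
        type = tp,
        time_vision = a$time[hit[1]], value_vision = a$value[hit[1]],
        time_ref = b$time[hit[2]], value_ref = b$value[hit[2]],
        delta = a$value[hit[1]] - b$value[hit[2]],
        stringsAsFactors = FALSE)
      dt[hit[1], ] <- Inf; dt[, hit[2]] <- Inf
    }
  }
  if (length(rows) == 0) {
    warning("no matchable peaks between the vision and reference traces")
    cmp <- data.frame(type = character(), time_vision = numeric(),
                      value_vision = numeric(), time_ref = numeric(),
                      value_ref = numeric(), delta = numeric())
  } else {
    cmp <- do.call(rbind, rows)
    cmp <- cmp[order(cmp$time_ref), ]
    rownames(cmp) <- NULL
  }
  structure(cmp,
            class = c("peak_comparison", "data.frame"),
            max_abs_delta = if (nrow(cmp)) max(abs(cmp$delta)) else NA_real_,
            n_vision_peaks = nrow(pv), n_reference_peaks = nrow(pr))
}

#' Maximum absolute matched-peak difference
#'
#' @param cmp A `peak_comparison`.
#' @return Numeric scalar, degrees.
#' @export
max_abs_delta <- function(cmp) attr(cmp, "max_abs_delta")

#' Plot a joint angle series
#'
#' @param x `joint_angle_series`.
#' @param channels Channels to draw.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.joint_angle_series <- function(x, channels = c("theta_k", "theta_x", "theta_kg"),
                                    ...) {
  chs <- channels[vapply(channels, function(ch) any(is.finite(x[[ch]])), TRUE)]
  if (length(chs) == 0) stop("no valid data to plot")
  graphics::matplot(x$time_s, as.matrix(x[chs]), type = "l", lty = 1,
                    xlab = "time [s]", ylab = "angle [deg]", ...)
  graphics::legend("topright", legend = chs, col = seq_along(chs), lty = 1)
  invisible(x)
}
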