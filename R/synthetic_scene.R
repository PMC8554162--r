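# Synthetic RGB-D scenes of a two-link articulated leg with strip markers.
#
# The generator is the package's reference instrument: it renders the seat,
# thigh and calf strips through the full camera model (distortion, separate
# depth-camera geometry, depth->color extrinsics) with configurable sensor
# noise, and stores the ground-truth joint angles per frame. Angle
# conventions match the measurement chain: the hip sagittal angle theta_H2 is
# measured from the seat-line direction, rotating from the frame's +x axis
# toward its +y axis positive; the knee angle theta_2 is measured from the
# thigh extension line in the same rotation sense; the coronal hip angle
# theta_H1 tilts the leg plane out of the sagittal plane about the hip's
# anterior-posterior axis (only its magnitude is observable).

#' Default RGB-D rig emulating a consumer LiDAR depth camera
#'
#' 1280x720 color at ~70 deg horizontal FOV, 1024x768 (XGA) depth, a 15 mm
#' depth-to-color baseline with a 0.5 degree relative rotation, no lens
#' distortion.
#'
#' @return A `camera_rig`.
#' @export
default_rig <- function() {
  ang <- 0.5 * pi / 180
  Ry <- matrix(c(cos(ang), 0, -sin(ang),
                 0, 1, 0,
                 sin(ang), 0, cos(ang)), 3, 3)
  camera_rig(
    color = camera_intrinsics(900, 900, 640, 360, 1280, 720),
    depth = camera_intrinsics(730, 730, 512, 384, 1024, 768),
    registration = extrinsic_registration(Ry, c(0.015, 0, 0)))
}

#' Leg scene configuration
#'
#' Geometry of the two-link leg, its marker strips, the seat marker, the
#' camera rig and the placement of everything in the camera frame. Distances
#' in meters. The defaults put the sagittal plane 1.2 m in front of the
#' camera with the whole leg inside both sensors' fields of view.
#'
#' @param thigh_len,calf_len Segment lengths.
#' @param thigh_strip_len,calf_strip_len,seat_strip_len Marker strip lengths.
#' @param strip_width Marker strip width.
#' @param marker_offset Offset of the marker plane from the limb axis toward
#'   the camera (skin/chair surface standoff).
#' @param hip_position Hip pivot in camera coordinates; its z is the camera
#'   to sagittal-plane distance.
#' @param seat_offset Seat-strip center relative to the hip (in-plane).
#' @param role_colors Named list of marker RGB colors.
#' @param background_color,background_depth Backdrop color and its constant
#'   depth.
#' @param fps Frame rate of generated sessions.
#' @param sample_step Surface sampling step used by the rasterizer.
#' @param rig `camera_rig` doing the imaging.
#' @param scene_rotation,scene_translation Optional rigid motion applied to
#'   the whole scene (camera-pose variation).
#' @param angle_bounds Plausibility bounds (degrees) for the trajectory
#'   channels and for the absolute calf direction.
#' @param max_invisible_frac Generation fails when a larger fraction of
#'   frames has a strip fully outside the color image.
#' @return An object of class `leg_scene_config`.
#' @export
leg_scene_config <- function(thigh_len = 0.40, calf_len = 0.38,
                             thigh_strip_len = 0.25, calf_strip_len = 0.20,
                             seat_strip_len = 0.25, strip_width = 0.02,
                             marker_offset = 0.06,
                             hip_position = c(-0.45, -0.15, 1.20),
                             seat_offset = c(-0.05, 0.18, 0),
                             role_colors = list(seat = c(40, 180, 70),
                                                thigh = c(30, 60, 230),
                                                calf = c(220, 50, 50)),
                             background_color = c(128, 128, 128),
                             background_depth = 3.0,
                             fps = 10,
                             sample_step = 5e-4,
                             rig = default_rig(),
                             scene_rotation = diag(3),
                             scene_translation = c(0, 0, 0),
                             angle_bounds = list(hip = c(-60, 45),
                                                 knee = c(-5, 95),
                                                 coronal = c(-5, 50),
                                                 calf_abs = c(-85, 85)),
                             max_invisible_frac = 0.1) {
  stopifnot(thigh_len > 0, calf_len > 0, strip_width > 0,
            inherits(rig, "camera_rig"))
  structure(list(thigh_len = thigh_len, calf_len = calf_len,
                 thigh_strip_len = thigh_strip_len,
                 calf_strip_len = calf_strip_len,
                 seat_strip_len = seat_strip_len,
                 strip_width = strip_width, marker_offset = marker_offset,
                 hip_position = as.numeric(hip_position),
                 seat_offset = as.numeric(seat_offset),
                 role_colors = role_colors,
                 background_color = as.numeric(background_color),
                 background_depth = background_depth,
                 fps = fps, sample_step = sample_step, rig = rig,
                 scene_rotation = matrix(as.numeric(scene_rotation), 3, 3),
                 scene_translation = as.numeric(scene_translation),
                 angle_bounds = angle_bounds,
                 max_invisible_frac = max_invisible_frac),
            class = "leg_scene_config")
}

#' Sensor noise specification
#'
#' Defaults reproduce a consumer LiDAR depth camera at ~1 m range: per-pixel
#' Gaussian depth noise of 5 mm, 8-bit color noise of 5 gray levels, 1 mm
#' depth quantization, no dropout.
#'
#' @param depth_sigma Depth noise standard deviation, meters.
#' @param color_sigma Color noise standard deviation, 8-bit units.
#' @param depth_quant Depth quantization step, meters (0 = none).
#' @param dropout Per-pixel probability of a missing depth return.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(depth_sigma = 0.005, color_sigma = 5,
                       depth_quant = 0.001, dropout = 0) {
  stopifnot(depth_sigma >= 0, color_sigma >= 0, depth_quant >= 0,
            dropout >= 0, dropout < 1)
  structure(list(depth_sigma = depth_sigma, color_sigma = color_sigma,
                 depth_quant = depth_quant, dropout = dropout),
            class = "noise_spec")
}

#' Noise-free sensor model
#' @return A `noise_spec` with all noise sources disabled.
#' @export
noise_none <- function() noise_spec(0, 0, 0, 0)

# ---- trajectory waveforms --------------------------------------------------

#' Trajectory waveforms
#'
#' Building blocks for per-frame ground-truth angle traces, degrees.
#' `wave_triangle` starts at `min` and reaches `max` at mid-cycle (exactly on
#' a sample when `frames_per_cycle` is even); `wave_trapezoid` inserts a
#' dwell of constant angle at each limit, the way a physician holds a limb at
#' its end of range; `wave_sine` is a smooth oscillation.
#'
#' @param value,n Constant value and length.
#' @param from,to Sweep endpoints.
#' @param min,max Oscillation limits.
#' @param cycles Number of oscillation cycles.
#' @param frames_per_cycle Samples per cycle.
#' @param ramp,dwell Trapezoid ramp and dwell lengths, frames.
#' @return Numeric vector of angles, degrees.
#' @export
wave_constant <- function(value, n) rep(value, n)

#' @rdname wave_constant
#' @export
wave_linear <- function(from, to, n) seq(from, to, length.out = n)

#' @rdname wave_constant
#' @export
wave_triangle <- function(min, max, cycles, frames_per_cycle) {
  k <- 0:(cycles * frames_per_cycle)
  phase <- (k %% frames_per_cycle) / frames_per_cycle
  min + (max - min) * (1 - abs(2 * phase - 1))
}

#' @rdname wave_constant
#' @export
wave_trapezoid <- function(min, max, cycles, ramp = 7, dwell = 4) {
  cyc <- c(seq(min, max, length.out = ramp + 1)[-1], rep(max, dwell),
           seq(max, min, length.out = ramp + 1)[-1], rep(min, dwell))
  c(min, rep(cyc, cycles))
}

#' @rdname wave_constant
#' @export
wave_sine <- function(min, max, cycles, frames_per_cycle) {
  k <- 0:(cycles * frames_per_cycle)
  mid <- (min + max) / 2
  mid - (max - min) / 2 * cos(2 * pi * k / frames_per_cycle)
}

#' Assemble a ground-truth trajectory
#'
#' @param hip Hip sagittal angle theta_H2 per frame, degrees.
#' @param knee Knee angle theta_2 per frame, degrees.
#' @param coronal Coronal hip angle theta_H1 per frame, degrees.
#'   Vectors are recycled to the longest channel.
#' @return Data frame with columns `theta_H2`, `theta_2`, `theta_H1`.
#' @export
make_trajectory <- function(hip = 0, knee = 0, coronal = 0) {
  n <- max(length(hip), length(knee), length(coronal))
  data.frame(theta_H2 = rep_len(hip, n),
             theta_2 = rep_len(knee, n),
             theta_H1 = rep_len(coronal, n))
}

check_trajectory <- function(traj, cfg) {
  b <- cfg$angle_bounds
  bad <- function(x, lim) any(x < lim[1] - 1e-9 | x > lim[2] + 1e-9)
  if (bad(traj$theta_H2, b$hip) || bad(traj$theta_2, b$knee) ||
      bad(traj$theta_H1, b$coronal) ||
      bad(traj$theta_H2 + traj$theta_2, b$calf_abs))
    stop("trajectory violates the configured anatomical angle bounds")
  traj
}

# ---- posing ----------------------------------------------------------------

rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

in_plane_dir <- function(deg) {
  a <- deg * pi / 180
  c(cos(a), sin(a), 0)
}

#' Pose the leg and its marker strips for one frame
#'
#' Places the seat, thigh and calf strips in camera coordinates for the given
#' ground-truth angles: the thigh rotates about the hip's coronal-parallel
#' axis by theta_H2, the calf attaches at the knee rotated by theta_2 from
#' the thigh extension line, and the whole leg (not the seat) tilts about the
#' hip's anterior-posterior axis by theta_H1. Marker strips run along their
#' segment axes, offset toward the camera; finally the configured scene pose
#' is applied to everything.
#'
#' @param traj_row One row of a trajectory (list/data frame row with
#'   `theta_H2`, `theta_2`, `theta_H1`, degrees).
#' @param cfg `leg_scene_config`.
#' @return Named list of strips (`seat`, `thigh`, `calf`), each with
#'   `center`, `axis`, `wdir`, `len`, `width`, `role`.
#' @export
pose_leg <- function(traj_row, cfg) {
  hip <- cfg$hip_position
  off <- c(0, 0, -cfg$marker_offset)
  thigh_dir <- in_plane_dir(traj_row$theta_H2)
  calf_dir <- in_plane_dir(traj_row$theta_H2 + traj_row$theta_2)
  knee <- hip + cfg$thigh_len * thigh_dir
  strip <- function(center, axis, len, role) {
    wdir <- c(-axis[2], axis[1], 0)  # in-plane perpendicular
    list(center = center, axis = axis, wdir = wdir,
         len = len, width = cfg$strip_width, role = role)
  }
  seat <- strip(hip + cfg$seat_offset + off, c(1, 0, 0),
                cfg$seat_strip_len, "seat")
  thigh <- strip(hip + cfg$thigh_len / 2 * thigh_dir + off, thigh_dir,
                 cfg$thigh_strip_len, "thigh")
  calf <- strip(knee + cfg$calf_len / 2 * calf_dir + off, calf_dir,
                cfg$calf_strip_len, "calf")
  # coronal tilt of the leg (not the seat) about the hip's A-P axis
  if (abs(traj_row$theta_H1) > 0) {
    Rx <- rot_x(traj_row$theta_H1)
    tilt <- function(s) {
      s$center <- as.numeric(Rx %*% (s$center - hip)) + hip
      s$axis <- as.numeric(Rx %*% s$axis)
      s$wdir <- as.numeric(Rx %*% s$wdir)
      s
    }
    thigh <- tilt(thigh); calf <- tilt(calf)
  }
  # rigid scene pose
  Rs <- cfg$scene_rotation; ts <- cfg$scene_translation
  if (any(Rs != diag(3)) || any(ts != 0)) {
    move <- function(s) {
      s$center <- as.numeric(Rs %*% s$center) + ts
      s$axis <- as.numeric(Rs %*% s$axis)
      s$wdir <- as.numeric(Rs %*% s$wdir)
      s
    }
    seat <- move(seat); thigh <- move(thigh); calf <- move(calf)
  }
  list(seat = seat, thigh = thigh, calf = calf)
}

strip_points <- function(s, step) {
  a <- seq(-s$len / 2, s$len / 2, by = step)
  w <- seq(-s$width / 2, s$width / 2, by = step)
  g <- expand.grid(a = a, w = w)
  cbind(s$center[1] + g$a * s$axis[1] + g$w * s$wdir[1],
        s$center[2] + g$a * s$axis[2] + g$w * s$wdir[2],
        s$center[3] + g$a * s$axis[3] + g$w * s$wdir[3])
}

#' Render one RGB-D frame of the posed scene
#'
#' Rasterizes the strips by dense surface point sampling with z-buffer
#' occlusion. The color image is formed in the color-camera geometry
#' (including its distortion model) at 2x2 subpixel resolution and
#' area-averaged down, emulating the areal integration of a real sensor
#' pixel (hard-edged rasterization leaves staircase artifacts on the strip
#' borders that a physical camera does not produce). The depth image is
#' formed independently in the depth-camera geometry, so the depth-to-color
#' registration of the measurement chain is genuinely exercised. Sensor
#' noise, quantization and dropout are applied last.
#'
#' @param strips Output of [pose_leg()].
#' @param cfg `leg_scene_config`.
#' @param noise `noise_spec`.
#' @param timestamp,frame_index Frame metadata.
#' @param store_label Keep the per-pixel role label map (for segmentation
#'   diagnostics); off by default to save memory. A pixel is labeled with a
#'   strip's role when that strip wins at least 3 of its 4 subpixels.
#' @return List with `frame` (`rgbd_frame`), `visibility` (named fraction of
#'   each strip's surface samples landing inside the color image) and
#'   optionally `label` (H x W integer matrix, 0 = background, 1..3 = seat,
#'   thigh, calf).
#' @export
render_frame <- function(strips, cfg, noise = noise_spec(),
                         timestamp = NA_real_, frame_index = NA_integer_,
                         store_label = FALSE) {
  rig <- cfg$rig
  ci <- rig$color; di <- rig$depth
  roles <- names(strips)
  pts <- lapply(strips, strip_points, step = cfg$sample_step)
  n_per <- vapply(pts, nrow, 1L)
  P <- do.call(rbind, pts)
  strip_id <- rep(seq_along(strips), n_per)
  if (any(P[, 3] <= 0)) stop("strips must lie in front of the camera")

  # color-camera pass at 2x2 subpixel resolution; subpixel (U, V) centers
  # sit at u = (U - 0.5) / 2, v = (V - 0.5) / 2 in pixel coordinates
  uv <- camera_to_pixel(P, ci, rig$color_dist)
  Ui <- as.integer(round(2 * uv[, 1] + 0.5))
  Vi <- as.integer(round(2 * uv[, 2] + 0.5))
  H2 <- 2L * ci$height; W2 <- 2L * ci$width
  inb <- Ui >= 0L & Ui < W2 & Vi >= 0L & Vi < H2
  visibility <- vapply(seq_along(strips), function(k)
    mean(inb[strip_id == k]), 1)
  names(visibility) <- roles
  npix <- ci$height * ci$width
  ch <- lapply(cfg$background_color, function(x) rep(as.integer(x), npix))
  label <- NULL
  if (any(inb)) {
    idx <- Ui[inb] * H2 + Vi[inb] + 1L
    zb <- cpp_zbuffer(idx, P[inb, 3], H2 * W2)
    ids <- matrix(0L, H2, W2)
    hit <- which(zb$who > 0L)
    src <- which(inb)[zb$who[hit]]
    ids[hit] <- strip_id[src]
    # per-pixel subpixel winner counts per strip
    odd_r <- seq(1L, H2, 2L); odd_c <- seq(1L, W2, 2L)
    sub <- list(ids[odd_r, odd_c], ids[odd_r + 1L, odd_c],
                ids[odd_r, odd_c + 1L], ids[odd_r + 1L, odd_c + 1L])
    covered <- matrix(0L, ci$height, ci$width)
    counts <- vector("list", length(strips))
    for (k in seq_along(strips)) {
      ck <- (sub[[1]] == k) + (sub[[2]] == k) + (sub[[3]] == k) + (sub[[4]] == k)
      counts[[k]] <- ck
      covered <- covered + ck
    }
    for (c in 1:3) {
      acc <- cfg$background_color[c] * (4L - covered)
      for (k in seq_along(strips))
        acc <- acc + cfg$role_colors[[roles[k]]][c] * counts[[k]]
      ch[[c]] <- as.integer(round(acc / 4))
    }
    if (store_label) {
      label <- matrix(0L, ci$height, ci$width)
      for (k in seq_along(strips)) label[counts[[k]] >= 3L] <- k
    }
  }
  color <- array(as.raw(c(ch[[1]], ch[[2]], ch[[3]])),
                 dim = c(ci$height, ci$width, 3))

  # depth-camera pass
  reg <- rig$registration
  Pd <- sweep(P, 2, reg$t) %*% reg$R   # R^T (p - t)
  depth <- matrix(cfg$background_depth, di$height, di$width)
  front <- Pd[, 3] > 0
  if (any(front)) {
    uvd <- camera_to_pixel(Pd[front, , drop = FALSE], di, rig$depth_dist)
    uid <- as.integer(round(uvd[, 1])); vid <- as.integer(round(uvd[, 2]))
    inbd <- uid >= 0 & uid < di$width & vid >= 0 & vid < di$height
    if (any(inbd)) {
      idxd <- uid[inbd] * di$height + vid[inbd] + 1L
      zbd <- cpp_zbuffer(idxd, Pd[front, 3][inbd], di$height * di$width)
      hitd <- which(zbd$who > 0L)
      depth[hitd] <- zbd$z[hitd]
    }
  }

  # sensor noise
  if (noise$color_sigma > 0)
    color <- array(cpp_noise_u8(color, noise$color_sigma), dim = dim(color))
  if (noise$depth_sigma > 0 || noise$depth_quant > 0 || noise$dropout > 0)
    depth <- matrix(cpp_noise_depth(depth, noise$depth_sigma,
                                    noise$depth_quant, noise$dropout),
                    di$height, di$width)

  out <- list(frame = rgbd_frame(color, depth, timestamp, frame_index),
              visibility = visibility)
  if (store_label) out$label <- label
  out
}

default_trajectory <- function(mode, n_frames, cycles) {
  switch(mode,
    "calibration" = make_trajectory(hip = -10,
                                    knee = wave_linear(10, 80, n_frames)),
    "sagittal-knee" = make_trajectory(hip = -10,
                                      knee = wave_triangle(0, 90, cycles, 12)),
    "sagittal-hip" = make_trajectory(hip = wave_triangle(-45, 30, cycles, 12),
                                     knee = 60),
    "coronal" = make_trajectory(hip = -10, knee = 45,
                                coronal = wave_trapezoid(0, 40, cycles)),
    stop("unknown session mode: ", mode))
}

#' Generate a ground-truth-annotated RGB-D session
#'
#' Renders a frame sequence for one measurement protocol: `"sagittal-knee"`
#' (hip still, knee oscillating), `"sagittal-hip"` (hip oscillating, knee at
#' a fixed comfortable flexion), `"coronal"` (bent knee, hip
#' abduction starting at zero) or `"calibration"` (knee sweep with the hip
#' fixed, used to fit the sagittal working plane).
#'
#' @param mode Session mode.
#' @param cfg `leg_scene_config`.
#' @param noise `noise_spec`.
#' @param seed Optional RNG seed; fixing it makes the session bit-identical
#'   across runs.
#' @param trajectory Optional explicit trajectory (from [make_trajectory()]);
#'   the default depends on the mode.
#' @param n_frames Frames of the default calibration sweep.
#' @param cycles Cycles of the default oscillating trajectories.
#' @param store_labels Keep per-pixel role label maps on every frame.
#' @return An object of class `rom_session`: `frames` (list of
#'   `rgbd_frame`), `truth` (data frame: frame, time_s, theta_H2, theta_2,
#'   theta_H1, visible), `cfg`, `noise`, `rig`, `seg` (a matching
#'   `segmentation_config`), `mode`, `seed`, and `labels` when requested.
#' @export
generate_session <- function(mode = c("sagittal-knee", "sagittal-hip",
                                      "coronal", "calibration"),
                             cfg = leg_scene_config(),
                             noise = noise_spec(), seed = NULL,
                             trajectory = NULL, n_frames = 8, cycles = 6,
                             store_labels = FALSE) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(trajectory))
    trajectory <- default_trajectory(mode, n_frames, cycles)
  check_trajectory(trajectory, cfg)
  if (mode == "coronal" && abs(trajectory$theta_H1[1]) > 1e-9)
    stop("coronal sessions must start at theta_H1 = 0 (reference posture)")
  n <- nrow(trajectory)
  frames <- vector("list", n)
  labels <- if (store_labels) vector("list", n) else NULL
  visible <- logical(n)
  min_vis <- numeric(n)
  for (j in seq_len(n)) {
    strips <- pose_leg(trajectory[j, ], cfg)
    r <- render_frame(strips, cfg, noise, timestamp = (j - 1) / cfg$fps,
                      frame_index = j, store_label = store_labels)
    frames[[j]] <- r$frame
    visible[j] <- all(r$visibility > 0)
    min_vis[j] <- min(r$visibility)
    if (store_labels) labels[[j]] <- r$label
  }
  if (mean(!visible) > cfg$max_invisible_frac)
    stop(sprintf("generation error: %.0f%% of frames have an invisible marker",
                 100 * mean(!visible)))
  truth <- data.frame(frame = seq_len(n), time_s = (seq_len(n) - 1) / cfg$fps,
                      theta_H2 = trajectory$theta_H2,
                      theta_2 = trajectory$theta_2,
                      theta_H1 = trajectory$theta_H1,
                      visible = visible,
                      min_visibility = min_vis)
  seg <- segmentation_config(role_colors = cfg$role_colors)
  structure(list(mode = mode, frames = frames, truth = truth, cfg = cfg,
                 noise = noise, rig = cfg$rig, seg = seg, seed = seed,
                 labels = labels),
            class = "rom_session")
}

#' @export
print.rom_session <- function(x, ...) {
  cat(sprintf("rom_session: mode=%s, %d frames, %dx%d color / %dx%d depth\n",
              x$mode, length(x$frames), x$rig$color$width, x$rig$color$height,
              x$rig$depth$width, x$rig$depth$height))
  invisible(x)
}

#' Run the measurement chain on a generated session
#'
#' Convenience wrapper: builds the sagittal working frame from a calibration
#' session (for the sagittal modes) and computes the session's joint-angle
#' series with its own rig and segmentation settings.
#'
#' @param session `rom_session` to measure.
#' @param calibration `rom_session` of mode "calibration" (required for
#'   sagittal sessions).
#' @param ... Passed on to [compute_sagittal_series()] or
#'   [compute_coronal_series()].
#' @return A `joint_angle_series`.
#' @export
measure_session <- function(session, calibration = NULL, ...) {
  stopifnot(inherits(session, "rom_session"))
  if (session$mode == "coronal")
    return(compute_coronal_series(session$frames, session$rig, session$seg,
                                  fps = session$cfg$fps, ...))
  if (is.null(calibration))
    stop("sagittal sessions need a calibration session to build the working frame")
  fr <- build_reference_frame(calibration$frames, calibration$rig,
                              calibration$seg)
  compute_sagittal_series(session$frames, session$rig, session$seg, fr,
                          fps = session$cfg$fps, ...)
}
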