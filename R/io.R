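# File formats: calibration YAML, on-disk frame sequences, angle traces.
#
# Calibration YAML keys:
#   color:  {fx, fy, u0, v0, width, height, distortion: [k1,k2,k3,p1,p2]}
#   depth:  {fx, fy, u0, v0, width, height, distortion: [k1,k2,k3,p1,p2]}
#   registration: {R: 9 row-major values, t: [tx,ty,tz] meters}
#   depth_dialect: "tsv_mm" | "png16_mm"
#
# Color frames are 8-bit RGB PNG. Depth frames are either 16-bit grayscale
# PNG in millimeters ("png16_mm", read-only here) or plain-text TSV of
# integer millimeters ("tsv_mm", read and write); 0 marks invalid depth.

intr_to_list <- function(i, d) {
  list(fx = i$fx, fy = i$fy, u0 = i$u0, v0 = i$v0,
       width = i$width, height = i$height,
       distortion = as.numeric(unlist(d)))
}

intr_from_list <- function(x) {
  list(intr = camera_intrinsics(x$fx, x$fy, x$u0, x$v0, x$width, x$height),
       dist = do.call(distortion_coefficients,
                      as.list(setNames(as.numeric(x$distortion),
                                       c("k1", "k2", "k3", "p1", "p2")))))
}

#' Read / write camera calibration files
#'
#' @param path YAML file path.
#' @param rig `camera_rig` to write.
#' @param depth_dialect On-disk depth format declared in the file.
#' @return `read_calibration` returns a list with `rig` and `depth_dialect`;
#'   `write_calibration` returns `path` invisibly.
#' @export
read_calibration <- function(path) {
  x <- yaml::read_yaml(path)
  col <- intr_from_list(x$color)
  dep <- intr_from_list(x$depth)
  R <- matrix(as.numeric(x$registration$R), 3, 3, byrow = TRUE)
  # calibration files carry finite precision; polish to the nearest rotation
  if (max(abs(crossprod(R) - diag(3))) < 1e-6) {
    s <- svd(R)
    R <- s$u %*% t(s$v)
    if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  }
  reg <- extrinsic_registration(R, as.numeric(x$registration$t))
  list(rig = camera_rig(col$intr, dep$intr, col$dist, dep$dist, reg),
       depth_dialect = if (is.null(x$depth_dialect)) "tsv_mm" else x$depth_dialect)
}

#' @rdname read_calibration
#' @export
write_calibration <- function(rig, path, depth_dialect = "tsv_mm") {
  x <- list(color = intr_to_list(rig$color, rig$color_dist),
            depth = intr_to_list(rig$depth, rig$depth_dist),
            registration = list(R = as.numeric(t(rig$registration$R)),
                                t = rig$registration$t),
            depth_dialect = depth_dialect)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

read_depth_file <- function(path, dialect) {
  if (dialect == "png16_mm") {
    z <- png::readPNG(path)
    if (length(dim(z)) == 3) z <- z[, , 1]
    return(z * 65535 / 1000)
  }
  if (dialect == "tsv_mm") {
    z <- as.matrix(utils::read.table(path, sep = "\t"))
    dimnames(z) <- NULL
    return(z / 1000)
  }
  stop("unknown depth dialect: ", dialect)
}

write_depth_file <- function(depth, path) {
  mm <- round(depth * 1000)
  mm[!is.finite(mm)] <- 0
  utils::write.table(mm, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
}

#' Write a generated session to a directory
#'
#' Emits color PNGs (`frame_0001.png`, ...), depth TSVs in millimeters
#' (`depth_0001.tsv`), the calibration YAML (`calibration.yaml`), the
#' ground-truth CSV (`truth.csv`) and the session metadata
#' (`session.yaml`).
#'
#' @param session `rom_session`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (j in seq_along(session$frames)) {
    f <- session$frames[[j]]
    img <- array(as.integer(f$color), dim = dim(f$color)) / 255
    png::writePNG(img, file.path(dir, sprintf("frame_%04d.png", j)))
    write_depth_file(f$depth, file.path(dir, sprintf("depth_%04d.tsv", j)))
  }
  write_calibration(session$rig, file.path(dir, "calibration.yaml"))
  utils::write.csv(session$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  yaml::write_yaml(list(mode = session$mode, fps = session$cfg$fps,
                        seed = session$seed,
                        noise = unclass(session$noise),
                        role_colors = session$cfg$role_colors),
                   file.path(dir, "session.yaml"))
  invisible(dir)
}

#' Read an on-disk frame sequence
#'
#' Loads the frames written by [write_session()] (or arranged the same way:
#' paired `frame_NNNN.png` / `depth_NNNN.*` files plus `calibration.yaml`).
#'
#' @param dir Directory path.
#' @return List with `frames` (list of `rgbd_frame`), `rig`, `fps`, and
#'   `seg` when the directory carries segmentation metadata.
#' @export
read_session <- function(dir) {
  cal <- read_calibration(file.path(dir, "calibration.yaml"))
  colf <- sort(list.files(dir, "^frame_\\d+\\.png$", full.names = TRUE))
  ext <- if (cal$depth_dialect == "png16_mm") "png" else "tsv"
  meta <- if (file.exists(file.path(dir, "session.yaml")))
    yaml::read_yaml(file.path(dir, "session.yaml")) else list()
  fps <- if (is.null(meta$fps)) 30 else meta$fps
  frames <- vector("list", length(colf))
  for (j in seq_along(colf)) {
    img <- png::readPNG(colf[j])
    if (dim(img)[3] == 4) img <- img[, , 1:3]
    depth <- read_depth_file(
      file.path(dir, sprintf("depth_%04d.%s", j, ext)), cal$depth_dialect)
    frames[[j]] <- rgbd_frame(round(img * 255), depth,
                              timestamp = (j - 1) / fps, frame_index = j)
  }
  seg <- NULL
  if (!is.null(meta$role_colors))
    seg <- segmentation_config(role_colors = meta$role_colors)
  list(frames = frames, rig = cal$rig, fps = fps, seg = seg)
}

#' Write per-frame angles and ROM summary
#'
#' `write_series` emits the per-frame angle CSV (frame, time_s, theta_k_deg,
#' theta_x_deg, theta_kg_deg, flags); `write_rom_json` emits the ROM summary
#' as JSON.
#'
#' @param series `joint_angle_series`.
#' @param rom `rom_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  out <- data.frame(frame = series$frame, time_s = series$time_s,
                    theta_k_deg = series$theta_k,
                    theta_x_deg = series$theta_x,
                    theta_kg_deg = series$theta_kg,
                    flags = series$flag)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @export
write_rom_json <- function(rom, path) {
  jsonlite::write_json(unclass(rom), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a reference angle-sensor trace
#'
#' CSV with columns `time_s`, `angle_deg` (the format emitted by serial
#' angle transducers: time and angle).
#'
#' @param path CSV path.
#' @return Data frame with `time_s`, `angle_deg`.
#' @export
read_reference_trace <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time_s", "angle_deg") %in% names(d)))
  d[c("time_s", "angle_deg")]
}
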