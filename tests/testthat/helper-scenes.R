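# Shared fixtures: a reduced-resolution rig for fast end-to-end tests and
# small helpers. All image data is generated in code at test time.

small_rig <- function(t = c(0.015, 0, 0)) {
  camera_rig(
    color = camera_intrinsics(450, 450, 320, 180, 640, 360),
    depth = camera_intrinsics(365, 365, 256, 192, 512, 384),
    registration = extrinsic_registration(diag(3), t))
}

small_cfg <- function(...) {
  args <- list(...)
  if (is.null(args$rig)) args$rig <- small_rig()
  if (is.null(args$sample_step)) args$sample_step <- 1e-3
  do.call(leg_scene_config, args)
}

truth_trace <- function(session, channel) {
  data.frame(time_s = session$truth$time_s,
             angle_deg = session$truth[[channel]])
}

# random rotation matrix, angle <= max_deg about a random axis
random_rotation <- function(max_deg) {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  a <- runif(1, 0, max_deg) * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * K %*% K
}

expect_unit <- function(v, tol = 1e-9) {
  expect_equal(sum(v^2), 1, tolerance = tol)
}
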