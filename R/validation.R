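# Simulated replication of the precision-verification experiment: a mechanical
# two-link leg oscillates one joint while the other is held, the vision chain
# measures the angle trace, and the peak angles are compared against the
# ground truth (standing in for the reference angle transducer).

#' Replicate the precision-verification experiment in simulation
#'
#' `replicate_sagittal_validation` oscillates the calf through triangular
#' knee cycles spanning 0-90 degrees with the thigh held still, runs the full
#' sagittal measurement chain on the rendered frames (calibration sweep
#' included), and compares the measured knee-angle peaks against the
#' ground-truth peaks. `replicate_coronal_validation` oscillates hip
#' abduction between 0 and 40 degrees with the knee bent at 45 degrees,
#' applies the median-average filter to the measured trace, and compares its
#' peaks the same way. Defaults reproduce the study conditions: 1280x720
#' color frames, camera 1.2 m from the sagittal plane, 5 mm depth noise
#' (the depth accuracy of the camera at ~1 m), color noise of 5 gray levels.
#'
#' @param seed RNG seed for the rendered session.
#' @param cfg `leg_scene_config`.
#' @param noise `noise_spec`.
#' @param cycles Oscillation cycles.
#' @param frames_per_cycle Frames per triangular knee cycle.
#' @param filter_window Median-average filter window (coronal).
#' @return A `peak_comparison` (see [compare_with_reference()]); its
#'   `max_abs_delta` attribute is the replication's headline error.
#' @export
replicate_sagittal_validation <- function(seed, cfg = leg_scene_config(),
                                          noise = noise_spec(), cycles = 6,
                                          frames_per_cycle = 12) {
  cal <- generate_session("calibration", cfg, noise, seed = seed)
  ses <- generate_session("sagittal-knee", cfg, noise, seed = seed + 500,
                          trajectory = make_trajectory(
                            hip = -10,
                            knee = wave_triangle(0, 90, cycles,
                                                 frames_per_cycle)))
  ser <- measure_session(ses, cal)
  compare_with_reference(ser,
                         data.frame(time_s = ses$truth$time_s,
                                    angle_deg = ses$truth$theta_2),
                         channel = "theta_x")
}

#' @rdname replicate_sagittal_validation
#' @export
replicate_coronal_validation <- function(seed, cfg = leg_scene_config(),
                                         noise = noise_spec(), cycles = 6,
                                         filter_window = 5) {
  ses <- generate_session("coronal", cfg, noise, seed = seed,
                          trajectory = make_trajectory(
                            hip = -10, knee = 45,
                            coronal = wave_trapezoid(0, 40, cycles)))
  ser <- compute_coronal_series(ses$frames, ses$rig, ses$seg,
                                fps = ses$cfg$fps,
                                filter_window = filter_window)
  compare_with_reference(ser,
                         data.frame(time_s = ses$truth$time_s,
                                    angle_deg = ses$truth$theta_H1),
                         channel = "theta_kg")
}
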