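test_that("median-average filter drops window extremes and keeps structure", {
  # impulse rejected: drop the 100 and one 0, mean of the rest is 0
  x <- c(0, 0, 100, 0, 0)
  expect_equal(median_average_filter(x, 5)[3], 0)
  # constant series unchanged
  expect_equal(median_average_filter(rep(7, 10), 5), rep(7, 10))
  # linear ramp unchanged at interior samples (symmetric windows)
  r <- as.numeric(1:7)
  expect_equal(median_average_filter(r, 3)[2:6], r[2:6])
  expect_equal(median_average_filter(r, 5)[3:5], r[3:5])
  # missing values are excluded, not propagated
  xm <- c(1, NA, 1, 1, 1)
  expect_true(all(is.finite(median_average_filter(xm, 3))))
  # window validation
  expect_error(median_average_filter(1:10, 4), "odd")
  expect_error(median_average_filter(1:10, 1), "odd")
  expect_error(median_average_filter(1:3, 5), "odd")
})

test_that("filtering never amplifies the extremes of a series", {
  set.seed(51)
  for (rep in 1:20) {
    x <- cumsum(rnorm(60)) + rnorm(60, 0, 3)
    f <- median_average_filter(x, 5)
    expect_lte(max(f), max(x))
    expect_gte(min(f), min(x))
  }
})

test_that("ROM extraction reports extrema with their frames", {
  s <- structure(data.frame(frame = 1:5, time_s = 0:4,
                            theta_k = c(0, 10, 45, 30, -5),
                            theta_x = NA_real_, theta_kg = NA_real_,
                            flag = ""),
                 class = c("joint_angle_series", "data.frame"))
  r <- extract_rom(s)
  expect_equal(names(r), "theta_k")
  expect_equal(r$theta_k$max, 45); expect_equal(r$theta_k$frame_max, 3)
  expect_equal(r$theta_k$min, -5); expect_equal(r$theta_k$frame_min, 5)
  expect_equal(r$theta_k$n_valid, 5)
  # single sample: max = min
  s1 <- s[3, ]; class(s1) <- class(s)
  r1 <- extract_rom(s1)
  expect_equal(r1$theta_k$max, r1$theta_k$min)
  # missing values interleaved are skipped
  s$theta_k[3] <- NA
  r2 <- extract_rom(s)
  expect_equal(r2$theta_k$max, 30)
  expect_equal(r2$theta_k$n_valid, 4)
  s$theta_k[] <- NA
  expect_error(extract_rom(s), "no valid data")
})

test_that("peak detection finds alternating extrema with prominence", {
  # one triangular oscillation: a single maximum at the apex
  tri <- c(seq(0, 40, 10), seq(30, 0, -10))
  p <- detect_peaks(tri, 5)
  expect_equal(nrow(p), 1)
  expect_equal(p$type, "max")
  expect_equal(p$index, 5)
  expect_equal(p$value, 40)
  # monotone series has no peaks
  expect_equal(nrow(detect_peaks(seq(0, 50, 5), 5)), 0)
  expect_equal(nrow(detect_peaks(seq(50, 0, -5), 5)), 0)
  # plateau reports its center sample
  pl <- c(0, 10, 20, 30, 30, 30, 20, 10, 0)
  pp <- detect_peaks(pl, 5)
  expect_equal(pp$index, 5)
  # 5-cycle sinusoid: 5 maxima, 4-5 minima, at the analytic extrema
  x <- wave_sine(0, 40, 5, 20)
  ps <- detect_peaks(x, 5)
  mx <- ps[ps$type == "max", ]; mn <- ps[ps$type == "min", ]
  expect_equal(nrow(mx), 5)
  expect_true(nrow(mn) %in% 4:5)
  expect_true(all(abs(mx$index - (c(0:4) * 20 + 11)) <= 1))
  expect_true(all(abs(mx$value - 40) < 1e-9))
  # alternation
  expect_true(all(abs(diff(match(ps$type[order(ps$index)], c("min", "max")))) == 1))
})

test_that("peak comparison matches by time and differences the values", {
  x <- wave_sine(0, 40, 4, 20)
  tr <- data.frame(time_s = seq_along(x) / 10, angle_deg = x)
  same <- compare_with_reference(tr, tr)
  expect_true(all(same$delta == 0))
  shifted <- tr; shifted$angle_deg <- shifted$angle_deg + 2
  cmp <- compare_with_reference(tr, shifted)
  expect_true(all(abs(cmp$delta + 2) < 1e-12))
  expect_equal(max_abs_delta(cmp), 2)
  # disjoint traces produce an empty comparison with a warning
  late <- tr; late$time_s <- late$time_s + 1000
  expect_warning(res <- compare_with_reference(tr, late, gate_s = 1),
                 "no matchable peaks")
  expect_equal(nrow(res), 0)
})

test_that("noiseless sagittal pipeline recovers constant ground truth", {
  cfg <- small_cfg()
  cal <- generate_session("calibration", cfg, noise_none(), seed = 61)
  ses <- generate_session("sagittal-knee", cfg, noise_none(), seed = 62,
                          trajectory = make_trajectory(hip = -30, knee = 60,
                                                       coronal = 0)[rep(1, 4), ])
  ser <- measure_session(ses, cal)
  expect_true(all(ser$flag == ""))
  expect_lt(max(abs(ser$theta_k + 30)), 1.0)
  expect_lt(max(abs(ser$theta_x - 60)), 1.0)
  # calibration posture: thigh along the seat line, knee straight -> both ~0
  ses0 <- generate_session("sagittal-knee", cfg, noise_none(), seed = 63,
                           trajectory = make_trajectory(hip = 0, knee = 0)[rep(1, 3), ])
  ser0 <- measure_session(ses0, cal)
  expect_lt(max(abs(ser0$theta_k)), 1.0)
  expect_lt(max(abs(ser0$theta_x)), 1.0)
})

test_that("an occluded marker yields a flagged frame, not an abort", {
  cfg <- small_cfg()
  cal <- generate_session("calibration", cfg, noise_none(), seed = 64)
  ses <- generate_session("sagittal-knee", cfg, noise_none(), seed = 65,
                          trajectory = make_trajectory(hip = -10, knee = 45)[rep(1, 3), ])
  # paint the calf strip over with background in frame 2
  f2 <- ses$frames[[2]]
  mask <- color_distance_mask(f2$color, cfg$role_colors$calf, 60)
  col <- array(as.integer(f2$color), dim = dim(f2$color))
  for (ch in 1:3) {
    plane <- col[, , ch]
    plane[mask != 0] <- cfg$background_color[ch]
    col[, , ch] <- plane
  }
  ses$frames[[2]] <- rgbd_frame(col, f2$depth, f2$timestamp, f2$frame_index)
  ser <- measure_session(ses, cal)
  expect_equal(ser$flag[2], "marker-lost:calf")
  expect_true(is.na(ser$theta_x[2]))
  expect_true(all(ser$flag[-2] == ""))
  expect_false(any(is.na(ser$theta_x[-2])))
})

test_that("coronal series is zero-referenced and recovers an abduction sweep", {
  cfg <- small_cfg()
  ses <- generate_session("coronal", cfg, noise_none(), seed = 66,
                          trajectory = make_trajectory(
                            hip = -10, knee = 45,
                            coronal = c(wave_linear(0, 40, 8), 40, 40)))
  ser <- compute_coronal_series(ses$frames, ses$rig, ses$seg, fps = cfg$fps,
                                filter_window = NULL)
  expect_equal(ser$theta_kg[1], 0)
  expect_lt(max(abs(ser$theta_kg - ses$truth$theta_H1)), 1.0)
  # straight knee -> degenerate plane error naming the remedy
  ses2 <- generate_session("coronal", cfg, noise_none(), seed = 67,
                           trajectory = make_trajectory(hip = -10, knee = 0,
                                                        coronal = 0)[rep(1, 3), ])
  expect_error(compute_coronal_series(ses2$frames, ses2$rig, ses2$seg),
               "bend the knee")
})

test_that("sagittal angles tolerate out-of-plane marker offsets", {
  cfg1 <- small_cfg()
  cfg2 <- small_cfg(marker_offset = 0.08)  # 2 cm further off the plane
  cal <- generate_session("calibration", cfg1, noise_none(), seed = 68)
  t1 <- make_trajectory(hip = -15, knee = 50)[rep(1, 2), ]
  sa <- measure_session(generate_session("sagittal-knee", cfg1, noise_none(),
                                         seed = 69, trajectory = t1), cal)
  sb <- measure_session(generate_session("sagittal-knee", cfg2, noise_none(),
                                         seed = 69, trajectory = t1), cal)
  expect_lt(max(abs(sa$theta_x - sb$theta_x)), 0.35)
  expect_lt(max(abs(sa$theta_k - sb$theta_k)), 0.35)
})

test_that("empty frame lists are rejected", {
  cfg <- small_cfg()
  seg <- segmentation_config(role_colors = cfg$role_colors)
  expect_error(compute_sagittal_series(list(), small_rig(), seg, NULL),
               "empty input")
  expect_error(compute_coronal_series(list(), small_rig(), seg),
               "empty input")
})
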