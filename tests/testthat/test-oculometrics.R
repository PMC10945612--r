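tj_default <- target_trajectory(duration = 10)

test_that("screening applies the strict 10% missing-data rule", {
  tr15 <- simulate_gaze_trace(target_trajectory(duration = 30),
                              gaze_sim_params(missing_fraction = 0.15,
                                              seed = 2))
  v <- screen_trace(tr15)
  expect_false(v$valid)
  expect_identical(v$reasons, "missing_fraction_exceeded")

  clean <- simulate_gaze_trace(tj_default, gaze_sim_params(seed = 1))
  vc <- screen_trace(clean)
  expect_true(vc$valid)
  expect_identical(vc$reasons, character(0))

  # exactly 10.0% invalid stays valid (strict inequality)
  tr10 <- clean
  n <- length(tr10$valid)
  kill <- seq_len(n / 10)
  tr10$valid[kill] <- FALSE
  tr10$x[kill] <- NA; tr10$y[kill] <- NA
  v10 <- screen_trace(tr10)
  expect_equal(v10$missing_fraction, 0.10)
  expect_true(v10$valid)
})

test_that("screening flags calibration offsets and head-position jumps", {
  off <- simulate_gaze_trace(tj_default,
                             gaze_sim_params(calibration_offset = c(3.5, 0),
                                             seed = 1))
  expect_true("calibration_artifact" %in% screen_trace(off)$reasons)

  # a 6-degree step in gaze-minus-target halfway through the record
  jump <- simulate_gaze_trace(tj_default, gaze_sim_params(seed = 1))
  half <- seq_along(jump$x) > length(jump$x) / 2
  jump$x[half] <- jump$x[half] + 6
  expect_true("head_instability" %in% screen_trace(jump)$reasons)

  # verdict on the simulator is predictable from the injected missing count
  pars <- gaze_sim_params(missing_fraction = 0.12, seed = 5)
  tr <- simulate_gaze_trace(target_trajectory(duration = 30), pars)
  expect_identical(screen_trace(tr)$valid,
                   attr(tr, "sim")$n_invalid / length(tr$valid) <= 0.10)
})

test_that("target-frame errors follow the closed-form geometry", {
  tj <- target_trajectory(duration = 2)
  times <- (seq_len(1000) - 1) / tj$sample_rate

  ident <- simulate_gaze_trace(tj, gaze_sim_params(seed = 1))
  e0 <- to_target_frame(ident)
  expect_lt(max(abs(e0$radial_error)), 1e-12)
  expect_lt(max(abs(e0$tangential_error)), 1e-12)
  expect_lt(max(abs(e0$phase_error)), 1e-12)

  # gaze at 11 deg radius on the target's angle: radial +1, tangential 0
  th <- pursuitrisk:::target_angle(tj, ident$times)
  out <- manual_trace(11 * cos(th), 11 * sin(th), tj)
  eo <- to_target_frame(out)
  expect_equal(eo$radial_error, rep(1, length(th)), tolerance = 1e-12)
  expect_lt(max(abs(eo$tangential_error)), 1e-12)

  # gaze rotated +5 degrees of arc ahead (counterclockwise motion)
  rot <- manual_trace(10 * cos(th + 5 * pi / 180),
                      10 * sin(th + 5 * pi / 180), tj)
  er <- to_target_frame(rot)
  expect_equal(er$phase_error[1], 5, tolerance = 1e-9)
  expect_equal(er$radial_error[1], 10 * (cos(5 * pi / 180) - 1),
               tolerance = 1e-9)
  expect_equal(er$tangential_error[1], 10 * sin(5 * pi / 180),
               tolerance = 1e-9)

  # gaze at the origin: phase undefined, radial retained
  orig <- manual_trace(rep(0, 1000), rep(0, 1000),
                       target_trajectory(duration = 2))
  eor <- to_target_frame(orig)
  expect_true(all(is.na(eor$phase_error)))
  expect_equal(eor$radial_error, rep(-10, 1000), tolerance = 1e-12)
})

test_that("saccade detection finds injected segments and respects the strict threshold", {
  # perfect pursuit of the default target: speed ~ 25 deg/s, below threshold
  clean <- simulate_gaze_trace(tj_default, gaze_sim_params(seed = 1))
  expect_identical(nrow(detect_saccades(clean)), 0L)

  # one injected 20-ms ballistic segment at 200 deg/s (4-degree jump)
  tr <- clean
  t0 <- 5; dur <- 0.02; speed <- 200
  rel <- tr$times - t0
  disp <- ifelse(rel < 0, 0, ifelse(rel <= dur, speed * rel, speed * dur))
  tr$x <- tr$x + disp
  iv <- detect_saccades(tr)
  expect_identical(nrow(iv), 1L)
  expect_lte(iv[1, "start"], t0 + 0.002)
  expect_gte(iv[1, "end"], t0 + dur - 0.002)
  expect_lt(iv[1, "end"] - iv[1, "start"], dur + 0.08)

  # plateau exactly at the threshold is not flagged (strict inequality)
  tjl <- target_trajectory(duration = 2)
  tt <- (seq_len(1000) - 1) / tjl$sample_rate
  line <- manual_trace(30 * tt, 40 * tt, tjl)  # speed exactly 50 deg/s
  expect_identical(nrow(detect_saccades(line)), 0L)
})

test_that("pursuit metrics recover identity, delay, noise and gain ground truth", {
  ident <- simulate_gaze_trace(target_trajectory(duration = 10),
                               gaze_sim_params(seed = 1))
  m <- compute_pursuit_metrics(ident)
  expect_equal(m$sd_radial, 0, tolerance = 1e-10)
  expect_equal(m$sd_tangential, 0, tolerance = 1e-10)
  expect_equal(m$mean_radial_error, 0, tolerance = 1e-10)
  expect_equal(m$phase_error_mean, 0, tolerance = 1e-10)
  expect_equal(m$gain_h, 1, tolerance = 1e-3)
  expect_equal(m$gain_v, 1, tolerance = 1e-3)

  # pure 50 ms delay at 0.4 Hz: phase lag of 360 * 0.4 * 0.05 = 7.2 degrees
  del <- delayed_trace(target_trajectory(duration = 10), 0.05)
  md <- compute_pursuit_metrics(del)
  expect_equal(md$phase_error_mean, -7.2, tolerance = 1e-6)

  # radial noise of known SD is recovered by sd_radial
  nz <- simulate_gaze_trace(target_trajectory(duration = 30),
                            gaze_sim_params(radial_noise_sd = 0.5, seed = 11))
  expect_lt(abs(compute_pursuit_metrics(nz)$sd_radial - 0.5), 0.05)

  # simulated gains recovered within 0.03 under moderate noise
  for (g in c(0.6, 1.1)) {
    tr <- simulate_gaze_trace(target_trajectory(duration = 30),
                              gaze_sim_params(gain_h = g, gain_v = g,
                                              radial_noise_sd = 0.3,
                                              tangential_noise_sd = 0.3,
                                              seed = 42))
    mg <- compute_pursuit_metrics(tr)
    expect_lt(abs(mg$gain_h - g), 0.03)
    expect_lt(abs(mg$gain_v - g), 0.03)
  }
})

test_that("metrics are rotation-equivariant and direction-symmetric", {
  tj <- target_trajectory(duration = 10, phase_origin = 0)
  pars <- gaze_sim_params(gain_h = 0.9, gain_v = 0.9, phase_offset = -4,
                          radial_noise_sd = 0.2, tangential_noise_sd = 0.2,
                          seed = 8)
  tr <- simulate_gaze_trace(tj, pars)
  m <- compute_pursuit_metrics(tr)

  # rotate gaze and target by the same fixed angle
  ang <- 0.7
  tj_rot <- target_trajectory(duration = 10, phase_origin = ang)
  tr_rot <- tr
  tr_rot$x <- tr$x * cos(ang) - tr$y * sin(ang)
  tr_rot$y <- tr$x * sin(ang) + tr$y * cos(ang)
  tr_rot$trajectory <- tj_rot
  m_rot <- compute_pursuit_metrics(tr_rot)
  expect_equal(m_rot$sd_radial, m$sd_radial, tolerance = 1e-8)
  expect_equal(m_rot$sd_tangential, m$sd_tangential, tolerance = 1e-8)
  expect_equal(m_rot$mean_radial_error, m$mean_radial_error, tolerance = 1e-8)
  expect_equal(m_rot$phase_error_mean, m$phase_error_mean, tolerance = 1e-8)

  # mirror the whole scene across the x axis: the direction label flips but
  # the physics (a lag stays a lag) does not — all signed metrics are
  # invariant because their sign conventions are anchored to the motion
  tj_cw <- target_trajectory(duration = 10, direction = "clockwise")
  tr_cw <- tr
  tr_cw$y <- -tr$y
  tr_cw$trajectory <- tj_cw
  m_cw <- compute_pursuit_metrics(tr_cw)
  expect_equal(m_cw$phase_error_mean, m$phase_error_mean, tolerance = 1e-8)
  expect_equal(m_cw$sd_radial, m$sd_radial, tolerance = 1e-8)
  expect_equal(m_cw$sd_tangential, m$sd_tangential, tolerance = 1e-8)
  expect_equal(m_cw$gain_h, m$gain_h, tolerance = 1e-8)
  expect_equal(m_cw$gain_v, m$gain_v, tolerance = 1e-8)
  e <- to_target_frame(tr)
  e_cw <- to_target_frame(tr_cw)
  expect_equal(e_cw$tangential_error, e$tangential_error, tolerance = 1e-8)
  expect_equal(e_cw$radial_error, e$radial_error, tolerance = 1e-8)

  # relabelling the direction for a fixed spatial offset negates the signed
  # lead/lag quantities: a gaze 5 degrees counterclockwise of the target is
  # a lead under ccw motion and a lag under cw motion
  for (dir in c("counterclockwise", "clockwise")) {
    tjd <- target_trajectory(duration = 2, direction = dir)
    times <- (seq_len(1000) - 1) / tjd$sample_rate
    th <- pursuitrisk:::target_angle(tjd, times)
    g <- manual_trace(10 * cos(th + 5 * pi / 180),
                      10 * sin(th + 5 * pi / 180), tjd)
    ph <- to_target_frame(g)$phase_error[1]
    expect_equal(ph, if (dir == "counterclockwise") 5 else -5,
                 tolerance = 1e-9)
  }
})

test_that("desaccading keeps gain estimates stable under injected saccades", {
  tj <- target_trajectory(duration = 30)
  base <- compute_pursuit_metrics(
    simulate_gaze_trace(tj, gaze_sim_params(seed = 3)))
  sac <- compute_pursuit_metrics(
    simulate_gaze_trace(tj, gaze_sim_params(saccade_rate = 1, seed = 3)))
  expect_lt(abs(sac$gain_h - base$gain_h), 0.02)
  expect_lt(abs(sac$gain_v - base$gain_v), 0.02)
})

test_that("invalid records yield a verdict with absent metrics, short records error", {
  bad <- simulate_gaze_trace(target_trajectory(duration = 30),
                             gaze_sim_params(missing_fraction = 0.2, seed = 4))
  mb <- compute_pursuit_metrics(bad)
  expect_false(mb$verdict$valid)
  expect_true(is.na(mb$sd_radial))
  expect_true(is.na(mb$gain_h))

  short <- simulate_gaze_trace(target_trajectory(duration = 0.5),
                               gaze_sim_params(seed = 1))
  expect_error(compute_pursuit_metrics(short), "1 s of usable samples")
})
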