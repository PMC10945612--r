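test_that("noiseless unit-gain trace reproduces the target exactly and is seed-deterministic", {
  tj <- target_trajectory(duration = 5)
  tr <- simulate_gaze_trace(tj, gaze_sim_params(seed = 1))
  tp <- target_position(tj, tr$times)
  expect_equal(tr$x, unname(tp[, "x"]))
  expect_equal(tr$y, unname(tp[, "y"]))
  expect_true(all(tr$valid))

  pars <- gaze_sim_params(radial_noise_sd = 0.3, saccade_rate = 0.5,
                          missing_fraction = 0.1, seed = 99)
  a <- simulate_gaze_trace(tj, pars)
  b <- simulate_gaze_trace(tj, pars)
  expect_identical(a$x, b$x)
  expect_identical(a$valid, b$valid)
})

test_that("injected missingness hits the requested fraction in contiguous runs", {
  tj <- target_trajectory(duration = 30)
  tr <- simulate_gaze_trace(tj, gaze_sim_params(missing_fraction = 0.20,
                                                seed = 7))
  expect_lt(abs(mean(!tr$valid) - 0.20), 0.01)
  expect_true(all(is.na(tr$x[!tr$valid])))
  # blink-like: far fewer runs than invalid samples
  runs <- rle(tr$valid)
  expect_lt(sum(!runs$values), sum(!tr$valid) / 20)
})

test_that("gaze trace round-trips through its tab-delimited format", {
  tj <- target_trajectory(duration = 2, direction = "clockwise",
                          phase_origin = 0.5)
  tr <- simulate_gaze_trace(tj, gaze_sim_params(radial_noise_sd = 0.2,
                                                missing_fraction = 0.05,
                                                seed = 3), subject_id = "S1")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gaze_trace(tr, path)
  rt <- read_gaze_trace(path)
  expect_equal(rt$x, tr$x, tolerance = 1e-5)
  expect_identical(rt$valid, tr$valid)
  expect_identical(rt$subject_id, "S1")
  expect_equal(rt$trajectory$frequency, tj$frequency)
  expect_identical(rt$trajectory$direction, "clockwise")
})

test_that("simulated cohort marginals match their configuration", {
  co <- simulate_cohort(cohort_config(n_athletes = 50000, seed = 21))
  # concussion incidence within 3 binomial SEs of 2.9%
  se <- sqrt(0.029 * 0.971 / 50000)
  expect_lt(abs(mean(co$concussed) - 0.029), 3 * se)
  # age within 3 SEs of 18.6 (SD 3.0, light truncation at 12/30)
  expect_lt(abs(mean(co$age) - 18.6), 3 * 3.0 / sqrt(50000) + 0.02)
  expect_lt(abs(mean(co$male) - 0.62), 3 * sqrt(0.62 * 0.38 / 50000))
  expect_lt(abs(mean(co$prior_head_injury) - 0.275),
            3 * sqrt(0.275 * 0.725 / 50000))
  # pursuit-block missingness near its configured technical-failure rate
  expect_lt(abs(mean(is.na(co$sd_radial)) - 0.266), 0.02)
})

test_that("outcome generator recovers its own log-odds under refit and is null when slopes are zero", {
  # fidelity: refit the true specification on a cohort with many events
  cfg <- cohort_config(n_athletes = 6000, concussion_rate = 1,
                       missing_pursuit = 0, missing_cognitive = 0,
                       missing_rpq = 0, missing_psych = 0, seed = 5)
  co <- simulate_cohort(cfg)
  tr <- attr(co, "truth")
  X <- cbind(`(Intercept)` = 1, tr$design)
  m <- fit_logistic(X, tr$symptomatic)
  for (v in names(tr$coefficients)) {
    expect_lt(abs(m$coefficients[v] - tr$coefficients[v]), 3 * m$se[v])
  }
  # null case: zero slopes give mean refit slope ~ 0 across replicates
  est <- sapply(1:40, function(i) {
    cfg0 <- cohort_config(n_athletes = 600, concussion_rate = 1,
                          outcome_coefficients =
                            c(prior_head_injury = 0, sd_radial = 0),
                          missing_pursuit = 0, seed = 1000 + i)
    co0 <- simulate_cohort(cfg0)
    t0 <- attr(co0, "truth")
    f <- fit_logistic(cbind(`(Intercept)` = 1, t0$design[, names(t0$coefficients)]),
                      t0$symptomatic)
    f$coefficients[-1]
  })
  expect_lt(max(abs(rowMeans(est))), 0.05)
})

test_that("cohort config rejects coefficients for absent features", {
  expect_error(cohort_config(outcome_coefficients = c(shoe_size = 1)),
               "absent feature")
})

test_that("participant-flow fixture reproduces the reference flow exactly", {
  fx <- make_flow_fixture()
  expect_identical(nrow(fx), 3091L)
  expect_identical(sum(fx$concussed), 90L)
  expect_identical(sum(fx$concussed == 1 & fx$days_to_test > 14), 1L)
  eval_days <- fx$days_to_test[fx$concussed == 1 & fx$days_to_test <= 14]
  expect_length(eval_days, 89)
  expect_true(all(eval_days >= 0 & eval_days <= 14))
  expect_equal(mean(eval_days), 5.8, tolerance = 1e-12)
  # invariant across calls (pure function)
  expect_identical(fx, make_flow_fixture())
})

test_that("fixture scaling reduces counts proportionally with half-up rounding", {
  fs <- make_flow_fixture(scale = 0.1)
  fl <- assemble_analysis_sample(fs)$flow_counts
  expect_identical(fl$symptomatic, 4L)   # 3.5 rounds half up
  expect_identical(fl$resolved, 5L)      # 5.4 rounds down
  expect_identical(fl$concussed, 9L)
  expect_equal(mean(fs$days_to_test[fs$concussed == 1 & fs$days_to_test <= 14]),
               5.8, tolerance = 1e-12)
})
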