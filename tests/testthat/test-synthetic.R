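test_that("schedules are validated and contiguous", {
  s <- activity_schedule(c("none", "exercise", "none"), c(60, 300, 600))
  expect_equal(s$start_s, c(0, 60, 360))
  expect_equal(s$end_s, c(60, 360, 960))
  expect_error(activity_schedule(character(0), numeric(0)), "empty")
  expect_error(activity_schedule("jogging", 60), "modes")
  expect_error(activity_schedule("none", -5), "positive")
})

test_that("no-motion acceleration never approaches the spike threshold", {
  cfg <- rsc_config()
  acc <- generate_accel(activity_schedule("none", 60), cfg, seed = 4)
  expect_equal(nrow(acc), 1200L)
  dz <- abs(diff(lowpass_filter(acc$az_g, cfg$accel_beta))) * 1000
  expect_true(all(dz < 90))
})

test_that("normal activity produces excursions but no spikes", {
  cfg <- rsc_config()
  acc <- generate_accel(activity_schedule("normal", 300), cfg, seed = 5)
  dz_raw <- abs(diff(acc$az_g)) * 1000
  expect_gt(max(dz_raw), 15)  # jumps are present in the raw signal
  d <- classify_stream(acc, cfg)
  expect_true(all(!d$exercise))
})

test_that("exercise windows always reach the spike-count criterion", {
  cfg <- rsc_config()
  acc <- generate_accel(activity_schedule("exercise", 120), cfg, seed = 6)
  d <- classify_stream(acc, cfg)
  expect_equal(nrow(d), 3L)
  expect_true(all(d$count >= cfg$count_th))
  expect_true(all(d$exercise))
  # oracle agreement on the same stream
  expect_equal(d$count, oracle_window_counts(acc, cfg)$count)
})

test_that("generators are deterministic in the seed", {
  sched <- activity_schedule(c("normal", "exercise"), c(120, 120))
  expect_identical(generate_accel(sched, seed = 11),
                   generate_accel(sched, seed = 11))
  expect_false(identical(generate_accel(sched, seed = 11),
                         generate_accel(sched, seed = 12)))
  expect_identical(generate_temperature(sched, seed = 11),
                   generate_temperature(sched, seed = 11))
  expect_identical(generate_indoor(600, seed = 11),
                   generate_indoor(600, seed = 11))
})

test_that("noise-free temperature follows the relaxation model", {
  quiet <- activity_schedule("none", 1800)
  p0 <- temp_model_params(noise_sd = 0)
  t0 <- generate_temperature(quiet, p0, seed = 1)
  expect_true(all(t0$value_c == 36.5))

  # a long exercise bout plateaus at baseline + rise and never reaches
  # the elevated threshold
  long_ex <- activity_schedule(c("none", "exercise"), c(60, 4 * 3600))
  tex <- generate_temperature(long_ex, p0, seed = 1)
  expect_lt(max(tex$value_c), 37.5)
  expect_gt(max(tex$value_c), 36.95)
  expect_equal(max(tex$value_c), 37.0, tolerance = 1e-3)

  # fever ramp crosses the normal threshold once and stays above
  fever <- generate_temperature(
    quiet, temp_model_params(noise_sd = 0, fever_target = 38.0), seed = 1)
  above <- fever$value_c >= 37.0
  expect_equal(sum(diff(above) != 0), 1L)
  expect_true(all(above[which(above)[1L]:length(above)]))
})

test_that("baseline temperature noise matches the configured sd", {
  quiet <- activity_schedule("none", 3600)
  tt <- generate_temperature(quiet, temp_model_params(noise_sd = 0.2),
                             fs_hz = 0.2, seed = 8)
  expect_gte(nrow(tt), 500L)
  expect_gt(sd(tt$value_c), 0.15)
  expect_lt(sd(tt$value_c), 0.25)
})

test_that("indoor drift walks the humidity through low, ok and high", {
  ind <- generate_indoor(3600, temp_c = 22, rh_pct = 15, drift_rh = 50,
                         noise_sd_rh = 0, seed = 9)
  status <- indoor_check(ind$temp_c, ind$rh_pct)$rh
  expect_equal(unique(status), c("low", "ok", "high"))
  # transitions happen in order and only forward
  codes <- match(status, c("low", "ok", "high"))
  expect_true(all(diff(codes) >= 0))

  # steady near-reference morning conditions: temp ok, rh low throughout
  ind2 <- generate_indoor(600, temp_c = 23.5, rh_pct = 18, seed = 10)
  st2 <- indoor_check(ind2$temp_c, ind2$rh_pct)
  expect_true(all(st2$temp == "ok"))
  expect_true(all(st2$rh == "low"))
})
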