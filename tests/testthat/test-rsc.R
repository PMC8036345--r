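raw_cfg <- rsc_config(accel_beta = 1)

test_that("consecutive-difference and spike primitives behave at the boundary", {
  expect_equal(abs_delta_mg(1.00, 1.10), 100)
  expect_equal(abs_delta_mg(1.0, 1.0), 0)
  expect_equal(abs_delta_mg(1.10, 1.00), 100)  # symmetric
  expect_error(abs_delta_mg(1.0, NaN), "non-finite")

  cfg <- rsc_config()
  expect_true(is_spike(100, cfg))
  expect_false(is_spike(89.9, cfg))
  expect_true(is_spike(90, cfg))  # inclusive threshold
})

test_that("a window's spike count and verdict follow the constructed pattern", {
  d <- classify_stream(toggle_window_stream(25, 150, raw_cfg), raw_cfg)
  expect_equal(nrow(d), 1L)
  expect_equal(d$count, 25L)
  expect_true(d$exercise)

  # no motion: constant 1 g gives zero spikes
  d0 <- classify_stream(toggle_window_stream(0, 0, raw_cfg), raw_cfg)
  expect_equal(d0$count, 0L)
  expect_false(d0$exercise)

  # exactly count_th spikes already classifies as exercise
  d24 <- classify_stream(toggle_window_stream(24, 150, raw_cfg), raw_cfg)
  expect_equal(d24$count, 24L)
  expect_true(d24$exercise)
  d23 <- classify_stream(toggle_window_stream(23, 150, raw_cfg), raw_cfg)
  expect_false(d23$exercise)
})

test_that("decision cadence and trailing-window handling match the window grid", {
  cfg <- rsc_config()
  sched <- activity_schedule("none", 150)
  acc <- generate_accel(sched, cfg, seed = 3)
  d <- classify_stream(acc, cfg)
  expect_equal(nrow(d), 4L)  # floor((150 - 30) / 30)
  expect_equal(d$window_end_s, c(60, 90, 120, 150))
  expect_equal(unique(diff(d$window_end_s)), 30)

  # a partial trailing window yields no decision
  acc_part <- acc[acc$t_s < 135, ]
  expect_equal(nrow(classify_stream(acc_part, cfg)), 3L)

  # empty stream: empty result
  expect_equal(nrow(classify_stream(acc[0, ], cfg)), 0L)
})

test_that("streaming counts equal the brute-force oracle", {
  cfg <- rsc_config()
  set.seed(99)
  for (rep in 1:25) {
    n <- 20 * (60 + sample(0:120, 1))
    t <- (seq_len(n) - 1) / 20
    az <- 1 + rnorm(n, 0, 0.05)  # rough motion, many boundary cases
    acc <- data.frame(t_s = t, az_g = az)
    got <- classify_stream(acc, cfg)
    want <- oracle_window_counts(acc, cfg)
    expect_equal(got$window_end_s, want$window_end_s)
    expect_equal(got$count, want$count)
  }
})

test_that("raising either threshold never creates activity from nothing", {
  set.seed(17)
  n <- 20 * 150
  acc <- data.frame(t_s = (seq_len(n) - 1) / 20, az_g = 1 + rnorm(n, 0, 0.06))
  lo <- classify_stream(acc, rsc_config(dz_th_mg = 90))
  hi <- classify_stream(acc, rsc_config(dz_th_mg = 120))
  expect_true(all(hi$count <= lo$count))
  strict <- classify_stream(acc, rsc_config(count_th = 40))
  expect_true(all(!strict$exercise | lo$exercise))
})

test_that("inserting one large excursion adds at least one spike", {
  cfg <- raw_cfg
  base <- toggle_window_stream(5, 150, cfg)
  d_base <- classify_stream(base, cfg)
  mod <- base
  i <- cfg$warmup_s * cfg$fs_hz + 300L  # mid-window sample
  mod$az_g[i] <- mod$az_g[i] + 0.2     # >= dz_th away from both neighbors
  d_mod <- classify_stream(mod, cfg)
  expect_gte(d_mod$count, d_base$count + 1L)
})

test_that("a data dropout cannot fabricate a spike", {
  cfg <- raw_cfg
  t <- c(seq(0, 40, by = 0.05), seq(41.5, 70, by = 0.05))  # 1.5 s gap
  az <- c(rep(1.0, 801), rep(1.2, 571))  # 200 mg level shift across the gap
  d <- classify_stream(data.frame(t_s = t, az_g = az), cfg)
  expect_true(all(d$count == 0))
})

test_that("out-of-order samples are rejected with a diagnostic", {
  st <- rsc_state()
  st <- rsc_step(st, 1.00, 1.0)$state
  expect_error(rsc_step(st, 0.95, 1.0), "out-of-order")
})
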