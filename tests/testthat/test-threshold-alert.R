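decision <- function(end, exercise, count = if (exercise) 30L else 0L) {
  list(window_end_s = end, count = count, exercise = exercise)
}

test_that("the threshold follows activity and holds for 20 min after it", {
  cfg <- threshold_config()
  st <- threshold_state()

  out <- threshold_step(st, decision(60, TRUE), 60, cfg)
  expect_equal(out$t_th, 37.5)            # during exercise
  st <- out$state

  out <- threshold_step(st, decision(90, FALSE), 90, cfg)
  st <- out$state
  expect_equal(out$t_th, 37.5)            # 30 s after: inside the hold
  expect_equal(threshold_step(st, NULL, 60 + 10 * 60, cfg)$t_th, 37.5)
  expect_equal(threshold_step(st, NULL, 60 + 25 * 60, cfg)$t_th, 37.0)
  # reversion at the first evaluation >= hold_min after the window end
  expect_equal(threshold_step(st, NULL, 60 + 20 * 60 - 5, cfg)$t_th, 37.5)
  expect_equal(threshold_step(st, NULL, 60 + 20 * 60, cfg)$t_th, 37.0)
})

test_that("each new exercise window restarts the hold", {
  cfg <- threshold_config()
  st <- threshold_state()
  st <- threshold_step(st, decision(60, TRUE), 60, cfg)$state
  st <- threshold_step(st, decision(90, FALSE), 90, cfg)$state
  # 15 min into the hold a fresh exercise window arrives
  st <- threshold_step(st, decision(960, TRUE), 960, cfg)$state
  st <- threshold_step(st, decision(990, FALSE), 990, cfg)$state
  expect_equal(threshold_step(st, NULL, 960 + 19 * 60, cfg)$t_th, 37.5)
  expect_equal(threshold_step(st, NULL, 960 + 20 * 60, cfg)$t_th, 37.0)
})

test_that("the threshold only ever takes the two configured values", {
  cfg <- threshold_config()
  st <- threshold_state()
  set.seed(21)
  seen <- numeric(0)
  now <- 0
  for (i in 1:300) {
    now <- now + 30
    d <- if (runif(1) < 0.3) decision(now, runif(1) < 0.5) else NULL
    out <- threshold_step(st, d, now, cfg)
    st <- out$state
    seen <- c(seen, out$t_th)
  }
  expect_true(all(seen %in% c(37.0, 37.5)))
})

run_alert <- function(t, temp, t_th, cfg = alert_config()) {
  st <- alert_state()
  events <- list()
  for (i in seq_along(t)) {
    out <- alert_step(st, temp[i], t_th[i], t[i], cfg)
    st <- out$state
    events <- c(events, out$events)
  }
  data.frame(
    t_s = vapply(events, `[[`, numeric(1), "t_s"),
    kind = vapply(events, `[[`, character(1), "kind")
  )
}

test_that("a sustained exceedance raises one alert after the dwell time", {
  t <- seq(0, 20 * 60, by = 5)
  ev <- run_alert(t, rep(37.2, length(t)), rep(37.0, length(t)))
  raised <- ev[ev$kind == "alert_raised", ]
  expect_equal(nrow(raised), 1L)          # edge-triggered, once per episode
  expect_equal(raised$t_s, 12 * 60)
  expect_true("request_infrared_confirmation" %in% ev$kind)
  expect_equal(ev$t_s[ev$kind == "request_infrared_confirmation"], 12 * 60)
})

test_that("one sub-threshold sample restarts the dwell timer", {
  t <- seq(0, 20 * 60, by = 5)
  temp <- rep(37.2, length(t))
  temp[t == 6 * 60] <- 36.8
  ev <- run_alert(t, temp, rep(37.0, length(t)))
  raised <- ev[ev$kind == "alert_raised", ]
  expect_equal(nrow(raised), 1L)
  expect_gte(raised$t_s, 18 * 60)         # 6 min lost plus a fresh 12 min
})

test_that("streams that never reach the threshold emit nothing", {
  t <- seq(0, 30 * 60, by = 5)
  ev <- run_alert(t, rep(36.6, length(t)), rep(37.0, length(t)))
  expect_equal(nrow(ev), 0L)
})

test_that("an active alert clears on the first sub-threshold sample", {
  t <- seq(0, 30 * 60, by = 5)
  temp <- ifelse(t <= 15 * 60, 37.3, 36.7)
  ev <- run_alert(t, temp, rep(37.0, length(t)))
  expect_equal(ev$kind[ev$t_s == 12 * 60],
               c("alert_raised", "request_infrared_confirmation"))
  cleared <- ev[ev$kind == "alert_cleared", ]
  expect_equal(nrow(cleared), 1L)
  expect_equal(cleared$t_s, 15 * 60 + 5)
})

test_that("exercise raising the threshold mid-dwell clears the timer", {
  cfg <- alert_config()
  st <- alert_state()
  # 10 min of exceedance against the normal threshold...
  for (now in seq(0, 600, by = 5)) {
    st <- alert_step(st, 37.2, 37.0, now, cfg)$state
  }
  expect_false(is.na(st$exceed_since))
  # ...then exercise lifts the threshold above the body temperature
  st <- alert_step(st, 37.2, 37.5, 605, cfg)$state
  expect_true(is.na(st$exceed_since))
  # dwell must start over once the threshold drops back
  out <- alert_step(st, 37.2, 37.0, 610, cfg)
  expect_equal(out$state$exceed_since, 610)
  expect_equal(length(out$events), 0L)
})

test_that("dwell exactness: alert lands within one sample of the dwell time", {
  for (dt in c(1, 5, 30)) {
    t <- seq(0, 15 * 60, by = dt)
    step_at <- 60
    temp <- ifelse(t >= step_at, 37.4, 36.5)
    ev <- run_alert(t, temp, rep(37.0, length(t)))
    raised_t <- ev$t_s[ev$kind == "alert_raised"][1L]
    delay <- raised_t - step_at
    expect_gte(delay, 12 * 60)
    expect_lte(delay, 12 * 60 + dt)
  }
})

test_that("lowering the threshold or the dwell never delays an alert", {
  set.seed(31)
  t <- seq(0, 40 * 60, by = 5)
  for (rep in 1:10) {
    temp <- 36.9 + cumsum(rnorm(length(t), 0.0012, 0.01))
    first_alert <- function(th, dwell) {
      ev <- run_alert(t, temp, rep(th, length(t)), alert_config(dwell))
      r <- ev$t_s[ev$kind == "alert_raised"]
      if (length(r)) r[1L] else Inf
    }
    expect_lte(first_alert(36.8, 12), first_alert(37.0, 12))
    expect_lte(first_alert(37.0, 8), first_alert(37.0, 12))
  }
})

test_that("indoor classification is inclusive at all four bounds", {
  b <- indoor_bounds()
  expect_equal(indoor_check(23.5, 18, b), list(temp = "ok", rh = "low"))
  expect_equal(indoor_check(22, 40, b), list(temp = "ok", rh = "ok"))
  expect_equal(indoor_check(25, 40, b), list(temp = "high", rh = "ok"))
  # the printed limits are themselves in range
  expect_equal(indoor_check(20, 20, b), list(temp = "ok", rh = "ok"))
  expect_equal(indoor_check(24, 60, b), list(temp = "ok", rh = "ok"))
  expect_equal(indoor_check(24.1, 60.5, b), list(temp = "high", rh = "high"))
  expect_equal(indoor_check(19.9, 19.5, b), list(temp = "low", rh = "low"))
  expect_error(indoor_check(22, 120, b), "\\[0, 100\\]")
})
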