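#' Full monitor configuration
#'
#' Aggregates the configuration of every stage of the monitoring pipeline:
#' RSC exercise recognition, adaptive threshold, alert dwell, indoor
#' bounds, filter coefficients, optional thermometer calibration and the
#' telemetry cadence (one record every 5 s, the ambient sensor's update
#' period).
#'
#' @param rsc An [rsc_config()].
#' @param thresholds A [threshold_config()].
#' @param alert An [alert_config()].
#' @param indoor An [indoor_bounds()].
#' @param temp_beta Low-pass coefficient for the contact-thermometer
#'   stream (see [filter_state()]).
#' @param calibration A `calibration_model` from [calibrate_fit()], or
#'   `NULL` for uncalibrated readings.
#' @param telemetry_period_s Seconds between telemetry records.
#' @param seed Integer seed recorded with the configuration; the pipeline
#'   itself is deterministic, the seed is passed on to generators by the
#'   command-line tools.
#' @return An object of class `monitor_config`.
#' @export
monitor_config <- function(rsc = rsc_config(),
                           thresholds = threshold_config(),
                           alert = alert_config(),
                           indoor = indoor_bounds(),
                           temp_beta = 0.5,
                           calibration = NULL,
                           telemetry_period_s = 5,
                           seed = 0L) {
  stopifnot(inherits(rsc, "rsc_config"),
            inherits(thresholds, "threshold_config"),
            inherits(alert, "alert_config"),
            inherits(indoor, "indoor_bounds"),
            temp_beta >= 0, temp_beta <= 1, telemetry_period_s > 0)
  if (!is.null(calibration)) {
    stopifnot(inherits(calibration, "calibration_model"))
  }
  structure(list(rsc = rsc, thresholds = thresholds, alert = alert,
                 indoor = indoor, temp_beta = temp_beta,
                 calibration = calibration,
                 telemetry_period_s = telemetry_period_s,
                 seed = as.integer(seed)),
            class = "monitor_config")
}

#' Snapshot the monitor state into one telemetry record
#'
#' Telemetry is the flat payload a cloud dashboard would receive: the
#' alert and exercise Booleans encoded as integers 0/1, the latest
#' evaluated body temperature and the latest indoor conditions
#' (sample-and-hold).
#'
#' @param snapshot A list with logical `alert` and `exercise`, and numeric
#'   `t_body`, `t_indoor`, `rh`, `t_th`.
#' @param t Record time, seconds.
#' @return One-row data frame with columns `t_s`, `alert`, `t_body_c`,
#'   `t_indoor_c`, `rh_pct`, `exercise`, `t_th_c`.
#' @export
make_telemetry <- function(snapshot, t) {
  if (is.na(snapshot$t_body)) {
    stop("cannot emit telemetry before any body-temperature sample",
         call. = FALSE)
  }
  data.frame(t_s = t,
             alert = as.integer(isTRUE(snapshot$alert)),
             t_body_c = snapshot$t_body,
             t_indoor_c = snapshot$t_indoor,
             rh_pct = snapshot$rh,
             exercise = as.integer(isTRUE(snapshot$exercise)),
             t_th_c = snapshot$t_th)
}

#' Summary statistics of a monitoring session
#'
#' Minimum, maximum, mean and population standard deviation of the body
#' temperature held in the telemetry records.
#'
#' @param telemetry Telemetry data frame with column `t_body_c`.
#' @return A list with `min_c`, `max_c`, `mean_c`, `std_c`, `n`.
#' @export
summarize_session <- function(telemetry) {
  stopifnot(is.data.frame(telemetry))
  if (nrow(telemetry) == 0L) {
    stop("cannot summarize an empty session", call. = FALSE)
  }
  x <- telemetry$t_body_c
  m <- mean(x)
  list(min_c = min(x), max_c = max(x), mean_c = m,
       std_c = sqrt(mean((x - m)^2)), n = length(x))
}

#' Run the full monitoring pipeline over one session
#'
#' Merges the three sensor streams in time order and runs each body
#' temperature sample through filtering, calibration and the alert state
#' machine, each acceleration window through the RSC and the threshold
#' manager, and each indoor sample through the range checker. Telemetry
#' records are emitted on a fixed cadence using the latest value of each
#' stream (sample-and-hold). Contact readings are low-pass filtered and
#' calibrated; infrared readings (single-shot confirmations) bypass both
#' and are evaluated against the current threshold directly.
#'
#' Events emitted: `exercise_start` / `exercise_end` on changes of the RSC
#' verdict, `alert_raised` / `request_infrared_confirmation` /
#' `alert_cleared` from the dwell state machine, and
#' `indoor_out_of_range` when the room leaves the configured bounds.
#'
#' @param accel Acceleration stream (`t_s`, `az_g`); may have zero rows,
#'   in which case exercise is reported as 0 throughout.
#' @param temp Body-temperature stream (`t_s`, `value_c`, `source`); must
#'   be non-empty.
#' @param indoor Indoor stream (`t_s`, `temp_c`, `rh_pct`); may have zero
#'   rows.
#' @param cfg A [monitor_config()].
#' @return An object of class `monitor_result`: a list with `events`
#'   (data frame `t_s`, `kind`, `detail`), `telemetry` (see
#'   [make_telemetry()]), `decisions` (RSC window decisions) and `summary`
#'   (see [summarize_session()]).
#' @export
run_monitor <- function(accel, temp, indoor, cfg = monitor_config()) {
  stopifnot(is.data.frame(temp), inherits(cfg, "monitor_config"))
  if (nrow(temp) == 0L) {
    stop("body-temperature stream is empty; nothing to monitor",
         call. = FALSE)
  }
  if (is.null(accel)) accel <- data.frame(t_s = numeric(0), az_g = numeric(0))
  if (is.null(indoor)) {
    indoor <- data.frame(t_s = numeric(0), temp_c = numeric(0),
                         rh_pct = numeric(0))
  }
  if (is.null(temp$source)) temp$source <- "contact"

  decisions <- classify_stream(accel, cfg$rsc)

  t_end <- max(c(temp$t_s, accel$t_s, indoor$t_s,
                 if (nrow(decisions)) decisions$window_end_s))
  t_start <- min(c(temp$t_s, accel$t_s, indoor$t_s))
  period <- cfg$telemetry_period_s
  ticks <- seq(ceiling(t_start / period) * period,
               floor(t_end / period) * period, by = period)

  # merged agenda; priority settles ties: window decisions update the
  # threshold first, then temperature and indoor samples, telemetry last.
  agenda <- rbind(
    if (nrow(decisions)) data.frame(t = decisions$window_end_s, pri = 1L,
                                    type = "decision",
                                    idx = seq_len(nrow(decisions))),
    if (nrow(temp)) data.frame(t = temp$t_s, pri = 2L, type = "temp",
                               idx = seq_len(nrow(temp))),
    if (nrow(indoor)) data.frame(t = indoor$t_s, pri = 3L, type = "indoor",
                                 idx = seq_len(nrow(indoor))),
    if (length(ticks)) data.frame(t = ticks, pri = 4L, type = "tick",
                                  idx = seq_along(ticks))
  )
  agenda <- agenda[order(agenda$t, agenda$pri), , drop = FALSE]

  thr_st <- threshold_state()
  al_st <- alert_state()
  filt_st <- filter_state(beta = cfg$temp_beta)
  events <- list()
  telemetry <- vector("list", length(ticks))
  n_tel <- 0L
  last <- list(t_body = NA_real_, t_indoor = NA_real_, rh = NA_real_,
               exercise = FALSE, alert = FALSE, t_th = cfg$thresholds$t_normal)
  indoor_in_range <- TRUE

  add_events <- function(evts) {
    for (e in evts) events[[length(events) + 1L]] <<- e
  }

  for (r in seq_len(nrow(agenda))) {
    now <- agenda$t[r]
    type <- agenda$type[r]
    i <- agenda$idx[r]

    if (type == "decision") {
      d <- list(window_end_s = decisions$window_end_s[i],
                count = decisions$count[i],
                exercise = decisions$exercise[i])
      if (d$exercise && !last$exercise) {
        add_events(list(monitor_event(now, "exercise_start",
                                      sprintf("count=%d", d$count))))
      } else if (!d$exercise && last$exercise) {
        add_events(list(monitor_event(now, "exercise_end",
                                      sprintf("count=%d", d$count))))
      }
      last$exercise <- d$exercise
      ts <- threshold_step(thr_st, d, now, cfg$thresholds)
      thr_st <- ts$state
      last$t_th <- ts$t_th
    } else if (type == "temp") {
      raw <- temp$value_c[i]
      src <- temp$source[i]
      if (identical(src, "infrared")) {
        t_eval <- raw
      } else {
        fs <- lowpass_step(filt_st, raw)
        filt_st <- fs$state
        t_eval <- fs$y
        if (!is.null(cfg$calibration)) {
          t_eval <- calibrate_apply(cfg$calibration, t_eval)
        }
      }
      last$t_body <- t_eval
      ts <- threshold_step(thr_st, NULL, now, cfg$thresholds)
      thr_st <- ts$state
      last$t_th <- ts$t_th
      as <- alert_step(al_st, t_eval, ts$t_th, now, cfg$alert)
      al_st <- as$state
      last$alert <- al_st$active
      add_events(as$events)
    } else if (type == "indoor") {
      last$t_indoor <- indoor$temp_c[i]
      last$rh <- indoor$rh_pct[i]
      st <- indoor_check(last$t_indoor, last$rh, cfg$indoor)
      ok <- st$temp == "ok" && st$rh == "ok"
      if (!ok && indoor_in_range) {
        add_events(list(monitor_event(
          now, "indoor_out_of_range",
          sprintf("temp=%s rh=%s", st$temp, st$rh))))
      }
      indoor_in_range <- ok
    } else { # telemetry tick
      if (!is.na(last$t_body)) {
        ts <- threshold_step(thr_st, NULL, now, cfg$thresholds)
        thr_st <- ts$state
        last$t_th <- ts$t_th
        n_tel <- n_tel + 1L
        telemetry[[n_tel]] <- make_telemetry(last, now)
      }
    }
  }

  telemetry <- if (n_tel > 0L) {
    do.call(rbind, telemetry[seq_len(n_tel)])
  } else {
    data.frame(t_s = numeric(0), alert = integer(0), t_body_c = numeric(0),
               t_indoor_c = numeric(0), rh_pct = numeric(0),
               exercise = integer(0), t_th_c = numeric(0))
  }
  events_df <- if (length(events)) {
    data.frame(t_s = vapply(events, `[[`, numeric(1), "t_s"),
               kind = vapply(events, `[[`, character(1), "kind"),
               detail = vapply(events, `[[`, character(1), "detail"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(t_s = numeric(0), kind = character(0), detail = character(0),
               stringsAsFactors = FALSE)
  }
  summary <- if (nrow(telemetry)) summarize_session(telemetry) else NULL

  structure(list(events = events_df, telemetry = telemetry,
                 decisions = decisions, summary = summary),
            class = "monitor_result")
}

#' @export
print.monitor_result <- function(x, ...) {
  cat("<monitor_result>\n")
  cat(sprintf("  telemetry: %d records, events: %d, windows: %d\n",
              nrow(x$telemetry), nrow(x$events), nrow(x$decisions)))
  if (!is.null(x$summary)) {
    cat(sprintf("  t_body degC: min %.2f / max %.2f / mean %.2f / std %.2f\n",
                x$summary$min_c, x$summary$max_c, x$summary$mean_c,
                x$summary$std_c))
  }
  invisible(x)
}
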