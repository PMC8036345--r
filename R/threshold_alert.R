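#' Activity-adaptive body-temperature threshold configuration
#'
#' Body temperature rises during and shortly after physical exercise, so a
#' fixed fever threshold would raise spurious alerts around training. The
#' threshold manager applies `t_exercise` while exercise is detected and
#' for `hold_min` minutes after the last exercise window ends (core
#' temperature typically returns to normal within about 20 minutes), and
#' `t_normal` otherwise.
#'
#' @param t_normal Threshold during normal activity, degC (default 37.0).
#' @param t_exercise Threshold during/after exercise, degC (default 37.5).
#' @param hold_min Minutes the elevated threshold persists after the last
#'   exercise window (default 20).
#' @return An object of class `threshold_config`.
#' @export
threshold_config <- function(t_normal = 37.0, t_exercise = 37.5,
                             hold_min = 20) {
  stopifnot(is.finite(t_normal), is.finite(t_exercise), hold_min >= 0)
  if (t_exercise < t_normal) {
    stop("`t_exercise` must be >= `t_normal`", call. = FALSE)
  }
  structure(list(t_normal = t_normal, t_exercise = t_exercise,
                 hold_min = hold_min),
            class = "threshold_config")
}

#' Fresh threshold-manager state
#' @return An object of class `threshold_state` with fields `exercising`
#'   (logical) and `last_exercise_end` (seconds, `NA` if no exercise seen).
#' @export
threshold_state <- function() {
  structure(list(exercising = FALSE, last_exercise_end = NA_real_),
            class = "threshold_state")
}

#' Advance the threshold manager
#'
#' Consumes an optional RSC window decision and returns the body
#' temperature threshold in force at time `now`. Every exercise window
#' restarts the post-exercise hold, which is timed from that window's end;
#' the threshold reverts to `t_normal` at the first evaluation at least
#' `hold_min` minutes after the last exercise window ended.
#'
#' @param state A [threshold_state()].
#' @param decision A window decision from [rsc_step()]/[classify_stream()]
#'   (a list with at least `window_end_s` and `exercise`), or `NULL` when
#'   only re-evaluating the threshold.
#' @param now Current time, seconds.
#' @param cfg A [threshold_config()].
#' @return A list with `state` (updated) and `t_th` (degC, always exactly
#'   `t_normal` or `t_exercise`).
#' @export
threshold_step <- function(state, decision = NULL, now,
                           cfg = threshold_config()) {
  stopifnot(inherits(state, "threshold_state"), is.finite(now))
  if (!is.null(decision)) {
    if (isTRUE(decision$exercise)) {
      state$exercising <- TRUE
      state$last_exercise_end <- decision$window_end_s
    } else {
      state$exercising <- FALSE
    }
  }
  in_hold <- !is.na(state$last_exercise_end) &&
    (now - state$last_exercise_end) < cfg$hold_min * 60
  t_th <- if (state$exercising || in_hold) cfg$t_exercise else cfg$t_normal
  list(state = state, t_th = t_th)
}

#' Alert dwell configuration
#'
#' A single reading at or above threshold is not trusted: the contact
#' thermometer is noisy and brief exceedances are common. The alert fires
#' only when body temperature stays at or above the current threshold
#' continuously for `dwell_min` minutes.
#'
#' @param dwell_min Minutes of continuous exceedance required (default 12).
#' @return An object of class `alert_config`.
#' @export
alert_config <- function(dwell_min = 12) {
  stopifnot(dwell_min > 0)
  structure(list(dwell_min = dwell_min), class = "alert_config")
}

#' Fresh alert state
#' @return An object of class `alert_state` with fields `exceed_since`
#'   (seconds, `NA` while below threshold) and `active` (logical).
#' @export
alert_state <- function() {
  structure(list(exceed_since = NA_real_, active = FALSE),
            class = "alert_state")
}

monitor_event <- function(t_s, kind, detail = "") {
  list(t_s = t_s, kind = kind, detail = detail)
}

#' Advance the alert state machine by one temperature evaluation
#'
#' Exceedance is judged against the *current* threshold at every sample:
#' `exceed_since` is set at the first sample with `t_body >= t_th` and
#' cleared by any sample below threshold (including the case where
#' detected exercise raises the threshold above the current body
#' temperature mid-dwell). Once the exceedance has lasted `dwell_min`
#' minutes, a single `alert_raised` event is emitted together with a
#' `request_infrared_confirmation` event, since a fever indicated by the
#' contact sensor should be confirmed with the infrared thermometer. A
#' later sub-threshold sample emits `alert_cleared`.
#'
#' @param state An [alert_state()].
#' @param t_body Evaluated body temperature, degC.
#' @param t_th Threshold currently in force, degC.
#' @param now Sample time, seconds.
#' @param cfg An [alert_config()].
#' @return A list with `state` (updated) and `events` (possibly empty list
#'   of events, each `list(t_s, kind, detail)`).
#' @export
alert_step <- function(state, t_body, t_th, now, cfg = alert_config()) {
  stopifnot(inherits(state, "alert_state"), is.finite(t_body),
            is.finite(t_th), is.finite(now))
  events <- list()
  if (t_body >= t_th) {
    if (is.na(state$exceed_since)) state$exceed_since <- now
    if (!state$active &&
        (now - state$exceed_since) >= cfg$dwell_min * 60) {
      state$active <- TRUE
      events <- list(
        monitor_event(now, "alert_raised",
                      sprintf("t_body=%.2f t_th=%.1f", t_body, t_th)),
        monitor_event(now, "request_infrared_confirmation",
                      sprintf("t_body=%.2f", t_body))
      )
    }
  } else {
    state$exceed_since <- NA_real_
    if (state$active) {
      state$active <- FALSE
      events <- list(
        monitor_event(now, "alert_cleared",
                      sprintf("t_body=%.2f t_th=%.1f", t_body, t_th))
      )
    }
  }
  list(state = state, events = events)
}

#' Indoor comfort bounds for a quarantine room
#'
#' Guidance for limiting airborne virus survival indoors: temperature held
#' between 20 and 24 degC and relative humidity between 20 and 60 percent.
#' Bounds are inclusive at both ends.
#'
#' @param temp_lo,temp_hi Indoor temperature bounds, degC.
#' @param rh_lo,rh_hi Relative humidity bounds, percent.
#' @return An object of class `indoor_bounds`.
#' @export
indoor_bounds <- function(temp_lo = 20, temp_hi = 24, rh_lo = 20,
                          rh_hi = 60) {
  stopifnot(temp_lo <= temp_hi, rh_lo <= rh_hi, rh_lo >= 0, rh_hi <= 100)
  structure(list(temp_lo = temp_lo, temp_hi = temp_hi, rh_lo = rh_lo,
                 rh_hi = rh_hi),
            class = "indoor_bounds")
}

#' Classify an indoor sample against the comfort bounds
#'
#' @param temp Indoor temperature, degC; vectorized.
#' @param rh Relative humidity, percent in `[0, 100]`; vectorized.
#' @param bounds An [indoor_bounds()].
#' @return A list with character vectors `temp` and `rh`, each one of
#'   `"low"`, `"ok"`, `"high"` per sample.
#' @export
#' @examples
#' indoor_check(23.5, 18)  # temp "ok", rh "low"
indoor_check <- function(temp, rh, bounds = indoor_bounds()) {
  stopifnot(inherits(bounds, "indoor_bounds"), all(is.finite(temp)),
            all(is.finite(rh)))
  if (any(rh < 0 | rh > 100)) {
    stop("relative humidity outside [0, 100]: ",
         format(rh[rh < 0 | rh > 100][1L]), call. = FALSE)
  }
  band <- function(x, lo, hi) {
    ifelse(x < lo, "low", ifelse(x > hi, "high", "ok"))
  }
  list(temp = band(temp, bounds$temp_lo, bounds$temp_hi),
       rh = band(rh, bounds$rh_lo, bounds$rh_hi))
}
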