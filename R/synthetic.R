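#' Build an activity schedule
#'
#' A session is described as contiguous segments, each in one of three
#' modes: `"none"` (no motion: sleep, sitting still), `"normal"` (ordinary
#' movement: standing up, walking about) and `"exercise"` (repetitive
#' training motion). The schedule drives all three stream generators and
#' serves as ground truth for recognition tests.
#'
#' @param modes Character vector of segment modes.
#' @param durations_s Numeric vector of segment durations, seconds (same
#'   length as `modes`).
#' @param start_s Start time of the first segment (default 0).
#' @return A data frame of class `activity_schedule` with columns
#'   `start_s`, `end_s`, `mode`.
#' @export
#' @examples
#' activity_schedule(c("none", "exercise", "none"), c(60, 300, 600))
activity_schedule <- function(modes, durations_s, start_s = 0) {
  modes <- as.character(modes)
  if (length(modes) == 0L) stop("empty schedule", call. = FALSE)
  if (length(modes) != length(durations_s)) {
    stop("`modes` and `durations_s` must have the same length",
         call. = FALSE)
  }
  if (!all(modes %in% c("none", "normal", "exercise"))) {
    stop("schedule modes must be 'none', 'normal' or 'exercise'",
         call. = FALSE)
  }
  if (!all(durations_s > 0)) {
    stop("segment durations must be positive", call. = FALSE)
  }
  ends <- start_s + cumsum(durations_s)
  starts <- c(start_s, ends[-length(ends)])
  structure(data.frame(start_s = starts, end_s = ends, mode = modes,
                       stringsAsFactors = FALSE),
            class = c("activity_schedule", "data.frame"))
}

# mode of each time point; segments are [start, end)
.schedule_mode_at <- function(schedule, t) {
  idx <- findInterval(t, c(schedule$start_s, schedule$end_s[nrow(schedule)]),
                      rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > nrow(schedule)] <- nrow(schedule)
  schedule$mode[idx]
}

#' Generate a synthetic Z-axis acceleration stream
#'
#' Emulates the three activity signatures a wrist accelerometer shows
#' around 1 g:
#' * `none` — constant gravity plus Gaussian sensor noise (sd 2 mg), so
#'   consecutive differences stay far below the spike threshold;
#' * `normal` — the same plus sparse single-sample excursions of 20-60 mg
#'   at a mean rate of 0.2 per second, deliberately capped below the 90 mg
#'   spike threshold;
#' * `exercise` — a deterministic square-wave carrier of +/-100 mg about
#'   1 g alternating at 1.5 Hz, giving about 90 super-threshold
#'   consecutive differences per 30 s window, comfortably above the
#'   24-spike exercise criterion even after low-pass filtering.
#'
#' @param schedule An [activity_schedule()].
#' @param cfg An [rsc_config()]; supplies the sampling rate.
#' @param seed Integer seed; identical seeds give identical streams.
#' @return Data frame with columns `t_s`, `az_g`.
#' @export
generate_accel <- function(schedule, cfg = rsc_config(), seed = 0) {
  stopifnot(inherits(schedule, "activity_schedule"))
  if (!is.null(seed)) set.seed(seed)
  fs <- cfg$fs_hz
  t0 <- schedule$start_s[1L]
  t_end <- schedule$end_s[nrow(schedule)]
  t <- seq(t0, t_end - 1 / fs, by = 1 / fs)
  n <- length(t)
  mode <- .schedule_mode_at(schedule, t)

  az <- 1 + stats::rnorm(n, 0, 0.002)

  i_norm <- which(mode == "normal")
  if (length(i_norm)) {
    jump <- stats::rbinom(length(i_norm), 1L, min(1, 0.2 / fs)) == 1L
    amp <- stats::runif(sum(jump), 0.020, 0.060) *
      sample(c(-1, 1), sum(jump), replace = TRUE)
    az[i_norm[jump]] <- az[i_norm[jump]] + amp
  }

  i_ex <- which(mode == "exercise")
  if (length(i_ex)) {
    carrier <- ifelse(floor(2 * 1.5 * t[i_ex]) %% 2 == 0, 0.100, -0.100)
    az[i_ex] <- az[i_ex] + carrier
  }

  data.frame(t_s = t, az_g = az)
}

#' Parameters of the synthetic body-temperature model
#'
#' Body temperature is modelled as a first-order relaxation toward an
#' activity-dependent set point, plus white measurement noise. The resting
#' set point defaults to 36.5 degC (normal core temperature), exercise
#' shifts it up by `exercise_rise`, and after exercise the temperature
#' decays back with time constant `relax_tau_s` (20 minutes, matching the
#' usual post-exercise recovery). `noise_sd` defaults to 0.2 degC, the
#' typical spread of a wrist contact thermometer. Setting `fever_target`
#' overrides the set point entirely: the trace ramps toward the fever
#' plateau and holds there.
#'
#' @param baseline Resting body temperature, degC.
#' @param noise_sd Measurement noise standard deviation, degC.
#' @param exercise_rise Set-point shift during exercise, degC.
#' @param relax_tau_s Relaxation time constant, seconds.
#' @param fever_target Optional fever plateau, degC, or `NULL`.
#' @return An object of class `temp_model_params`.
#' @export
temp_model_params <- function(baseline = 36.5, noise_sd = 0.2,
                              exercise_rise = 0.5, relax_tau_s = 1200,
                              fever_target = NULL) {
  stopifnot(noise_sd >= 0, relax_tau_s > 0)
  structure(list(baseline = baseline, noise_sd = noise_sd,
                 exercise_rise = exercise_rise, relax_tau_s = relax_tau_s,
                 fever_target = fever_target),
            class = "temp_model_params")
}

#' Generate a synthetic body-temperature stream
#'
#' @param schedule An [activity_schedule()].
#' @param params A [temp_model_params()].
#' @param fs_hz Sampling rate of the temperature stream (default 0.2, one
#'   sample every 5 s).
#' @param seed Integer seed.
#' @return Data frame with columns `t_s`, `value_c`, `source` (all
#'   `"contact"`).
#' @export
generate_temperature <- function(schedule, params = temp_model_params(),
                                 fs_hz = 0.2, seed = 0) {
  stopifnot(inherits(schedule, "activity_schedule"),
            inherits(params, "temp_model_params"))
  if (!is.null(seed)) set.seed(seed)
  dt <- 1 / fs_hz
  t0 <- schedule$start_s[1L]
  t_end <- schedule$end_s[nrow(schedule)]
  t <- seq(t0, t_end, by = dt)
  mode <- .schedule_mode_at(schedule, t)
  target <- if (!is.null(params$fever_target)) {
    rep(params$fever_target, length(t))
  } else {
    ifelse(mode == "exercise", params$baseline + params$exercise_rise,
           params$baseline)
  }
  core <- numeric(length(t))
  core[1L] <- params$baseline
  a <- dt / params$relax_tau_s
  for (i in seq_along(t)[-1L]) {
    core[i] <- core[i - 1L] + a * (target[i] - core[i - 1L])
  }
  value <- core + stats::rnorm(length(t), 0, params$noise_sd)
  data.frame(t_s = t, value_c = value, source = "contact",
             stringsAsFactors = FALSE)
}

#' Generate a synthetic indoor temperature / relative humidity stream
#'
#' Ambient conditions drift slowly; the stream is sampled every 5 s (the
#' ambient sensor's update period) with optional linear drift across the
#' session and small measurement noise.
#'
#' @param duration_s Session length, seconds (> 0).
#' @param temp_c Indoor temperature at session start, degC.
#' @param rh_pct Relative humidity at session start, percent.
#' @param drift_temp_c Total temperature drift over the session, degC.
#' @param drift_rh Total relative-humidity drift over the session, percent.
#' @param noise_sd_temp,noise_sd_rh Measurement noise sd.
#' @param period_s Sampling period, seconds (default 5).
#' @param seed Integer seed.
#' @return Data frame with columns `t_s`, `temp_c`, `rh_pct`.
#' @export
generate_indoor <- function(duration_s, temp_c = 22, rh_pct = 40,
                            drift_temp_c = 0, drift_rh = 0,
                            noise_sd_temp = 0.05, noise_sd_rh = 0.2,
                            period_s = 5, seed = 0) {
  stopifnot(duration_s > 0, period_s > 0)
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration_s, by = period_s)
  frac <- if (duration_s > 0) t / duration_s else 0
  temp <- temp_c + drift_temp_c * frac + stats::rnorm(length(t), 0, noise_sd_temp)
  rh <- rh_pct + drift_rh * frac + stats::rnorm(length(t), 0, noise_sd_rh)
  rh <- pmin(100, pmax(0, rh))
  data.frame(t_s = t, temp_c = temp, rh_pct = rh)
}
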