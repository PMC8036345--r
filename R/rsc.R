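#' Configuration of the Repetition Spikes Counter (RSC)
#'
#' The RSC classifies physical exercise from the Z axis of a wrist-worn
#' MEMS accelerometer. Consecutive filtered samples are differenced; an
#' absolute difference of at least `dz_th_mg` milli-g counts as one spike,
#' and a tumbling window of `window_s` seconds whose spike count reaches
#' `count_th` is classified as exercise. The defaults (30 s windows, 90 mg
#' spike threshold, 24 spikes per window, 20 Hz sampling, 30 s start-up
#' discarded) are the operating point of the wearable system this package
#' models; lowering `dz_th_mg` makes softer motion count as a spike, and
#' `count_th` scales with motion speed.
#'
#' @param window_s Tumbling window length, seconds.
#' @param dz_th_mg Spike amplitude threshold on consecutive differences,
#'   milli-g. A difference counts as a spike when `|dz| >= dz_th_mg`.
#' @param count_th Spikes per window at or above which the window is
#'   classified as exercise.
#' @param warmup_s Start-up interval discarded before the first window.
#' @param fs_hz Sampling rate of the acceleration stream.
#' @param accel_beta Low-pass coefficient applied to the raw Z acceleration
#'   before differencing (see [filter_state()]); `1` disables filtering.
#' @return An object of class `rsc_config`.
#' @export
rsc_config <- function(window_s = 30, dz_th_mg = 90, count_th = 24,
                       warmup_s = 30, fs_hz = 20, accel_beta = 0.5) {
  stopifnot(window_s > 0, dz_th_mg > 0, count_th > 0, warmup_s >= 0,
            fs_hz > 0, accel_beta >= 0, accel_beta <= 1)
  n_win <- window_s * fs_hz
  if (abs(n_win - round(n_win)) > 1e-9) {
    stop("`window_s * fs_hz` must be a whole number of samples",
         call. = FALSE)
  }
  structure(list(window_s = window_s, dz_th_mg = dz_th_mg,
                 count_th = count_th, warmup_s = warmup_s, fs_hz = fs_hz,
                 accel_beta = accel_beta),
            class = "rsc_config")
}

#' Absolute consecutive-sample difference in milli-g
#'
#' @param z_prev,z_curr Consecutive Z-axis acceleration samples, g.
#' @return `|z_curr - z_prev| * 1000`, milli-g. Vectorized.
#' @export
#' @examples
#' abs_delta_mg(1.00, 1.10)  # 100
abs_delta_mg <- function(z_prev, z_curr) {
  if (!all(is.finite(z_prev)) || !all(is.finite(z_curr))) {
    stop("non-finite acceleration sample in abs_delta_mg", call. = FALSE)
  }
  abs(z_curr - z_prev) * 1000
}

#' Is a consecutive difference a spike?
#'
#' Spikes are declared with an inclusive threshold, so the configured
#' constant is itself the decision boundary: `dz = dz_th_mg` is a spike.
#'
#' @param dz Absolute consecutive difference, milli-g (non-negative).
#' @param cfg An [rsc_config()].
#' @return Logical; vectorized over `dz`.
#' @export
is_spike <- function(dz, cfg = rsc_config()) {
  stopifnot(inherits(cfg, "rsc_config"), all(dz >= 0))
  dz >= cfg$dz_th_mg
}

#' Fresh streaming state for the RSC
#'
#' @param cfg An [rsc_config()].
#' @return An object of class `rsc_state`. Fields: `t0` (time of the first
#'   sample), `prev_t`, `filt_prev` (filter memory), `prev_az` (last
#'   filtered acceleration used for differencing, `NA` after a dropout),
#'   `window` (index of the tumbling window currently being filled; 0 while
#'   warming up) and `count` (spikes in that window).
#' @export
rsc_state <- function(cfg = rsc_config()) {
  structure(list(t0 = NA_real_, prev_t = NA_real_, filt_prev = NA_real_,
                 prev_az = NA_real_, window = 0L, count = 0L),
            class = "rsc_state")
}

# window index of a sample at time t: windows are anchored at the end of
# warm-up and are half-open on the left, (anchor + (k-1) W, anchor + k W],
# so a delta is credited to the window containing its *later* sample.
.rsc_window_index <- function(t, t0, cfg) {
  rel <- (t - t0 - cfg$warmup_s) / cfg$window_s
  k <- ceiling(rel - 1e-9)
  max(0L, as.integer(k))
}

.rsc_decision <- function(window_end, count, cfg) {
  list(window_end_s = window_end, count = as.integer(count),
       exercise = count >= cfg$count_th)
}

#' Advance the RSC by one acceleration sample
#'
#' Feeds one time-stamped Z-axis sample through the low-pass filter,
#' differencing, spike test and tumbling-window counter. Whenever the
#' sample falls beyond the window currently being filled, the completed
#' window (and any empty windows skipped over) are emitted as decisions.
#' Samples during the warm-up interval only prime the filter. A gap longer
#' than two sampling intervals clears the differencing memory so that a
#' data dropout cannot fabricate a spike.
#'
#' @param state An [rsc_state()].
#' @param t Sample time, seconds; must strictly increase.
#' @param az Z-axis acceleration, g.
#' @param cfg An [rsc_config()].
#' @return A list with `state` (updated) and `decisions` (possibly empty
#'   list of window decisions, each with `window_end_s`, `count`,
#'   `exercise`).
#' @export
rsc_step <- function(state, t, az, cfg = rsc_config()) {
  if (!is.finite(t) || !is.finite(az)) {
    stop("non-finite accelerometer sample at t = ", format(t), call. = FALSE)
  }
  if (!is.na(state$prev_t) && t <= state$prev_t) {
    stop("out-of-order accelerometer timestamp: ", format(t),
         " follows ", format(state$prev_t), call. = FALSE)
  }
  if (is.na(state$t0)) state$t0 <- t
  decisions <- list()

  # dropout: reset filter and differencing memory
  if (!is.na(state$prev_t) && (t - state$prev_t) > 2 / cfg$fs_hz) {
    state$filt_prev <- NA_real_
    state$prev_az <- NA_real_
  }

  filt <- if (is.na(state$filt_prev)) az else
    cfg$accel_beta * az + (1 - cfg$accel_beta) * state$filt_prev
  state$filt_prev <- filt

  k <- .rsc_window_index(t, state$t0, cfg)
  anchor <- state$t0 + cfg$warmup_s

  if (k > state$window) {
    if (state$window >= 1L) {
      decisions[[length(decisions) + 1L]] <-
        .rsc_decision(anchor + state$window * cfg$window_s, state$count, cfg)
    }
    w <- state$window + 1L
    while (w < k) {
      if (w >= 1L) {
        decisions[[length(decisions) + 1L]] <-
          .rsc_decision(anchor + w * cfg$window_s, 0L, cfg)
      }
      w <- w + 1L
    }
    state$window <- k
    state$count <- 0L
  }

  if (k >= 1L && !is.na(state$prev_az)) {
    if (abs_delta_mg(state$prev_az, filt) >= cfg$dz_th_mg) {
      state$count <- state$count + 1L
    }
  }

  state$prev_az <- filt
  state$prev_t <- t
  list(state = state, decisions = decisions)
}

#' Flush the RSC at end of stream
#'
#' In batch use, the window being filled is emitted as a final decision if
#' the stream reached its end: the last sample time plus one sampling
#' interval covers the window boundary. A genuinely partial trailing window
#' produces no decision.
#'
#' @param state An [rsc_state()] after the last sample.
#' @param cfg An [rsc_config()].
#' @return A list of zero or one window decisions.
#' @export
rsc_flush <- function(state, cfg = rsc_config()) {
  if (is.na(state$t0) || state$window < 1L) return(list())
  anchor <- state$t0 + cfg$warmup_s
  window_end <- anchor + state$window * cfg$window_s
  if (state$prev_t + 1 / cfg$fs_hz >= window_end - 1e-9) {
    list(.rsc_decision(window_end, state$count, cfg))
  } else {
    list()
  }
}

#' Classify an acceleration stream into per-window exercise decisions
#'
#' Batch driver over [rsc_step()]: runs the streaming counter over a whole
#' acceleration stream and returns one decision per complete post-warm-up
#' window.
#'
#' @param accel Data frame with columns `t_s` (seconds, strictly
#'   increasing) and `az_g` (Z acceleration, g). Extra columns (e.g.
#'   `ax_g`, `ay_g`) are ignored.
#' @param cfg An [rsc_config()].
#' @return Data frame with columns `window_end_s`, `count`, `exercise`;
#'   zero rows if the stream is empty or covers no complete window.
#' @export
#' @examples
#' acc <- generate_accel(activity_schedule("exercise", 120), seed = 1)
#' classify_stream(acc)
classify_stream <- function(accel, cfg = rsc_config()) {
  stopifnot(is.data.frame(accel))
  empty <- data.frame(window_end_s = numeric(0), count = integer(0),
                      exercise = logical(0))
  if (nrow(accel) == 0L) return(empty)
  stopifnot(all(c("t_s", "az_g") %in% names(accel)))

  ts <- as.numeric(accel$t_s)
  az <- as.numeric(accel$az_g)
  st <- rsc_state(cfg)
  out <- vector("list", 64L)
  n_out <- 0L
  for (i in seq_along(ts)) {
    step <- rsc_step(st, ts[i], az[i], cfg)
    st <- step$state
    for (d in step$decisions) {
      n_out <- n_out + 1L
      if (n_out > length(out)) out <- c(out, vector("list", length(out)))
      out[[n_out]] <- d
    }
  }
  for (d in rsc_flush(st, cfg)) {
    n_out <- n_out + 1L
    if (n_out > length(out)) out <- c(out, vector("list", 1L))
    out[[n_out]] <- d
  }
  if (n_out == 0L) return(empty)
  out <- out[seq_len(n_out)]
  data.frame(
    window_end_s = vapply(out, `[[`, numeric(1), "window_end_s"),
    count = vapply(out, `[[`, integer(1), "count"),
    exercise = vapply(out, `[[`, logical(1), "exercise")
  )
}
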