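#' Fit an additive calibration for a contact thermometer
#'
#' A wrist-mounted contact thermometer reads systematically below a core
#' reference (a glass thermometer held until stable). The calibration
#' averages `n` raw samples taken after the sensor has stabilized and
#' stores the additive bias \deqn{T_{bias} = T_{ref} - T_{avg},} which
#' [calibrate_apply()] later adds to every raw reading.
#'
#' @param raw Numeric vector of raw contact-thermometer readings (degC),
#'   already restricted to the stabilized portion of the stream; the first
#'   `n` values are used.
#' @param t_ref Reference temperature (degC).
#' @param n Number of samples to average (default 50).
#' @return An object of class `calibration_model` with fields `t_ref`,
#'   `t_avg`, `bias` and `n`.
#' @seealso [calibrate_apply()], [calibrate_from_stream()]
#' @export
#' @examples
#' m <- calibrate_fit(rep(34.0, 50), t_ref = 36.6)
#' m$bias  # 2.6
calibrate_fit <- function(raw, t_ref, n = 50L) {
  stopifnot(is.numeric(raw), is.numeric(t_ref), length(t_ref) == 1L,
            is.finite(t_ref))
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be a positive integer", call. = FALSE)
  if (length(raw) < n) {
    stop("insufficient calibration data: need ", n, " samples, got ",
         length(raw), call. = FALSE)
  }
  used <- raw[seq_len(n)]
  if (!all(is.finite(used))) {
    stop("non-finite raw sample at position ",
         which(!is.finite(used))[1L], " in calibration data", call. = FALSE)
  }
  t_avg <- mean(used)
  structure(
    list(t_ref = as.numeric(t_ref), t_avg = t_avg,
         bias = as.numeric(t_ref) - t_avg, n = n),
    class = "calibration_model"
  )
}

#' Fit a calibration from a temperature stream
#'
#' Convenience wrapper around [calibrate_fit()] that drops the
#' stabilization interval first. The contact sensor needs roughly ten
#' minutes on the wrist before its reading is steady, so by default the
#' first 600 s of the stream are discarded and the next `n` contact
#' samples are averaged.
#'
#' @param stream Temperature stream data frame with columns `t_s`,
#'   `value_c`, `source` (see [read_stream()]).
#' @param t_ref Reference temperature (degC).
#' @param n Number of samples to average (default 50).
#' @param stabilization_s Seconds discarded from the start of the stream
#'   before averaging (default 600).
#' @return A `calibration_model`.
#' @export
calibrate_from_stream <- function(stream, t_ref, n = 50L,
                                  stabilization_s = 600) {
  stopifnot(is.data.frame(stream),
            all(c("t_s", "value_c") %in% names(stream)))
  keep <- stream$t_s >= stabilization_s
  if ("source" %in% names(stream)) keep <- keep & stream$source == "contact"
  calibrate_fit(stream$value_c[keep], t_ref = t_ref, n = n)
}

#' Apply an additive calibration to raw readings
#'
#' @param model A `calibration_model` from [calibrate_fit()].
#' @param t_raw Raw reading(s), degC; vectorized.
#' @return `t_raw + model$bias`.
#' @export
#' @examples
#' m <- calibrate_fit(rep(34.0, 50), t_ref = 36.6)
#' calibrate_apply(m, 34.2)  # 36.8
calibrate_apply <- function(model, t_raw) {
  stopifnot(inherits(model, "calibration_model"), is.numeric(t_raw))
  if (length(t_raw) && !all(is.finite(t_raw))) {
    stop("non-finite raw temperature passed to calibrate_apply",
         call. = FALSE)
  }
  t_raw + model$bias
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> t_ref = %.2f degC, t_avg = %.3f degC over n = %d samples, bias = %+.3f degC\n",
    x$t_ref, x$t_avg, x$n, x$bias))
  invisible(x)
}
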