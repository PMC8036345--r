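#' Create the state of a first-order IIR low-pass filter
#'
#' The smoother used throughout the package is the recursive exponential
#' filter \deqn{y_i = \beta x_i + (1 - \beta) y_{i-1},} where `beta` weights
#' the current raw sample against the previous *output*. `beta = 1` passes
#' the input through unchanged; smaller values smooth more strongly at the
#' cost of a slower dynamic response. The default `beta = 0.5` balances
#' noise suppression against responsiveness for wrist-worn contact
#' thermometer streams, and the same structure is reused (with its own
#' `beta`) to pre-filter accelerometer samples before spike detection.
#'
#' @param beta Smoothing coefficient in `[0, 1]`.
#' @param prev Previous filter output, or `NA` before the first sample.
#' @return An object of class `filter_state`.
#' @seealso [lowpass_step()], [lowpass_filter()]
#' @export
#' @examples
#' st <- filter_state(beta = 0.5)
#' lowpass_step(st, 36.6)
filter_state <- function(beta = 0.5, prev = NA_real_) {
  stopifnot(is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (beta < 0 || beta > 1) {
    stop("`beta` must lie in [0, 1], got ", beta, call. = FALSE)
  }
  structure(list(beta = as.numeric(beta), prev = as.numeric(prev)),
            class = "filter_state")
}

#' Advance a low-pass filter by one sample
#'
#' Applies one step of the recursive smoother. The very first sample passes
#' through unchanged and initializes the state, which avoids imposing an
#' arbitrary prior on the stream.
#'
#' @param state A [filter_state()].
#' @param x New raw sample (finite numeric scalar).
#' @return A list with elements `state` (updated `filter_state`) and `y`
#'   (the filtered output).
#' @export
#' @examples
#' st <- filter_state(beta = 0.5, prev = 36.0)
#' lowpass_step(st, 38.0)$y  # 37.0
lowpass_step <- function(state, x) {
  stopifnot(inherits(state, "filter_state"))
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("non-finite or non-scalar sample passed to the low-pass filter: ",
         deparse(substitute(x)), " = ", format(x), call. = FALSE)
  }
  y <- if (is.na(state$prev)) {
    as.numeric(x)
  } else {
    state$beta * x + (1 - state$beta) * state$prev
  }
  state$prev <- y
  list(state = state, y = y)
}

#' Low-pass filter a whole numeric stream
#'
#' Batch equivalent of folding [lowpass_step()] over `x`: the first output
#' equals the first input (unless `init` supplies a prior output) and each
#' later output is `beta * x[i] + (1 - beta) * y[i - 1]`.
#'
#' @param x Numeric vector of raw samples, all finite.
#' @param beta Smoothing coefficient in `[0, 1]`.
#' @param init Optional previous output used to seed the recursion.
#' @return Numeric vector of filtered samples, same length as `x`.
#' @export
lowpass_filter <- function(x, beta = 0.5, init = NULL) {
  if (length(x) == 0L) return(numeric(0))
  if (!all(is.finite(x))) {
    stop("non-finite value at position ", which(!is.finite(x))[1L],
         " passed to the low-pass filter", call. = FALSE)
  }
  st <- filter_state(beta = beta,
                     prev = if (is.null(init)) NA_real_ else init)
  y <- numeric(length(x))
  b <- st$beta
  prev <- st$prev
  for (i in seq_along(x)) {
    prev <- if (is.na(prev)) x[i] else b * x[i] + (1 - b) * prev
    y[i] <- prev
  }
  y
}
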