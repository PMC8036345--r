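#' Reference 14-day nightly body-temperature averages
#'
#' Loads the packaged record of end-of-day average body temperatures from
#' a two-week quarantine monitoring deployment of the wearable system this
#' package models (one average per day, all in the normal 36.3-36.9 degC
#' band, none of which triggered an alert). Useful as a realistic
#' below-threshold input for replay tests and examples.
#'
#' @return Data frame with columns `day` (1-14), `avg_tbody_c` (degC) and
#'   `alert` (0/1 as recorded).
#' @export
#' @examples
#' daily_average_reference()
daily_average_reference <- function() {
  path <- system.file("extdata", "daily_avg_tbody.csv",
                      package = "rscmonitor", mustWork = TRUE)
  utils::read.csv(path)
}
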