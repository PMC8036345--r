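.stream_columns <- list(
  accel = c("t_s", "az_g"),
  temp = c("t_s", "value_c", "source"),
  indoor = c("t_s", "temp_c", "rh_pct")
)

#' Read a sensor stream CSV
#'
#' Streams are plain comma-separated files with a mandatory header, dot
#' decimals and UTF-8 encoding. Three kinds are understood:
#' * `accel` — `t_s,az_g` (optional `ax_g`, `ay_g` columns are ignored);
#' * `temp` — `t_s,value_c,source` with `source` one of `contact`,
#'   `infrared`;
#' * `indoor` — `t_s,temp_c,rh_pct`.
#'
#' Validation errors (missing column, non-monotone time, non-finite value,
#' out-of-range value) name the offending file line.
#'
#' @param path Path to the CSV file.
#' @param kind One of `"accel"`, `"temp"`, `"indoor"`.
#' @return A validated, time-ordered data frame of the matching kind.
#' @export
read_stream <- function(path, kind = c("accel", "temp", "indoor")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  required <- .stream_columns[[kind]]
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s) for a %s stream: %s",
                 path, kind, paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  df <- df[required]
  line <- function(i) i + 1L # header occupies line 1

  num_cols <- setdiff(required, "source")
  for (col in num_cols) {
    v <- df[[col]]
    if (!is.numeric(v)) v <- suppressWarnings(as.numeric(v))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop(sprintf("%s line %d: non-finite value in column '%s'",
                   path, line(bad[1L]), col), call. = FALSE)
    }
    df[[col]] <- v
  }
  if (any(df$t_s < 0)) {
    stop(sprintf("%s line %d: negative timestamp", path,
                 line(which(df$t_s < 0)[1L])), call. = FALSE)
  }
  if (nrow(df) > 1L) {
    bad <- which(diff(df$t_s) <= 0)
    if (length(bad)) {
      stop(sprintf("%s line %d: timestamps must strictly increase", path,
                   line(bad[1L] + 1L)), call. = FALSE)
    }
  }
  if (kind == "accel") {
    bad <- which(abs(df$az_g) > 2)
    if (length(bad)) {
      stop(sprintf("%s line %d: |az_g| exceeds the 2 g sensor range",
                   path, line(bad[1L])), call. = FALSE)
    }
  }
  if (kind == "temp") {
    bad <- which(!df$source %in% c("contact", "infrared"))
    if (length(bad)) {
      stop(sprintf("%s line %d: source must be 'contact' or 'infrared'",
                   path, line(bad[1L])), call. = FALSE)
    }
    bad <- which(df$value_c < 30 | df$value_c > 45)
    if (length(bad)) {
      stop(sprintf("%s line %d: body temperature outside [30, 45] degC",
                   path, line(bad[1L])), call. = FALSE)
    }
  }
  if (kind == "indoor") {
    bad <- which(df$rh_pct < 0 | df$rh_pct > 100)
    if (length(bad)) {
      stop(sprintf("%s line %d: relative humidity outside [0, 100]",
                   path, line(bad[1L])), call. = FALSE)
    }
  }
  df
}

#' Write a sensor stream CSV
#'
#' @param stream Data frame of one of the three stream kinds.
#' @param path Output path.
#' @param kind One of `"accel"`, `"temp"`, `"indoor"`.
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path, kind = c("accel", "temp", "indoor")) {
  kind <- match.arg(kind)
  required <- .stream_columns[[kind]]
  stopifnot(is.data.frame(stream), all(required %in% names(stream)))
  utils::write.csv(stream[required], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write monitor events as JSON lines
#'
#' One JSON object per line with keys `t_s`, `kind`, `detail`, mirroring
#' the structured log a deployed monitor would publish.
#'
#' @param events Events data frame from [run_monitor()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(is.data.frame(events),
            all(c("t_s", "kind", "detail") %in% names(events)))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      writeLines(jsonlite::toJSON(
        list(t_s = events$t_s[i], kind = events$kind[i],
             detail = events$detail[i]),
        auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}

#' Read monitor events from JSON lines
#'
#' @param path Path to a JSONL events file written by [write_events()].
#' @return Events data frame (`t_s`, `kind`, `detail`).
#' @export
read_events <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(t_s = numeric(0), kind = character(0),
                      detail = character(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(lines, jsonlite::fromJSON)
  data.frame(t_s = vapply(rows, function(r) as.numeric(r$t_s), numeric(1)),
             kind = vapply(rows, function(r) as.character(r$kind),
                           character(1)),
             detail = vapply(rows, function(r) as.character(r$detail),
                             character(1)),
             stringsAsFactors = FALSE)
}

#' Write a telemetry table as CSV
#'
#' Writes the canonical six-column telemetry payload
#' (`t_s,alert,t_body_c,t_indoor_c,rh_pct,exercise`); the internally
#' carried threshold column is dropped.
#'
#' @param telemetry Telemetry data frame from [run_monitor()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_telemetry <- function(telemetry, path) {
  cols <- c("t_s", "alert", "t_body_c", "t_indoor_c", "rh_pct", "exercise")
  stopifnot(is.data.frame(telemetry), all(cols %in% names(telemetry)))
  utils::write.csv(telemetry[cols], path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

# flat key-value representation of a monitor_config
.config_keys <- c("window_s", "dz_th_mg", "count_th", "warmup_s", "fs_hz",
                  "accel_beta", "temp_beta", "t_normal", "t_exercise",
                  "hold_min", "dwell_min", "indoor_temp_lo",
                  "indoor_temp_hi", "indoor_rh_lo", "indoor_rh_hi",
                  "telemetry_period_s", "seed", "cal_t_ref", "cal_t_avg",
                  "cal_n")

#' Save a monitor configuration as a flat YAML file
#'
#' The file is a flat key-value document whose defaults are the decision
#' constants of the monitoring method (30 s windows, 90 mg, 24 spikes,
#' 37.0/37.5 degC thresholds, 20 min hold, 12 min dwell, 20-24 degC and
#' 20-60 % indoor bounds, 5 s telemetry). [load_config()] rejects unknown
#' keys and round-trips exactly.
#'
#' @param cfg A [monitor_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "monitor_config"))
  flat <- list(
    window_s = cfg$rsc$window_s, dz_th_mg = cfg$rsc$dz_th_mg,
    count_th = cfg$rsc$count_th, warmup_s = cfg$rsc$warmup_s,
    fs_hz = cfg$rsc$fs_hz, accel_beta = cfg$rsc$accel_beta,
    temp_beta = cfg$temp_beta,
    t_normal = cfg$thresholds$t_normal,
    t_exercise = cfg$thresholds$t_exercise,
    hold_min = cfg$thresholds$hold_min,
    dwell_min = cfg$alert$dwell_min,
    indoor_temp_lo = cfg$indoor$temp_lo,
    indoor_temp_hi = cfg$indoor$temp_hi,
    indoor_rh_lo = cfg$indoor$rh_lo,
    indoor_rh_hi = cfg$indoor$rh_hi,
    telemetry_period_s = cfg$telemetry_period_s,
    seed = cfg$seed
  )
  if (!is.null(cfg$calibration)) {
    flat$cal_t_ref <- cfg$calibration$t_ref
    flat$cal_t_avg <- cfg$calibration$t_avg
    flat$cal_n <- cfg$calibration$n
  }
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' Load a monitor configuration from a flat YAML file
#'
#' @param path Path to a YAML file written by [save_config()] (or edited
#'   by hand). Unknown keys are rejected; absent keys keep their defaults.
#' @return A [monitor_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  flat <- yaml::read_yaml(path)
  unknown <- setdiff(names(flat), .config_keys)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  get <- function(key, default) if (!is.null(flat[[key]])) flat[[key]] else default
  cal <- NULL
  if (!is.null(flat$cal_t_ref)) {
    if (is.null(flat$cal_t_avg) || is.null(flat$cal_n)) {
      stop("calibration keys must be given together: cal_t_ref, cal_t_avg, cal_n",
           call. = FALSE)
    }
    cal <- structure(list(t_ref = flat$cal_t_ref, t_avg = flat$cal_t_avg,
                          bias = flat$cal_t_ref - flat$cal_t_avg,
                          n = as.integer(flat$cal_n)),
                     class = "calibration_model")
  }
  monitor_config(
    rsc = rsc_config(window_s = get("window_s", 30),
                     dz_th_mg = get("dz_th_mg", 90),
                     count_th = get("count_th", 24),
                     warmup_s = get("warmup_s", 30),
                     fs_hz = get("fs_hz", 20),
                     accel_beta = get("accel_beta", 0.5)),
    thresholds = threshold_config(t_normal = get("t_normal", 37.0),
                                  t_exercise = get("t_exercise", 37.5),
                                  hold_min = get("hold_min", 20)),
    alert = alert_config(dwell_min = get("dwell_min", 12)),
    indoor = indoor_bounds(temp_lo = get("indoor_temp_lo", 20),
                           temp_hi = get("indoor_temp_hi", 24),
                           rh_lo = get("indoor_rh_lo", 20),
                           rh_hi = get("indoor_rh_hi", 60)),
    temp_beta = get("temp_beta", 0.5),
    calibration = cal,
    telemetry_period_s = get("telemetry_period_s", 5),
    seed = get("seed", 0L)
  )
}

#' Human-readable session report
#'
#' Formats a session the way a daily log sheet would: body-temperature
#' minimum / maximum / average / standard deviation, the thresholds that
#' were in force, whether an alert fired (and when the first one did), and
#' the minutes classified as exercise.
#'
#' @param result A `monitor_result` from [run_monitor()].
#' @return Character vector of report lines, invisibly; the report is also
#'   printed.
#' @export
report <- function(result) {
  stopifnot(inherits(result, "monitor_result"))
  if (nrow(result$telemetry) == 0L) {
    lines <- "Empty session: no telemetry records."
    cat(lines, sep = "\n")
    return(invisible(lines))
  }
  s <- result$summary
  alerts <- result$events[result$events$kind == "alert_raised", , drop = FALSE]
  period <- if (nrow(result$telemetry) > 1L) {
    stats::median(diff(result$telemetry$t_s))
  } else {
    NA_real_
  }
  ex_min <- if (is.na(period)) 0 else
    sum(result$telemetry$exercise) * period / 60
  lines <- c(
    "Session report",
    "--------------",
    sprintf("Records          : %d telemetry rows over %.1f min", s$n,
            diff(range(result$telemetry$t_s)) / 60),
    sprintf("Minimum (degC)   : %.2f", s$min_c),
    sprintf("Maximum (degC)   : %.2f", s$max_c),
    sprintf("Average (degC)   : %.2f", s$mean_c),
    sprintf("Std (degC)       : %.2f", s$std_c),
    sprintf("T_TH applied     : %s degC",
            paste(sort(unique(result$telemetry$t_th_c)), collapse = " / ")),
    sprintf("Exercise minutes : %.1f", ex_min),
    if (nrow(alerts)) {
      sprintf("Alert            : Yes (first at %.0f s)", alerts$t_s[1L])
    } else {
      "Alert            : No"
    }
  )
  cat(lines, sep = "\n")
  invisible(lines)
}
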