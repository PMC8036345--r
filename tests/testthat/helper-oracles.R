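# Independent oracles used across the suite. They deliberately avoid the
# package's streaming code paths: filtering goes through stats::filter and
# window counting is a vectorized pass over precomputed differences.

# reference IIR low-pass: y_1 = x_1, y_i = b x_i + (1 - b) y_{i-1}
oracle_lowpass <- function(x, beta) {
  if (length(x) == 0L) return(numeric(0))
  if (beta == 0) return(rep(x[1L], length(x)))
  # init seeds y_0; choosing y_0 = x_1 makes y_1 = x_1
  as.numeric(stats::filter(beta * x, 1 - beta, method = "recursive",
                           init = x[1L]))
}

# brute-force per-window spike counts over an acceleration stream:
# filter, difference, assign each delta to the window of its later sample,
# tabulate. Windows are (anchor + (k-1) W, anchor + k W], anchor = t0 +
# warmup. Only windows fully covered by the stream are returned.
oracle_window_counts <- function(accel, cfg) {
  t <- accel$t_s
  filt <- oracle_lowpass(accel$az_g, cfg$accel_beta)
  dz <- abs(diff(filt)) * 1000
  t_later <- t[-1L]
  anchor <- t[1L] + cfg$warmup_s
  k <- ceiling((t_later - anchor) / cfg$window_s - 1e-9)
  keep <- k >= 1
  spikes <- tapply(dz[keep] >= cfg$dz_th_mg, k[keep], sum)
  k_max <- floor((t[length(t)] + 1 / cfg$fs_hz - anchor) / cfg$window_s + 1e-9)
  counts <- integer(k_max)
  if (k_max >= 1) {
    idx <- as.integer(names(spikes))
    ok <- idx <= k_max
    counts[idx[ok]] <- as.integer(spikes[ok])
  }
  if (k_max < 1) return(data.frame(window_end_s = numeric(0),
                                   count = integer(0)))
  data.frame(window_end_s = anchor + seq_len(k_max) * cfg$window_s,
             count = counts)
}

# builds a raw stream whose post-warm-up window holds exactly `k` deltas of
# `amp_mg` (meant for configs with accel_beta = 1 so deltas are exact):
# the level toggles between 1 g and 1 g + amp at k separated samples.
toggle_window_stream <- function(k, amp_mg, cfg) {
  n_warm <- cfg$warmup_s * cfg$fs_hz
  n_win <- cfg$window_s * cfg$fs_hz
  n <- n_warm + n_win
  t <- (seq_len(n) - 1) / cfg$fs_hz
  az <- rep(1, n)
  if (k > 0) {
    pos <- n_warm + floor(seq(2, n_win - 2, length.out = k))
    level <- 1
    j <- 1L
    for (i in (n_warm + 1L):n) {
      if (j <= k && i == pos[j]) {
        level <- if (level == 1) 1 + amp_mg / 1000 else 1
        j <- j + 1L
      }
      az[i] <- level
    }
  }
  data.frame(t_s = t, az_g = az)
}

# ground-truth exercise intervals from a schedule
schedule_exercise_intervals <- function(sched) {
  sched[sched$mode == "exercise", c("start_s", "end_s"), drop = FALSE]
}

# standard session fixture: one exercise bout inside a quiet session
session_streams <- function(ex_start = 330, ex_end = 930, total = 2730,
                            seed = 1, noise_sd = 0.2, fever = NULL) {
  sched <- activity_schedule(c("normal", "exercise", "none"),
                             c(ex_start, ex_end - ex_start, total - ex_end))
  list(
    schedule = sched,
    accel = generate_accel(sched, seed = seed),
    temp = generate_temperature(
      sched, temp_model_params(noise_sd = noise_sd, fever_target = fever),
      seed = seed + 1000L),
    indoor = generate_indoor(total, seed = seed + 2000L)
  )
}
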