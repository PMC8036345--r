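# rscmonitor

Streaming analysis engine for wrist-worn quarantine monitoring: it turns
three raw sensor streams — Z-axis acceleration from a MEMS accelerometer
(20 Hz, ±2 g), body temperature from a contact or infrared thermometer,
and indoor temperature / relative humidity — into exercise classifications,
activity-adaptive fever alerts and a flat telemetry feed, entirely on the
desk. It is aimed at people prototyping or validating wearable
fever-alert logic who need every decision rule to be inspectable and
testable without hardware: all inputs can be synthesized by the package's
seeded generators.

## The method

**Exercise recognition (RSC — Repetition Spikes Counter).** Raw Z
acceleration is smoothed with a first-order IIR low-pass filter
`y_i = β·x_i + (1 − β)·y_{i−1}` (β = 0.5), then consecutive samples are
differenced. A difference with `|Δz| ≥ 90 mg` is a *spike*; a tumbling
30-s window with `count ≥ 24` spikes is classified as physical exercise.
Repetitive training motion produces dense trains of large differences,
while ordinary movement gives sparse, small ones, so a simple counter
separates the two without any trained model.

**Adaptive fever threshold.** The alert threshold `T_TH` is 37.0 °C during
normal activity and 37.5 °C during exercise and for 20 minutes afterwards
(body temperature normally recovers within that time), so
exercise-induced warming cannot trip the alarm.

**Dwell-time alert.** An alert is raised only when the evaluated body
temperature satisfies `T_body ≥ T_TH` *continuously* for 12 minutes; a
single sub-threshold sample restarts the timer. When the alert fires, the
engine also requests a one-shot infrared confirmation reading, which
bypasses filtering and calibration.

**Thermometer calibration.** The wrist sensor is calibrated against a
reference core reading: `T_bias = T_ref − mean(first N raw samples)`
(N = 50, after a 10-minute stabilization), and `T_cal = T_raw + T_bias`
thereafter.

**Indoor check.** Room conditions are classified against the recommended
quarantine ranges 20–24 °C and 20–60 % RH (inclusive bounds).

## Worked example

Simulate a 45.5-minute session with a 10-minute exercise bout starting at
t = 330 s, in a slightly dry room, and run the full pipeline:

```r
library(rscmonitor)

sched  <- activity_schedule(c("normal", "exercise", "none"), c(330, 600, 1800))
accel  <- generate_accel(sched, seed = 1)
temp   <- generate_temperature(sched, seed = 2)
indoor <- generate_indoor(2730, temp_c = 23.5, rh_pct = 18, seed = 3)

result <- run_monitor(accel, temp, indoor)
result$events
#>   t_s                kind         detail
#> 1   0 indoor_out_of_range temp=ok rh=low
#> 2 360      exercise_start       count=90
#> 3 960        exercise_end        count=0
report(result)
#> Session report
#> --------------
#> Records          : 547 telemetry rows over 45.5 min
#> Minimum (degC)   : 36.22
#> Maximum (degC)   : 36.94
#> Average (degC)   : 36.61
#> Std (degC)       : 0.13
#> T_TH applied     : 37 / 37.5 degC
#> Exercise minutes : 10.0
#> Alert            : No
```

Reading the output: the room humidity (18 %) is below the 20 % bound, so
the session opens with an `indoor_out_of_range` event. The exercise bout
scheduled for 330–930 s is detected at the first full window boundary
inside it (360 s) with 90 spikes per window, and ends one window after the
bout (960 s). The threshold ran at 37.5 °C during the bout and for 20
minutes after it (both values appear under `T_TH applied`); body
temperature stayed in the normal band, so no alert fired.

The same engine is scriptable from a shell via `exec/monitor`
(`simulate`, `run`, `calibrate`, `report` subcommands), with streams as
CSV, events as JSON lines and the configuration as a flat YAML file.

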