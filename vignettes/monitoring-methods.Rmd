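---
title: "Methods: wearable fever monitoring with activity-adaptive thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wearable fever monitoring with activity-adaptive thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rscmonitor)
```

## The monitoring problem

A person in home quarantine should have their body temperature watched
continuously, but a fixed fever threshold fails in practice for two
reasons: wrist-worn contact thermometers are noisy and biased relative to
core temperature, and physical exercise legitimately raises body
temperature by around half a degree. `rscmonitor` implements the
processing chain of a wearable monitor that addresses both: filtering and
calibration for the sensor artifacts, and accelerometer-based exercise
recognition that adapts the alert threshold to activity.

The package operates on three time-stamped streams per session (relative
seconds; sessions are independent, with no state carried across them):
Z-axis acceleration at 20 Hz, body temperature (contact or infrared
source), and indoor temperature/relative humidity updated every 5 s.

## Signal conditioning

**Low-pass filter.** All smoothing uses the first-order recursive filter
$y_i = \beta x_i + (1-\beta)\,y_{i-1}$ with $\beta \in [0,1]$. $\beta = 1$
is the identity; smaller $\beta$ filters harder but responds more slowly.
Both the temperature and the acceleration paths default to $\beta = 0.5$,
a compromise between noise suppression and dynamic response. Three
properties make the filter predictable and are enforced by tests: each
output lies between the previous output and the new input (convexity), a
constant stream is a fixed point, and white-noise variance is strictly
reduced.

*Initialization.* The first sample passes through unchanged and seeds the
recursion. The alternative — seeding with a nominal prior such as
36.5 °C — would bias the first minutes of every session for no benefit.
The recursion is applied to the previous *output* (an IIR structure),
not the previous raw input; with the previous-input reading the "filter"
would be a two-tap FIR average with far weaker smoothing.

**Calibration.** The contact sensor on the wrist reads low relative to
core temperature. After a stabilization interval (default 600 s — the
time a reference glass thermometer needs to settle, and enough for the
wrist sensor to reach skin equilibrium), the first $N = 50$ raw samples
are averaged and the additive bias $T_{bias} = T_{ref} - T_{avg}$ is
stored; every later contact reading gets $T_{cal} = T_{raw} + T_{bias}$.
The model is deliberately a single offset: gain errors of this sensor
class are small over the 35–40 °C span of interest, and an offset is
identifiable from one reference point. Calibration applies to contact
readings only; infrared spot checks are an independent confirmation path
and pass through raw.

## Exercise recognition (RSC)

The Repetition Spikes Counter classifies activity from the Z axis alone.
Per sample: filter, take the absolute difference to the previous filtered
sample (in milli-g), call it a spike if it reaches `dz_th_mg`, and count
spikes in tumbling windows of `window_s`. A window whose count reaches
`count_th` is exercise. Defaults: 30 s windows, 90 mg, 24 spikes, with the
first 30 s of each session discarded as sensor start-up.

Numerical conventions, chosen once and enforced as boundaries by the
acceptance suite:

* **Inclusive thresholds.** `|Δz| ≥ 90 mg` is a spike and `count ≥ 24` is
  exercise, so the configured constants are themselves the decision
  boundaries rather than the last excluded values.
* **Tumbling, not sliding, windows**, anchored at the end of warm-up:
  the device this models makes one verdict per period, and tumbling
  windows keep each difference attributable to exactly one verdict.
* **Boundary deltas** belong to the window containing the *later* sample,
  so every consecutive pair is counted exactly once.
* **Dropouts.** A gap longer than two sampling intervals clears the
  differencing memory: a transmission dropout would otherwise manufacture
  one large spurious difference.
* **Trailing data.** A partial final window yields no verdict; in batch
  mode a window whose last expected sample was seen counts as complete.

Raising `dz_th_mg` can only lower window counts, and raising `count_th`
can only demote windows from exercise to normal (monotonicity); the
streaming counter is checked window-for-window against an independent
vectorized recount over 1,000 random windows.

## Threshold manager and alert state machine

The threshold is binary by design: `t_normal = 37.0 °C` during ordinary
activity and `t_exercise = 37.5 °C` during exercise — normal core
temperature is 36.5–37 °C and a primed, exercising body sits near
37.5 °C. The elevated value persists for `hold_min = 20` minutes after
the *end of the last exercise window*, matching typical post-exercise
thermal recovery; every new exercise window restarts the hold. Reversion
happens at the first evaluation at or beyond the 20-minute mark, so the
hold is exact at the evaluation cadence.

The alert requires `T_body ≥ T_TH` continuously for `dwell_min = 12`
minutes. "Continuously" is interpreted at sample resolution: any single
sub-threshold sample clears the timer. Exceedance is re-evaluated against
the *current* threshold at every sample, which has one deliberate
consequence: if exercise begins mid-dwell and lifts the threshold above
the current body temperature, the timer clears — the whole point of the
adaptive threshold is to excuse exercise-induced rises. `alert_raised` is
edge-triggered (once per episode) and is paired with a
`request_infrared_confirmation` event, since a contact-sensor fever
should be verified with the more trustworthy spot reading; the telemetry
Boolean stays 1 until a sub-threshold sample emits `alert_cleared`. On a
uniformly sampled step input the alert lands within one sampling interval
after exactly `dwell_min` minutes.

Indoor conditions are classified per dimension (`low`/`ok`/`high`)
against inclusive bounds 20–24 °C and 20–60 % RH. Real deployments
occasionally sit just outside these bands (a dry heated room in winter,
an afternoon at 25 °C); the checker flags them regardless, leaving
interpretation to the observer.

## Pipeline and telemetry

`run_monitor()` merges the three streams in time order. Ties are resolved
deterministically: window verdicts update the threshold first, then
temperature and indoor samples are evaluated, and the telemetry snapshot
comes last, so a record at time *t* reflects everything known at *t*.
Fusion is sample-and-hold — each stream's latest value is carried forward
to the 5-s telemetry ticks, mirroring a device that reads its sensors at
independent rates and displays the latest values. Exercise status between
window boundaries is the last window's verdict, undebounced; debouncing
would only delay the threshold adaptation the verdict exists to drive.
The telemetry row is the flat payload an MQTT dashboard would receive
(`t_s, alert, t_body_c, t_indoor_c, rh_pct, exercise`, Booleans as 0/1);
the threshold in force is carried as an extra internal column for
inspection and dropped by the CSV writer. An empty acceleration stream
degrades gracefully (exercise stays 0); an empty temperature stream is an
error, since the monitor is then pointless. Session summaries report
min/max/mean and the *population* standard deviation, the natural
descriptive spread of a fully observed session.

## What the generators emulate — and what they do not

The synthetic module exists so that every stage is testable without any
recorded data; its defaults are the study conditions the package assumes.

* **Acceleration.** No motion is 1 g plus 2 mg Gaussian sensor noise.
  Normal activity adds sparse single-sample excursions of 20–60 mg at
  0.2/s — deliberately capped below the 90 mg spike threshold, encoding
  the assumption that ordinary movement shows small differences at low
  frequency. Exercise adds a deterministic ±100 mg square wave at 1.5 Hz:
  about 90 super-threshold differences per 30-s window, so exercise
  windows reach the 24-spike criterion with certainty rather than with
  high probability, and schedule-recovery tests are exact. After the
  β = 0.5 filter a 200 mg flip still yields a 100 mg first difference,
  keeping a clean margin over 90 mg.
* **Body temperature.** First-order relaxation toward an
  activity-dependent set point: baseline 36.5 °C, +0.5 °C during
  exercise, time constant 1200 s so recovery is essentially complete
  within the 20-minute hold; white measurement noise with sd 0.2 °C, the
  spread a wrist contact sensor shows in practice. A fever is a monotone
  ramp to a plateau (`fever_target`) that holds.
* **Indoor.** Start values plus linear drift and small noise, sampled
  every 5 s.

These generators reproduce the *statistical structure the decision rules
key on*, not wearable physics: no gait harmonics or multi-axis coupling,
no circadian or ambient-coupled temperature variation, no sensor drift or
quantization. Passing tests therefore demonstrate that the decision logic
is correct at its boundaries and robust to the modelled noise — not that
the thresholds themselves are clinically optimal for any particular
wearer.

## Problem sizes and determinism

All randomness flows through explicit integer seeds; identical seeds give
byte-identical streams, events and telemetry. The test suite runs
sessions of roughly 45 minutes (54,000 acceleration samples), checks the
counting oracle over 1,000 windows and schedule recovery over ten seeded
sessions with randomized bouts; the whole suite completes in about a
minute on one CPU. The acceptance script replays a 20-minute step-input
fever trace and a 50-minute one-bout session.

## Known limitations

* Only the Z axis is used; activities with predominantly horizontal
  motion could evade the counter (a limitation shared with the device
  this models).
* The calibration is a constant offset from a single reference; it does
  not track drift within or across sessions.
* The 12-minute dwell means genuinely abrupt high fevers are reported
  with that latency by construction.
* Sessions are independent: a fever episode spanning a battery swap
  restarts its dwell.
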