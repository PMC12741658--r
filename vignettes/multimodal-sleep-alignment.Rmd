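---
title: "Deriving and aligning multimodal sleep measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and aligning multimodal sleep measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Outside the sleep laboratory there is no polysomnographic ground truth, yet
clinical sleep research increasingly relies on consumer-grade and ambient
devices: wrist actigraphs that score 30-second epochs as
`ACTIVE`/`REST`/`REST-S`, ballistocardiographic mattress sensors that emit a
1 Hz occupancy/sleep status code (`1` = asleep; `0`, `2`, `3` = not in bed,
awake in bed, signal overload), smartphone screen event logs (`on`, `off`,
`lock`, `unlock`), and brief morning self-reports with categorical total
sleep time ("under 5 hours" ... "over 10 hours"). Each modality measures a
different physical correlate of sleep, so the derived nightly parameters --
onset, offset and total sleep time (TST) -- disagree systematically. This
package implements the full chain from raw event streams to quantified
cross-modal agreement, and a synthetic cohort generator so that every stage
can be validated against known ground truth.

## Deriving nightly sleep measures

All timestamps are standardized to Europe/Helsinki (conversion only changes
the display zone, never the instant). Days are aligned on a **3 PM-to-3 PM
window**: the study day of an instant is the calendar date of the most recent
local 15:00, half-open `[15:00 D, 15:00 D+1)`. This keeps a whole night --
including late onsets after midnight -- inside a single analysis unit. All
onset/offset arithmetic is done in *window-relative minutes* (minutes since
the 15:00 start), which avoids the midnight wrap-around; wall-clock strings
are presentation only.

For the label streams, maximal runs of sleep-marked samples are grouped into
episodes, and two runs separated by at most **5 minutes** of non-sleep are
merged, the gap counting toward the episode span ("up to 5 minutes" is read
as inclusive; the same rule is applied to the 30-second and the 1 Hz stream,
which the source description leaves open). For the smartphone, a two-state
machine maps `lock`/`off` to inactive and `unlock`/`on` to active, emits
maximal inactive intervals, ignores redundant repeated events, opens no
interval before the first observed event, and discards a trailing interval
whose end was never observed. The same 5-minute merge is applied across
brief nocturnal phone checks.

Within each window, the **longest** candidate is classified as nocturnal
sleep (ties broken by earliest onset, for determinism); an episode belongs to
the window containing its onset. Selection happens **before** the 3-13 h
plausibility filter: a main episode failing the filter yields no record for
that day rather than promoting the runner-up, because the filter is meant to
exclude implausible days, not to re-rank candidates. The bounds are
inclusive (180 and 780 minutes both keep).

Categorical morning reports convert to interval midpoints ("6-7 hours" is
6.5 h). The open-ended categories are not defined numerically by the source;
we use half an hour beyond the bound (4.5 h and 10.5 h), consistent with the
one-hour inner bins.

Finally, per modality, the 2 largest outliers in each of the onset and
offset columns -- largest absolute deviation from the column mean, on
window-relative minutes -- are removed as a union (a row extreme in both
columns is removed once). The source does not state whether this operated on
participant-day rows or participant means; rows are used here, and `k` is
configurable.

## Agreement statistics

Day-to-day variability is absorbed by averaging each participant's records
per modality before pairwise comparison; a participant enters a comparison
only with both modalities present (pairwise deletion, which is why each
comparison has its own n). For a pair "A vs B" the differences are `A - B`
(positive onset bias: A detects sleep later).

Bland-Altman agreement reports the mean bias, the sample SD of the
differences, 95% limits of agreement `bias ± 1.96·SD` (the conventional
normal quantile, not a t quantile), and a t-based confidence interval for
the bias itself. Paired two-sided t tests, Pearson correlations with
Fisher-z confidence intervals, and Shapiro-Wilk normality statistics (which
are reported but never block the analysis) complete the picture.
Correlation magnitudes are labelled by the Mukaka bands (negligible < 0.30,
low < 0.50, moderate < 0.70, high >= 0.70; boundaries take the higher band).
Fisher-z intervals are bounded by ±1 by construction; published tables of
this kind sometimes show interval limits above 1, suggesting
regression-slope intervals were used there -- we deliberately keep Fisher z
and document the difference rather than imitate it.

## Mixed models of alignment

Alignment is modelled at the day level: for each metric and modality pair,
the absolute between-modality difference (in hours) on each
participant-day, with a participant random intercept and fixed effects for
age, sex, MEQ chronotype score, diagnostic group (control reference) and
seasonal day length:

`abs_diff ~ age + sex + meq + daylight + group + (1 | participant)`

fitted by REML via lme4, with Wald normal 95% intervals and p-values
(simple, deterministic, and consistent with an "estimate (95% CI)"
presentation). The ICC is `tau00 / (tau00 + sigma2)`; marginal and
conditional R-squared follow the Nakagawa variance-partition definitions
(`var_f / (var_f + tau00 + sigma2)` and `(var_f + tau00) / (...)`).
A singular fit (participant variance at zero) is flagged, not an error.

Day length comes from a NOAA-style solar position routine (declination from
a Meeus low-precision series; sunrise hour angle at -0.833 degrees), clamped
to 0/1440 minutes for polar night/day; it is validated against an
independent almanac ephemeris to within 2 minutes. The daylight covariate is
entered **per hour** by default: coefficient magnitudes of roughly -0.1 per
unit are only plausible per *hour* of day length -- read per minute they
would imply tens of hours of alignment change across Finland's seasonal
daylight swing -- so the per-hour reading is the default and the per-minute
scaling remains available (`daylight_scale = "min"`). The covariate is evaluated at the
wake-up morning (study day + 1), Helsinki coordinates by default.

## The synthetic cohort: what it emulates, what it does not

The generator's defaults (shipped in `inst/extdata/cohort_defaults.json`)
state a fixed world mirroring the published cohort's magnitudes:

* cohort composition 50 controls / 78 MDD / 21 BD / 20 BPD, 14 nights,
  Helsinki, winter start date (2019-01-07, arbitrary but fixed);
* controls: mean onset ~23:55 (60 min between-person SD, 45 min
  night-to-night), TST ~7.6 h; patient groups ~35-45 min later onsets,
  longer TST and larger SDs -- matching the direction and size of the
  published group differences;
* device biases relative to the bed sensor: actigraph +2 min onset /
  +30 min offset, smartphone +6 / -38, each with night-level Gaussian noise
  (20-30 min SD) -- the magnitudes of the published bias tables;
* Bernoulli per-night missingness (25% actigraph, 20% bed, 8% smartphone,
  10% EMA), echoing the ordering of device attrition in the study; the
  study reports attrition, not its mechanism, so independent Bernoulli is a
  deliberate simplification;
* EMA misperception: Gaussian noise (40 min SD) on true TST before binning;
* a seasonal term moving true offsets by -6 min per hour of day length away
  from 12 h (earlier waking in summer).

Nightly parameters are Gaussian around participant means, truncated at
window edges; sleep intervals are rendered half-open `[onset, offset)` on
each device's grid and snapped to the 30-s actigraph grid so a zero-noise
round trip is exact to one grid step. Daytime phone-use bouts have a 6-min
floor: sessions shorter than the 5-minute merge threshold would chain a
whole evening of idle time into one "inactivity" interval, which real users
do not exhibit at that density. The bed stream covers the biased sleep
interval plus a margin rather than a full 24 h at 1 Hz, purely for
tractability; absent samples carry no sleep marks, so derivation is
unaffected.

The generator does **not** emulate: within-night wake architecture (the
source gives none; interruptions are parameterized, not calibrated),
physiological ballistocardiography signal content, medication effects, nap
behaviour, or participant-level device abandonment patterns. A green
round-trip test therefore establishes the correctness of the derivation and
statistics, not the realism of any particular device's failure modes.

## Numerical choices and edge cases

* Gap merging and the TST filter are inclusive at their thresholds.
* Duplicate timestamps: strictly sampled streams keep the first row with a
  warning; the screen log legitimately allows coincident events; EMA keeps
  the first response per participant-date.
* Zero-length or negative inactivity intervals from malformed logs are
  dropped with a warning.
* Display rounding is half away from zero at 2 decimals; CSVs keep full
  precision.
* DST: the 15:00 window boundary never coincides with a Finnish DST
  transition (03:00/04:00), so windows partition the timeline; this is
  tested by exhaustive minute scans over both 2019 transition weeks.
* Degenerate Bland-Altman inputs (zero SD) collapse the limits onto the
  bias and flag the t test rather than dividing by zero.
* The timezone database is repaired at package load when the host R has no
  reachable Olson database (seen in some container images), since every
  windowing rule depends on Helsinki wall-clock time.

## Known limitations

Repeated-measures corrections for Bland-Altman limits are out of scope, as
are nonparametric limits, random slopes, and Satterthwaite/Kenward-Roger
degrees of freedom. The nine alignment models are fitted without
multiple-testing correction, mirroring the source presentation. Raw
vendor-native exports (Actiwatch binary files, bed-node payloads) are not
parsed; ingestion starts from the documented CSV schemas.
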