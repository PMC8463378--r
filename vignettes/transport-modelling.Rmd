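---
title: "Modelling stroke transport paradigms under diurnal traffic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling stroke transport paradigms under diurnal traffic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stroketriage)
```

## The problem

When a patient with a suspected large-vessel occlusion (LVO) stroke is
picked up by emergency medical services, three transport strategies
compete. **Mothership** drives the patient directly to a comprehensive
stroke center (CSC or CSC+), possibly bypassing a closer primary stroke
center (PSC), so thrombectomy (EVT) starts as early as possible at the
cost of a later thrombolysis (IVT) start. **Drip-and-ship (DS)**
thrombolyses at the nearest PSC first and then transfers the patient to a
CSC for EVT. **Drip-and-drive (DD)** also thrombolyses at the PSC, but
moves the neurointerventionalist from a high-volume CSC+ to the PSC's
angiosuite instead of moving the patient.

Which paradigm is best depends on geography *and on the clock*: commuter
traffic is directional, so the patient's suburban-to-urban leg and the
interventionalist's urban-to-suburban leg are delayed at different times
of day. This package models that interaction and classifies every
location of a region by the paradigm with the highest predicted
probability of good outcome (modified Rankin Scale 0–1 at 90 days),
hour by hour.

## The outcome model

For a screen-positive patient (RACE ≥ 5) the expected probability of good
outcome given an onset-to-needle time $t_n$ and onset-to-groin time $t_g$
is a conditional-probability composition over the cohort:

$$
\begin{aligned}
P(\text{good}) ={}& p_{\mathrm{LVO}}\Big[ r_{\mathrm{EVT}}\,
  P_{\mathrm{EVT}}(t_g) + (1-r_{\mathrm{EVT}})\big( e\, r_{\mathrm{IVT}}
  P_{\mathrm{IVT/LVO}}(t_n) + (1 - e\, r_{\mathrm{IVT}})\,
  u_{\mathrm{LVO}} \big) \Big] \\
  &+ p_{\mathrm{nLVO}}\Big[ e\, r_{\mathrm{IVT}}
  P_{\mathrm{IVT/nLVO}}(t_n) + (1 - e\, r_{\mathrm{IVT}})\,
  u_{\mathrm{nLVO}} \Big] + p_{\mathrm{other}}\, u_{\mathrm{other}},
\end{aligned}
$$

where $e = \mathbf{1}[t_n < 270\,\text{min}]$ is IVT eligibility (strict
"< 4.5 h"), $r_{\mathrm{EVT}} = 0.9$ and $r_{\mathrm{IVT}} = 0.8$ are the
assumed treatment rates, the $P_\cdot(t)$ are monotone non-increasing
decay curves clamped to their treatment windows, and the $u_\cdot$ are
constant outcome probabilities for untreated and mimic patients.

Three points deserve emphasis:

* **The composition is a reconstruction.** The published description of
  the underlying conditional-probability model states its ingredients
  (LVO probability, geography, hospital efficiency, time to treatment)
  but not its algebra. The formula above is the simplest composition that
  honours every stated constraint; in particular, an EVT-treated
  patient's outcome is attributed to the EVT curve alone, with no
  IVT-then-EVT interaction term, because no such interaction is
  documented.
* **The decay curves are pluggable configuration.** The defaults
  (`default_curves()`) are synthetic logistic ramps — EVT from 0.50 to
  0.10 over a 360-min window, IVT over 270 min — with scales chosen so
  the decline is gentle and near-linear over most of the window, as
  trial meta-analyses report. They are placeholders: real applications
  must supply published coefficients via the configuration file.
* **Monotonicity has a validity domain.** $P(\text{good})$ is
  non-increasing in both times provided treatment at the curve floor is
  no worse than no treatment ($P_\cdot(t_{\max}) \ge u_\cdot$). If a
  configuration violates that (late IVT "worse than nothing"), the
  expectation jumps upward when eligibility lapses at 270 min. The
  shipped defaults and test fixtures respect the domain.

## Paradigm timelines

Workflow constants (all minutes, `workflow_times()`): onset to first
medical response 30, on-scene 30, door-to-needle 30 at PSC and CSC,
needle-to-door 20 at the PSC, door-to-groin 60 at the CSC, 30 when no
reimaging is needed, needle-to-interventionalist-leave 10 and
interventionalist-arrival-to-groin 20 for DD. The three event chains:

```{r timelines}
mothership_timeline(50)$trace
drip_and_ship_timeline(20, 30)$trace
drip_and_drive_timeline(20, 60)$trace
```

The DS chain has one genuine discontinuity: if the patient reaches the
CSC within 90 min of first imaging at the PSC (inclusive — "within" is
read as ≤), reimaging is skipped and door-to-groin drops from 60 to
30 min, so DS groin time jumps by exactly 30 min as the transfer length
crosses the threshold. First imaging is assumed to happen at PSC arrival
(`imaging_offset_psc = 0`); the offset is exposed as configuration
because the moment of "first imaging" inside the 30-min door-to-needle
interval is not otherwise pinned down. A consequence worth knowing: with
co-located hospitals and zero travel the DS chain *qualifies* for the
fast track (arrival 50 min after imaging), giving an onset-to-groin of
140 min rather than the 170 min one would get if reimaging were always
required.

The DD groin time is driven by the interventionalist chain
(needle + 10 + drive + 20); a `max()` guard against patient readiness is
implemented for robustness with user-supplied constants, although with
the defaults the interventionalist chain always dominates. Negative
traffic deltas may never push a door-to-X interval below zero; intervals
are clamped at zero with a warning.

## Traffic

Hourly travel times for the 68-km reference route between the urban CSC+
and the suburban PSC are expressed as *deltas* against the 03:00 value of
the same profile (low traffic, ambulance right of way). The delta of the
urban-to-suburban profile delays the DD interventionalist; the
suburban-to-urban delta delays the DS transfer and the mothership
patient (applied to both CSC door times). The mothership direction is an
assumption — the patient travels *towards* the urban CSC — since no
direction is stated for that paradigm.

Deltas generalise to all routes as absolute minutes, mirroring how the
reference route's differences were generalised region-wide; a
proportional mode (`delta_mode: proportional`) exists behind a
configuration flag but is off by default. Hours are integral; a timeline
is evaluated at its dispatch hour without within-hour interpolation.

The bundled profiles (`bundled_traffic_profiles()`) are smooth
piecewise-linear 24-h curves constructed to reproduce the observed
summaries exactly — weekday urban-to-suburban mean 66 / max 93 at 16:00,
suburban-to-urban mean 65 with peaks 90 at 07:00 and 78 at 16:00,
weekend means 57/57 with maxima 65 and 60 — while the unobserved 03:00
baselines (50/50/48/53 min) are a choice consistent with those
constraints, not data. Between the pinned points the hourly values are
non-unique; any smooth curve matching the summaries would do.

```{r traffic}
sapply(bundled_traffic_profiles(), function(p) summarize_profile(p)$mean)
```

## Synthetic geography

No real road network or hospital coordinates are used anywhere: the
geography module generates planar regions in km with a travel model
`detour × distance / speed`. Relative travel times are all the model
needs, so geodesy is deliberately avoided. Two presets:

* `toy3` — 100 × 100 km, one CSC+ (urban), one CSC, one PSC 68 km from
  the CSC+ (the reference-route distance). Its travel speed,
  1.36 km/min, makes the CSC+→PSC drive exactly the 50-min 03:00
  baseline of the bundled weekday profile.
* `nwde-like` — 352 × 182 km (64,064 km² on the default 2-km cells,
  matching a 64,065 km² territory to within one cell) with 21 PSCs,
  23 CSCs and 5 CSC+ placed on a lattice with seeded ±4 km jitter such
  that the mean nearest PSC→CSC distance is ≈ 44 km and the mean nearest
  CSC+→PSC distance ≈ 67 km, the territory's reported averages. The
  lattice guarantees the distance bands for every seed; tests verify
  them by brute-force pairwise scans.

Cell size defaults to 2 km, which keeps a full territory-scale day
(16,016 cells × 24 h × 3 paradigms) under a second thanks to the
vectorised classifier. Unroutable (no-road) cells are supported as a
per-cell flag and count toward total area but are never classified.

## Catchment classification

For each routable cell: mothership travels to the nearest CSC/CSC+; DS
goes to the nearest PSC and transfers to the CSC/CSC+ nearest *to that
PSC* (the transfer decision is made at the PSC, not at the scene); DD
uses the CSC+ nearest to that PSC for the interventionalist. The hour's
deltas are applied, the expected good-outcome probability is evaluated
for each available paradigm, and the cell takes the argmax label.

Numerical choices: probabilities are rounded to 12 decimals before
comparison so ties are platform-reproducible, and ties break by fixed
priority mothership > DS > DD (fewest handoffs). A paradigm whose
required hospitals are missing (no PSC, or no CSC+ for DD) is excluded
from the argmax. Areas are exact cell-count arithmetic; percentages are
taken against the *total* region area including unroutable cells and
rounded half away from zero — the convention that reproduces every
reported area/percentage pair (e.g. 30,879 of 64,065 km² → 48%).

```{r catchment}
region <- generate_region(1, "toy3")
cfg <- model_config()
hs <- hourly_series(region, bundled_traffic_profiles(), cfg, "weekday")
subset(hs$areas, hour %in% c(3, 7, 16) & km2 > 0)
```

On the toy region the qualitative diurnal pattern emerges: mothership
dominates at night, DD peaks during the morning rush (the
interventionalist drives against the commute while the patient would
drive with it), and DS appears in the afternoon rush when the transfer
direction runs against the commute. The *magnitudes* of the
territory-scale catchment areas depend on the real road network and
hospital geography and are not reproducible on synthetic geography;
the package's claims are therefore structural (partition of the region,
delta monotonicity, oracle-equivalence of the vectorised classifier)
plus exact worked arithmetic on the reported number pairs.

## Operation logs

The operation-log module summarises emergency-operation records
(timestamp, alert-to-angiosuite transfer minutes) by day type
(weekday = Mon–Fri) and hour, with half-away-from-zero integer
percentages of the full log and per-stratum medians/means. Clock windows
are half-open `[start, end)` and may wrap midnight; the reported
"12 p.m. to 7 a.m." night window is interpreted as midnight-to-07:00.
The `lueneburg-like` preset of `generate_oplog()` has *deterministic*
per-(day type, hour) counts reproducing every reported marginal —
128 operations, 106/22 weekday/weekend split, 69 in the weekday 08:00–17:00
window, none at 02:00–03:59, a maximum of 15 at 10:00 — while dates
within a stratum and transfer times (normal around 82 min, floored at
20) are seeded draws. One known rounding wrinkle in the source material:
69/128 is 53.9%, which half-away rounding reports as 54%.

## Problem sizes and limitations

The test suite runs the oracle-equivalence check on 50 × 50 grids across
all 24 hours and both day types, and property sweeps on coarser toy
grids; the full suite completes in well under a minute. Known
limitations: no air transport or mobile stroke units, no seasonality or
incident congestion, no sub-hourly resolution, no real geography, binary
good/poor outcome only, and synthetic decay-curve defaults — all
inherited scope bounds of the modelling framework rather than
implementation gaps.
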