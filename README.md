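# stroketriage

Transport-paradigm catchment modelling for acute stroke under diurnal
traffic.

When emergency services pick up a patient with a suspected large-vessel
occlusion (LVO), three strategies compete: **mothership** (drive
directly to a comprehensive stroke center, CSC/CSC+), **drip-and-ship**
(thrombolyse at the nearest primary stroke center, PSC, then transfer
the patient) and **drip-and-drive** (thrombolyse at the PSC while a
neurointerventionalist drives out from a high-volume CSC+). Because
commuter traffic is directional and varies over the day, the best choice
depends on both *where* and *when* the stroke happens. This package is
for health-services researchers and stroke-network planners who want to
model that interaction on fully synthetic, reproducible geography.

## The model

For a screen-positive patient (RACE ≥ 5) with onset-to-needle time
*t<sub>n</sub>* and onset-to-groin time *t<sub>g</sub>*, the expected
probability of good outcome (mRS 0–1 at 90 days) is

P(good) = p<sub>LVO</sub> [ r<sub>EVT</sub> P<sub>EVT</sub>(t<sub>g</sub>) +
(1 − r<sub>EVT</sub>)( e r<sub>IVT</sub> P<sub>IVT/LVO</sub>(t<sub>n</sub>) +
(1 − e r<sub>IVT</sub>) u<sub>LVO</sub> ) ] +
p<sub>nLVO</sub> [ e r<sub>IVT</sub> P<sub>IVT/nLVO</sub>(t<sub>n</sub>) +
(1 − e r<sub>IVT</sub>) u<sub>nLVO</sub> ] +
p<sub>other</sub> u<sub>other</sub>

with IVT eligibility e = 1[t<sub>n</sub> < 270 min], treatment rates
r<sub>EVT</sub> = 0.9 and r<sub>IVT</sub> = 0.8, monotone non-increasing
decay curves P(·) clamped to their treatment windows, and constant
untreated/mimic outcomes u. Onset-to-treatment times come from
per-paradigm event timelines built from workflow constants (response 30,
on-scene 30, door-to-needle 30, needle-to-door 20, door-to-groin 60 — or
30 when the transferred patient arrives within 90 min of first imaging
and needs no reimaging — and the 10/20-min drip-and-drive handoffs),
shifted by hourly directional traffic deltas relative to a 3 a.m.
baseline. Every grid cell of a region is labelled with the
argmax-probability paradigm; catchment areas are cell-count arithmetic.

The outcome composition is a documented reconstruction and the shipped
decay-curve coefficients are synthetic placeholders — supply published
coefficients through the configuration file for real applications. See
`vignettes/transport-modelling.Rmd` for the full account.

## Worked example

```r
library(stroketriage)

region <- generate_region(seed = 1, preset = "toy3")  # 100x100 km, CSC+/CSC/PSC
cfg <- model_config()                                  # synthetic defaults
hs <- hourly_series(region, bundled_traffic_profiles(), cfg, "weekday")
subset(hs$areas, hour %in% c(3, 7, 16) & km2 > 0)
#>    day_type hour       paradigm  km2 percent
#> 13  weekday    3     mothership 10000     100
#> 29  weekday    7     mothership  6868      69
#> 31  weekday    7 drip_and_drive  3132      31
#> 65  weekday   16     mothership  9208      92
#> 66  weekday   16  drip_and_ship   792       8
```

At 03:00 (baseline traffic) mothership wins everywhere. During the
morning rush (07:00) the drip-and-drive catchment grows to 31% of the
region: the interventionalist drives *against* the commute while the
patient would drive with it. In the afternoon rush (16:00) the pattern
flips and drip-and-ship takes 8%, because the patient transfer now runs
against the commute while the interventionalist's direction is
congested. The analysis drivers under `analysis/` (run in order,
`01_build_inputs.R` … `05_oplog.R`) repeat this at territory scale
(64,064 km², 21 PSC / 23 CSC / 5 CSC+), summarise the traffic profiles
and timelines, and tabulate the synthetic emergency-operation log,
writing tables under `results/`.

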