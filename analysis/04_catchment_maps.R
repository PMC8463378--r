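#!/usr/bin/env Rscript
# Classifies every grid cell of both synthetic regions by the transport
# paradigm with the highest predicted probability of good outcome, for
# every hour of a weekday and a weekend day, and summarises catchment
# areas. Hourly maps are exported for the morning and afternoon rush.

suppressMessages(library(stroketriage))
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

profiles <- read_traffic_profiles("results/inputs/traffic_profiles.csv")
config <- read_model_config("results/inputs/model_config.yaml")
seed <- 20160404

for (preset in c("toy3", "nwde-like")) {
  region <- generate_region(seed, preset)
  tag <- gsub("-", "_", preset)
  for (dt in c("weekday", "weekend")) {
    hs <- hourly_series(region, profiles, config, dt)
    write.csv(hs$areas,
              sprintf("results/catchment_areas_%s_%s.csv", tag, dt),
              row.names = FALSE)
    dd <- hs$areas[hs$areas$paradigm == "drip_and_drive", ]
    ms <- hs$areas[hs$areas$paradigm == "mothership", ]
    message(sprintf(
      "%s %s: mothership %d-%d%%; DD peaks at %d%% (%02d:00), %d%% at 16:00",
      preset, dt, min(ms$percent), max(ms$percent), max(dd$percent),
      dd$hour[which.max(dd$percent)], dd$percent[dd$hour == 16]))
    for (h in c(3, 7, 16)) {
      write_map_geojson(hs$maps[[h + 1]],
                        sprintf("scratch/map_%s_%s_%02d.geojson", tag, dt, h))
    }
  }
}
message("per-cell maps for 03:00/07:00/16:00 exported under scratch/")
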