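#!/usr/bin/env Rscript
# Builds every model input: synthetic regions (toy and territory-scale),
# the reference traffic profiles, the model configuration, and the
# synthetic operation log. Everything downstream reads from results/.

suppressMessages(library(stroketriage))
dir.create("results/inputs", recursive = TRUE, showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

seed <- 20160404

toy <- generate_region(seed, "toy3")
write_region_geojson(toy, "results/inputs/region_toy3.geojson")
nwde <- generate_region(seed, "nwde-like")
write_region_geojson(nwde, "results/inputs/region_nwde_like.geojson")
write_grid_csv(toy, "scratch/grid_toy3.csv")
write_grid_csv(nwde, "scratch/grid_nwde_like.csv")
message("toy3: ", nrow(toy$grid), " cells, ",
        attr(toy$grid, "total_area"), " km^2; nwde-like: ",
        nrow(nwde$grid), " cells, ", attr(nwde$grid, "total_area"), " km^2")

profiles <- bundled_traffic_profiles()
write_traffic_profiles(profiles, "results/inputs/traffic_profiles.csv")
message("traffic profiles written (", length(profiles), " day/direction pairs)")

write_model_config(model_config(), "results/inputs/model_config.yaml")
message("model configuration written (synthetic decay-curve defaults)")

log <- generate_oplog(seed = seed, preset = "lueneburg-like")
write_oplog(log, "results/inputs/oplog_lueneburg_like.csv")
message("operation log written: ", nrow(log), " operations")
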