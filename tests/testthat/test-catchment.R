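test_that("a CSC-only network labels every routable cell mothership", {
  reg <- list(
    grid = region_grid(20, 20, cell_size = 2, unroutable = c(1, 5)),
    network = hospital_network("C1", "CSC", 10, 10),
    travel = travel_model(1, 1), preset = "custom")
  class(reg) <- "stroke_region"
  m <- classify_region(reg, bundled_traffic_profiles(), fixture_config(),
                       "weekday", 7)
  expect_equal(sum(m$labels == "mothership"), sum(reg$grid$routable))
  expect_equal(sum(m$labels == "unroutable"), 2)
})

test_that("co-located hospitals tie towards mothership by priority", {
  # PSC, CSC+ and the cell all at one point: groin 120 (MS) vs 120 (DD)
  reg <- list(
    grid = region_grid(2, 2, cell_size = 2),
    network = hospital_network(c("P1", "U1"), c("PSC", "CSC_PLUS"),
                               c(1, 1), c(1, 1)),
    travel = travel_model(1, 1), preset = "custom")
  class(reg) <- "stroke_region"
  m <- classify_region(reg, bundled_traffic_profiles(), fixture_config(),
                       "weekday", 3)
  expect_equal(unname(m$probs[1, "mothership"]),
               unname(m$probs[1, "drip_and_drive"]))
  expect_equal(m$labels, "mothership")
})

test_that("vectorised classification equals the per-cell oracle on toy3", {
  reg <- generate_region(1, "toy3", cell_size = 10)  # 10x10 grid
  pr <- bundled_traffic_profiles()
  cfg <- fixture_config()
  for (dt in c("weekday", "weekend")) {
    for (h in c(3, 7, 16)) {
      m <- classify_region(reg, pr, cfg, dt, h)
      expect_identical(m$labels, oracle_classify(reg, pr, cfg, dt, h),
                       label = sprintf("%s %02d", dt, h))
    }
  }
})

test_that("catchment areas partition the region every hour", {
  reg <- generate_region(1, "toy3", cell_size = 5)
  reg$grid$routable[c(10, 20, 30)] <- FALSE
  pr <- bundled_traffic_profiles()
  hs <- hourly_series(reg, pr, fixture_config(), "weekday")
  for (m in hs$maps) {
    a <- area_summary(m)
    expect_equal(sum(a$km2), m$total_area)
    expect_equal(a$km2[a$paradigm == "unroutable"], 3 * 25)
  }
  expect_equal(nrow(hs$areas), 24 * 4)
})

test_that("flat traffic makes all 24 hourly maps identical", {
  flat <- list(
    traffic_profile(rep(55, 24), "weekday", "urban_to_suburban"),
    traffic_profile(rep(55, 24), "weekday", "suburban_to_urban"))
  reg <- generate_region(1, "toy3", cell_size = 5)
  hs <- hourly_series(reg, flat, fixture_config(), "weekday")
  for (m in hs$maps) expect_identical(m$labels, hs$maps[[1]]$labels)
})

test_that("zero-delta override reproduces the baseline-hour map at any hour", {
  reg <- generate_region(1, "toy3", cell_size = 5)
  pr <- bundled_traffic_profiles()
  cfg <- fixture_config()
  base <- classify_region(reg, pr, cfg, "weekday", 3)
  for (h in c(0, 7, 12, 16, 23)) {
    m <- classify_region(reg, pr, cfg, "weekday", h, zero_delta = TRUE)
    expect_identical(m$labels, base$labels)
  }
})

test_that("raising only the DD delta never grows the DD catchment", {
  reg <- generate_region(1, "toy3", cell_size = 4)
  cfg <- fixture_config()
  dd_area <- vapply(c(0, 5, 10, 20, 40, 80), function(d) {
    m <- classify_region(reg, NULL, cfg, "weekday", 7,
                         deltas = list(mothership = 10, ds = 10, dd = d))
    area_summary(m)$km2[3]
  }, numeric(1))
  expect_true(all(diff(dd_area) <= 0))
})

test_that("morning-rush DD catchment is at least the afternoon one on toy3", {
  reg <- generate_region(1, "toy3", cell_size = 4)
  hs <- hourly_series(reg, bundled_traffic_profiles(), fixture_config(),
                      "weekday")
  dd <- hs$areas[hs$areas$paradigm == "drip_and_drive", ]
  expect_gte(dd$km2[dd$hour == 7], dd$km2[dd$hour == 16])
})

test_that("area summaries use cell-count arithmetic and half-away rounding", {
  # region of 64,065 one-km^2 cells with the observed paradigm areas
  labels <- rep(c("drip_and_drive", "mothership", "drip_and_ship",
                  "unroutable"),
                c(30879, 25467, 5205, 64065 - 30879 - 25467 - 5205))
  m <- catchment_map(labels, cell_area = 1)
  a <- area_summary(m)
  expect_equal(m$total_area, 64065)
  expect_equal(a$percent[a$paradigm == "drip_and_drive"], 48)
  expect_equal(a$percent[a$paradigm == "mothership"], 40)
  expect_equal(a$percent[a$paradigm == "drip_and_ship"], 8)

  all_one <- catchment_map(rep("mothership", 100), cell_area = 4)
  expect_equal(area_summary(all_one)$percent[1], 100)
})

test_that("map GeoJSON export is deterministic and carries labels", {
  reg <- generate_region(3, "toy3", cell_size = 10)
  m <- classify_region(reg, bundled_traffic_profiles(), fixture_config(),
                       "weekday", 7)
  f1 <- tempfile(fileext = ".geojson"); f2 <- tempfile(fileext = ".geojson")
  write_map_geojson(m, f1); write_map_geojson(m, f2)
  expect_identical(readLines(f1), readLines(f2))
  js <- jsonlite::read_json(f1)
  expect_equal(length(js$features), nrow(reg$grid))
  expect_true(all(vapply(js$features, function(f) f$properties$label,
                         character(1)) %in%
                    c("mothership", "drip_and_ship", "drip_and_drive",
                      "unroutable")))
  unlink(c(f1, f2))
})
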