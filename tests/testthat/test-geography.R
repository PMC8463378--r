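test_that("planar travel time is proportional, symmetric and zero iff equal points", {
  m <- travel_model(speed = 1, detour = 1)
  expect_equal(travel_time(m, c(0, 0), c(0, 0)), 0)
  expect_equal(travel_time(m, c(0, 0), c(68, 0)), 68)
  expect_equal(travel_time(travel_model(1, 1.3), c(0, 0), c(10, 0)), 13)
  set.seed(7)
  for (i in 1:50) {
    a <- runif(2, 0, 100); b <- runif(2, 0, 100); c <- runif(2, 0, 100)
    md <- travel_model(runif(1, 0.5, 2), runif(1, 1, 1.5))
    expect_equal(travel_time(md, a, b), travel_time(md, b, a))
    expect_lte(travel_time(md, a, c),
               travel_time(md, a, b) + travel_time(md, b, c) + 1e-9)
  }
  expect_error(travel_model(speed = 0), "> 0")
  expect_error(travel_model(detour = 0.5))
})

test_that("nearest hospital minimises travel time with lowest-id tie-break", {
  tv <- travel_model(1, 1)
  one <- hospital_network("A", "CSC", 10, 10)
  expect_equal(nearest_hospital(0, 0, one, tv)$id, "A")

  tied <- hospital_network(c("B2", "B1"), c("CSC", "CSC"), c(-5, 5), c(0, 0))
  expect_equal(nearest_hospital(0, 0, tied, tv)$id, "B1")

  set.seed(21)
  net <- hospital_network(sprintf("H%02d", 1:5),
                          c("PSC", "CSC", "CSC_PLUS", "PSC", "CSC"),
                          runif(5, 0, 100), runif(5, 0, 100))
  for (i in 1:20) {
    p <- runif(2, 0, 100)
    got <- nearest_hospital(p[1], p[2], net, tv)
    # exhaustive scan over all hospitals
    tt <- sqrt((net$x - p[1])^2 + (net$y - p[2])^2)
    expect_equal(got$id, net$id[which.min(tt)])
    expect_equal(got$minutes, min(tt))
  }
  expect_error(nearest_hospital(0, 0, net, tv, roles = character(0)),
               "non-empty")
  expect_error(nearest_hospital(0, 0, one, tv, roles = "PSC"), "no hospital")
})

test_that("toy3 preset places the PSC 68 km from the urban CSC+", {
  reg <- generate_region(1, "toy3")
  net <- reg$network
  expect_equal(sort(unique(net$level)), c("CSC", "CSC_PLUS", "PSC"))
  p <- net[net$level == "PSC", ]
  u <- net[net$level == "CSC_PLUS", ]
  expect_equal(sqrt((p$x - u$x)^2 + (p$y - u$y)^2), 68)
  expect_equal(attr(reg$grid, "total_area"), 100 * 100)
  expect_error(generate_region(1, "nope"))
})

test_that("nwde-like preset matches the territory counts and mean distances", {
  reg <- generate_region(1, "nwde-like")
  net <- reg$network
  tab <- table(net$level)
  expect_equal(unname(tab[c("PSC", "CSC", "CSC_PLUS")]), c(21, 23, 5),
               ignore_attr = TRUE)
  expect_equal(attr(reg$grid, "total_area"), 64064)

  # brute-force pairwise scans
  dist2 <- function(a, b) {
    outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j) {
      sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2)
    })
  }
  pscs <- net[net$level == "PSC", ]
  cscs <- net[net$level %in% c("CSC", "CSC_PLUS"), ]
  cscp <- net[net$level == "CSC_PLUS", ]
  mean_psc_csc <- mean(apply(dist2(pscs, cscs), 1, min))
  expect_gt(mean_psc_csc, 44 - 8)
  expect_lt(mean_psc_csc, 44 + 8)
  mean_cscp_psc <- mean(apply(dist2(cscp, pscs), 1, min))
  expect_gt(mean_cscp_psc, 67 - 12)
  expect_lt(mean_cscp_psc, 67 + 12)

  # bands hold across seeds, not just the default
  for (s in c(7, 123)) {
    n2 <- generate_region(s, "nwde-like")$network
    p2 <- n2[n2$level == "PSC", ]
    c2 <- n2[n2$level %in% c("CSC", "CSC_PLUS"), ]
    m2 <- mean(apply(dist2(p2, c2), 1, min))
    expect_true(m2 > 36 && m2 < 52)
  }
})

test_that("region generation and GeoJSON export are seed-deterministic", {
  f1 <- tempfile(fileext = ".geojson"); f2 <- tempfile(fileext = ".geojson")
  write_region_geojson(generate_region(5, "nwde-like"), f1)
  write_region_geojson(generate_region(5, "nwde-like"), f2)
  expect_identical(readLines(f1), readLines(f2))
  f3 <- tempfile(fileext = ".geojson")
  write_region_geojson(generate_region(6, "nwde-like"), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
  js <- jsonlite::read_json(f1)
  expect_equal(js$type, "FeatureCollection")
  expect_equal(length(js$features), 50)  # boundary + 49 hospitals
  unlink(c(f1, f2, f3))
})

test_that("region grids account for every cell in the total area", {
  g <- region_grid(10, 6, cell_size = 2, unroutable = c(1, 2))
  expect_equal(nrow(g), 15)
  expect_equal(attr(g, "total_area"), 60)
  expect_equal(sum(g$routable) * attr(g, "cell_area") +
                 sum(!g$routable) * attr(g, "cell_area"),
               attr(g, "total_area"))
  expect_error(region_grid(10, 10, cell_size = 0), "> 0")
})
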