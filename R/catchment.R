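#' Construct a catchment map
#'
#' Per-cell winning paradigm for one hour and day type, plus the cell
#' geometry needed for area accounting. Usually produced by
#' [classify_region()]; the constructor is exported so area arithmetic can
#' be exercised on maps built directly from label vectors.
#'
#' @param labels Character vector with one entry per grid cell, each of
#'   `"mothership"`, `"drip_and_ship"`, `"drip_and_drive"`,
#'   `"unroutable"`.
#' @param cell_area Cell area in km^2.
#' @param day_type,hour Day type and hour the map is valid for.
#' @param probs Optional numeric matrix (cells x 3 paradigms) of predicted
#'   good-outcome probabilities.
#' @param grid Optional [region_grid()] backing the labels.
#' @return Object of class `catchment_map`.
#' @export
catchment_map <- function(labels, cell_area, day_type = "weekday",
                          hour = 3L, probs = NULL, grid = NULL) {
  lev <- c("mothership", "drip_and_ship", "drip_and_drive", "unroutable")
  if (!all(labels %in% lev)) stop("unknown paradigm label", call. = FALSE)
  .chk_num(cell_area, "cell_area")
  structure(list(labels = as.character(labels), cell_area = cell_area,
                 total_area = length(labels) * cell_area,
                 day_type = day_type, hour = as.integer(hour),
                 probs = probs, grid = grid),
            class = "catchment_map")
}

#' @export
print.catchment_map <- function(x, ...) {
  cat(sprintf("<catchment_map %s %02d:00, %d cells>\n",
              x$day_type, x$hour, length(x$labels)))
  print(area_summary(x))
  invisible(x)
}

# per-cell routing shared by every hour: travel minutes for the three
# paradigms' legs, computed once per region
.region_routing <- function(region) {
  net <- region$network
  tv <- region$travel
  g <- region$grid
  pts <- cbind(g$x, g$y)
  tt_to <- function(sub) {
    # cells x hospitals travel-time matrix
    dx <- outer(pts[, 1], sub$x, "-")
    dy <- outer(pts[, 2], sub$y, "-")
    tv$detour * sqrt(dx^2 + dy^2) / tv$speed
  }
  ord_cols <- function(sub) order(sub$id)  # lexicographic tie-break
  pick_nearest <- function(sub) {
    m <- tt_to(sub)
    o <- ord_cols(sub)
    m <- m[, o, drop = FALSE]
    j <- max.col(-m, ties.method = "first")
    list(idx = which(net$id %in% sub$id)[o][j],
         minutes = m[cbind(seq_len(nrow(m)), j)])
  }
  cscs <- net[net$level %in% c("CSC", "CSC_PLUS"), , drop = FALSE]
  pscs <- net[net$level == "PSC", , drop = FALSE]
  cscp <- net[net$level == "CSC_PLUS", , drop = FALSE]

  has_ms <- nrow(cscs) > 0L
  has_ds <- nrow(pscs) > 0L && nrow(cscs) > 0L
  has_dd <- nrow(pscs) > 0L && nrow(cscp) > 0L
  if (!has_ms && !has_ds && !has_dd) {
    stop("network supports no transport paradigm", call. = FALSE)
  }

  out <- list(has_ms = has_ms, has_ds = has_ds, has_dd = has_dd)
  if (has_ms) out$t_ms <- pick_nearest(cscs)$minutes
  if (nrow(pscs) > 0L) {
    np <- pick_nearest(pscs)
    out$t_psc <- np$minutes
    # per-PSC onward legs, indexed by the PSC each cell is assigned to
    psc_pts <- cbind(pscs$x, pscs$y)
    if (has_ds) {
      transfer_by_psc <- vapply(seq_len(nrow(pscs)), function(i) {
        min(travel_time(tv, psc_pts[i, ], cbind(cscs$x, cscs$y)))
      }, numeric(1))
    }
    if (has_dd) {
      iv_by_psc <- vapply(seq_len(nrow(pscs)), function(i) {
        min(travel_time(tv, psc_pts[i, ], cbind(cscp$x, cscp$y)))
      }, numeric(1))
    }
    psc_rank <- match(net$id[np$idx], pscs$id)
    if (has_ds) out$t_transfer <- transfer_by_psc[psc_rank]
    if (has_dd) out$t_iv <- iv_by_psc[psc_rank]
  }
  out
}

# vectorised paradigm times for all routable cells; mirrors the scalar
# timeline functions (negative intervals clamped at 0, silently here)
.paradigm_times <- function(routing, keep, deltas, w) {
  pre <- w$onset_to_fmr + w$on_scene
  out <- list()
  if (routing$has_ms) {
    door <- pre + routing$t_ms[keep]
    out$ms <- list(needle = door + pmax(w$dtn_csc + deltas$mothership, 0),
                   groin = door + pmax(w$dtg_csc + deltas$mothership, 0))
  }
  if (routing$has_ds) {
    psc_door <- pre + routing$t_psc[keep]
    needle <- psc_door + w$dtn_psc
    csc_door <- needle + w$ntd_psc + routing$t_transfer[keep]
    gap <- csc_door - (psc_door + w$imaging_offset_psc)
    dtg <- ifelse(gap <= w$reimage_window, w$dtg_csc_fast, w$dtg_csc)
    out$ds <- list(needle = needle,
                   groin = csc_door + pmax(dtg + deltas$ds, 0))
  }
  if (routing$has_dd) {
    needle <- pre + routing$t_psc[keep] + w$dtn_psc
    groin <- pmax(needle,
                  needle + w$ntl_dd + routing$t_iv[keep] +
                    pmax(w$arr_to_groin_dd + deltas$dd, 0))
    out$dd <- list(needle = needle, groin = groin)
  }
  out
}

#' Classify every grid cell by best transport paradigm
#'
#' For each routable cell, builds the three paradigm timelines (mothership
#' travel to the nearest CSC/CSC+; drip-and-ship via the nearest PSC and
#' that PSC's nearest CSC/CSC+; drip-and-drive with the
#' neurointerventionalist driving from the CSC+ nearest to that PSC),
#' applies the hour's traffic deltas, evaluates the expected good-outcome
#' probability under the model configuration, and labels the cell with the
#' argmax paradigm. Probabilities are rounded to 12 decimals before
#' comparison and ties go to mothership, then drip-and-ship, then
#' drip-and-drive (fewest handoffs first). Paradigms whose required
#' hospitals are absent are excluded.
#'
#' @param region A [generate_region()] result (or compatible list).
#' @param profiles List of [traffic_profile()]s (ignored when `deltas` is
#'   given or `zero_delta` is set).
#' @param config A [model_config()].
#' @param day_type `"weekday"` or `"weekend"`.
#' @param hour Hour of day, 0--23.
#' @param zero_delta If `TRUE`, classify under baseline (3 a.m.) traffic
#'   with all deltas zero.
#' @param deltas Optional manual override, a list with `mothership`, `ds`,
#'   `dd` deltas in minutes.
#' @return A [catchment_map()].
#' @export
classify_region <- function(region, profiles, config,
                            day_type = c("weekday", "weekend"), hour,
                            zero_delta = FALSE, deltas = NULL) {
  day_type <- match.arg(day_type)
  stopifnot(inherits(config, "model_config"))
  .chk_num(hour, "hour", 0, 23)
  routing <- .region_routing(region)
  .classify_with_routing(region, routing, profiles, config, day_type, hour,
                         zero_delta, deltas)
}

.classify_with_routing <- function(region, routing, profiles, config,
                                   day_type, hour, zero_delta = FALSE,
                                   deltas = NULL) {
  g <- region$grid
  keep <- g$routable
  if (zero_delta) {
    deltas <- list(mothership = 0, ds = 0, dd = 0)
  } else if (is.null(deltas)) {
    deltas <- paradigm_deltas(profiles, day_type, hour, config$delta_mode)
    if (config$delta_mode == "proportional") {
      # fractional deltas scale the leg they delay
      deltas <- list(
        mothership = if (routing$has_ms) deltas$mothership * routing$t_ms[keep] else 0,
        ds = if (routing$has_ds) deltas$ds * routing$t_transfer[keep] else 0,
        dd = if (routing$has_dd) deltas$dd * routing$t_iv[keep] else 0)
    }
  }
  tl <- .paradigm_times(routing, keep, deltas, config$workflow)
  n_keep <- sum(keep)
  prob <- matrix(-Inf, nrow = n_keep, ncol = 3,
                 dimnames = list(NULL, c("mothership", "drip_and_ship",
                                         "drip_and_drive")))
  ego <- function(t) expected_good_outcome(t$needle, t$groin, config$cohort,
                                           config$rates, config$curves)
  if (routing$has_ms) prob[, 1] <- ego(tl$ms)
  if (routing$has_ds) prob[, 2] <- ego(tl$ds)
  if (routing$has_dd) prob[, 3] <- ego(tl$dd)

  win <- max.col(round(prob, 12), ties.method = "first")
  labels <- rep("unroutable", nrow(g))
  labels[keep] <- colnames(prob)[win]
  full_prob <- matrix(NA_real_, nrow = nrow(g), ncol = 3,
                      dimnames = dimnames(prob))
  full_prob[keep, ] <- ifelse(is.finite(prob), prob, NA_real_)
  catchment_map(labels, attr(g, "cell_area"), day_type, hour,
                probs = full_prob, grid = g)
}

#' Catchment area summary
#'
#' Area per paradigm as km^2 (cell count times cell area) and as an
#' integer percentage of the *total* region area (including unroutable
#' cells), rounded half away from zero.
#'
#' @param map A [catchment_map()].
#' @return Data frame with columns `paradigm`, `km2`, `percent`.
#' @export
area_summary <- function(map) {
  stopifnot(inherits(map, "catchment_map"))
  lev <- c("mothership", "drip_and_ship", "drip_and_drive", "unroutable")
  n <- vapply(lev, function(l) sum(map$labels == l), numeric(1))
  km2 <- n * map$cell_area
  data.frame(paradigm = lev, km2 = unname(km2),
             percent = unname(round_half_away(100 * km2 / map$total_area)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hourly catchment series
#'
#' Classifies the region for every hour 0--23 of one day type and stacks
#' the per-paradigm areas into a long table.
#'
#' @inheritParams classify_region
#' @return List with `maps` (24 [catchment_map()]s, one per hour) and
#'   `areas` (long data frame: `day_type`, `hour`, `paradigm`, `km2`,
#'   `percent`).
#' @export
hourly_series <- function(region, profiles, config,
                          day_type = c("weekday", "weekend")) {
  day_type <- match.arg(day_type)
  routing <- .region_routing(region)
  maps <- lapply(0:23, function(h) {
    .classify_with_routing(region, routing, profiles, config, day_type, h)
  })
  areas <- do.call(rbind, lapply(maps, function(m) {
    cbind(day_type = day_type, hour = m$hour, area_summary(m))
  }))
  list(maps = maps, areas = areas)
}

#' Export a catchment map to GeoJSON
#'
#' One Point feature per grid cell (centroid, planar km) with its `label`
#' property; byte-deterministic for identical inputs. Intended to pair
#' with a sidecar CSV from [area_summary()].
#'
#' @param map A [catchment_map()] carrying its grid.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_map_geojson <- function(map, path) {
  stopifnot(inherits(map, "catchment_map"))
  if (is.null(map$grid)) stop("map carries no grid", call. = FALSE)
  feats <- lapply(seq_along(map$labels), function(i) {
    list(type = "Feature",
         properties = list(cell = map$grid$cell[i], label = map$labels[i]),
         geometry = list(type = "Point",
                         coordinates = c(map$grid$x[i], map$grid$y[i])))
  })
  fc <- list(type = "FeatureCollection",
             properties = list(day_type = map$day_type, hour = map$hour,
                               cell_area_km2 = map$cell_area),
             features = feats)
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = 8), path)
  invisible(path)
}

#' Plot a catchment map
#'
#' Base-graphics raster of the winning paradigm per cell using the
#' conventional colour code: green mothership, red drip-and-ship, purple
#' drip-and-drive, grey unroutable; hospitals overplotted as points.
#'
#' @param map A [catchment_map()] carrying its grid.
#' @param network Optional [hospital_network()] to overplot.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, the label matrix.
#' @export
plot_catchment <- function(map, network = NULL, ...) {
  stopifnot(inherits(map, "catchment_map"))
  if (is.null(map$grid)) stop("map carries no grid", call. = FALSE)
  g <- map$grid
  nx <- attr(g, "nx"); ny <- attr(g, "ny")
  lev <- c("mothership", "drip_and_ship", "drip_and_drive", "unroutable")
  z <- matrix(match(map$labels, lev), nrow = nx, ncol = ny)
  cols <- c("#2ca02c", "#d62728", "#9467bd", "#bbbbbb")
  graphics::image(x = sort(unique(g$x)), y = sort(unique(g$y)), z = z,
                  zlim = c(1, 4), col = cols, xlab = "km", ylab = "km",
                  main = sprintf("%s %02d:00", map$day_type, map$hour), ...)
  if (!is.null(network)) {
    pch <- c(PSC = 24, CSC = 21, CSC_PLUS = 19)[network$level]
    graphics::points(network$x, network$y, pch = pch, bg = "white")
  }
  invisible(z)
}
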