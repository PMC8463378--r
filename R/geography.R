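#' Hospital network
#'
#' Hospitals on a planar region, with levels `PSC` (IVT only, angiosuite
#' but no on-site neurointerventionalist), `CSC` (IVT + EVT 24/7) and
#' `CSC_PLUS` (high-volume university CSC able to dispatch a
#' neurointerventionalist for drip-and-drive).
#'
#' @param id Character vector of unique hospital ids.
#' @param level Character vector of levels (`"PSC"`, `"CSC"`,
#'   `"CSC_PLUS"`).
#' @param x,y Planar coordinates in km.
#' @return A `hospital_network` data frame.
#' @export
hospital_network <- function(id, level, x, y) {
  level <- as.character(level)
  if (anyDuplicated(id)) stop("hospital ids must be unique", call. = FALSE)
  if (!all(level %in% c("PSC", "CSC", "CSC_PLUS"))) {
    stop("levels must be PSC, CSC or CSC_PLUS", call. = FALSE)
  }
  stopifnot(is.numeric(x), is.numeric(y), all(is.finite(c(x, y))))
  structure(data.frame(id = as.character(id), level = level,
                       x = as.numeric(x), y = as.numeric(y),
                       stringsAsFactors = FALSE),
            class = c("hospital_network", "data.frame"))
}

#' Travel-time model
#'
#' Planar baseline travel model: travel time is
#' `detour * Euclidean distance / speed`. A detour factor `>= 1` accounts
#' for road networks being longer than straight lines. Diurnal variation
#' is layered on top through [traffic_delta()]s, not here.
#'
#' @param speed Speed in km/min (`> 0`).
#' @param detour Detour factor (unitless, `>= 1`).
#' @return Object of class `travel_model`.
#' @export
travel_model <- function(speed = 1, detour = 1) {
  .chk_num(speed, "speed")
  if (speed <= 0) stop("`speed` must be > 0", call. = FALSE)
  .chk_num(detour, "detour", lo = 1)
  structure(list(speed = speed, detour = detour), class = "travel_model")
}

#' Travel time between two points
#'
#' @param model A [travel_model()].
#' @param a,b Points as numeric `c(x, y)` in km, or matrices with columns
#'   x, y (vectorised row-wise).
#' @return Travel time(s) in minutes; symmetric, zero iff `a == b`.
#' @export
travel_time <- function(model, a, b) {
  stopifnot(inherits(model, "travel_model"))
  a <- rbind(a); b <- rbind(b)
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  d <- sqrt((a[, 1] - b[, 1])^2 + (a[, 2] - b[, 2])^2)
  unname(model$detour * d / model$speed)
}

#' Discretised rectangular region grid
#'
#' Square cells of side `cell_size` covering `[0, width] x [0, height]`;
#' cell centroids carry a routable flag (cells without road infrastructure
#' are excluded from classification but counted in the total area).
#'
#' @param width,height Region extent in km (multiples of `cell_size`).
#' @param cell_size Cell side in km (`> 0`), default 2.
#' @param unroutable Optional integer vector of cell indices without road
#'   access.
#' @return A `region_grid` data frame (`cell`, `x`, `y`, `routable`) with
#'   attributes `cell_size`, `cell_area`, `total_area`, `nx`, `ny`.
#' @export
region_grid <- function(width, height, cell_size = 2, unroutable = NULL) {
  .chk_num(width, "width"); .chk_num(height, "height")
  .chk_num(cell_size, "cell_size")
  if (cell_size <= 0) stop("`cell_size` must be > 0", call. = FALSE)
  nx <- round(width / cell_size); ny <- round(height / cell_size)
  cx <- (seq_len(nx) - 0.5) * cell_size
  cy <- (seq_len(ny) - 0.5) * cell_size
  g <- expand.grid(x = cx, y = cy, KEEP.OUT.ATTRS = FALSE)
  g <- data.frame(cell = seq_len(nrow(g)), x = g$x, y = g$y,
                  routable = TRUE)
  if (!is.null(unroutable)) g$routable[unroutable] <- FALSE
  structure(g, class = c("region_grid", "data.frame"),
            cell_size = cell_size, cell_area = cell_size^2,
            total_area = nrow(g) * cell_size^2, nx = nx, ny = ny)
}

#' Nearest hospital of given roles
#'
#' Minimises travel time from a point over all hospitals whose level is in
#' `roles`; ties are broken by the lexicographically lowest id.
#'
#' @param x,y Point coordinates in km.
#' @param network A [hospital_network()].
#' @param travel A [travel_model()].
#' @param roles Character vector of levels to consider.
#' @return List with `id`, `level`, `x`, `y`, `minutes`.
#' @export
nearest_hospital <- function(x, y, network, travel,
                             roles = c("PSC", "CSC", "CSC_PLUS")) {
  stopifnot(inherits(network, "hospital_network"))
  if (length(roles) == 0L) stop("`roles` must be non-empty", call. = FALSE)
  cand <- network[network$level %in% roles, , drop = FALSE]
  if (nrow(cand) == 0L) {
    stop(sprintf("no hospital with role(s) %s", paste(roles, collapse = "/")),
         call. = FALSE)
  }
  tt <- travel_time(travel, c(x, y), cbind(cand$x, cand$y))
  ord <- order(tt, cand$id)
  i <- ord[1L]
  list(id = cand$id[i], level = cand$level[i], x = cand$x[i], y = cand$y[i],
       minutes = tt[i])
}

#' Generate a synthetic region, hospital network and travel model
#'
#' Seed-deterministic synthetic geography for fully reproducible
#' experiments. Presets:
#' * `"toy3"` — a 100 x 100 km region with one urban CSC+, one CSC and one
#'   PSC located 68 km from the CSC+ (the reference transfer route
#'   distance); deterministic regardless of seed.
#' * `"nwde-like"` — a 352 x 182 km region (64,064 km^2 on 2-km cells)
#'   with 21 PSCs, 23 CSCs and 5 CSC+, laid out so the mean nearest
#'   PSC-to-CSC distance is about 44 km and the mean nearest CSC+-to-PSC
#'   distance about 67 km (a large mixed urban/rural territory); hospital
#'   positions get seeded +/-4 km jitter.
#'
#' @param seed Integer seed for the jitter.
#' @param preset `"toy3"` or `"nwde-like"`.
#' @param cell_size Grid cell side in km, default 2.
#' @return List with `grid` ([region_grid()]), `network`
#'   ([hospital_network()]), `travel` ([travel_model()]) and `preset`;
#'   class `stroke_region`.
#' @export
generate_region <- function(seed = 1L, preset = c("toy3", "nwde-like"),
                            cell_size = 2) {
  preset <- match.arg(preset)
  if (preset == "toy3") {
    grid <- region_grid(100, 100, cell_size)
    network <- hospital_network(
      id = c("CSCP01", "CSC01", "PSC01"),
      level = c("CSC_PLUS", "CSC", "PSC"),
      x = c(16, 50, 84), y = c(50, 20, 50)
    )
    # 68 km at 1.36 km/min = 50 min: the bundled profiles' 03:00 baseline
    travel <- travel_model(speed = 1.36, detour = 1)
  } else {
    grid <- region_grid(352, 182, cell_size)
    psc <- expand.grid(x = c(22, 110, 198),
                       y = 13 + 26 * (0:6), KEEP.OUT.ATTRS = FALSE)
    csc <- expand.grid(x = c(66, 154, 242),
                       y = 13 + 26 * (0:6), KEEP.OUT.ATTRS = FALSE)
    csc <- rbind(csc, data.frame(x = c(308, 308), y = c(65, 117)))
    cscp <- data.frame(x = rep(265, 5), y = c(39, 65, 91, 117, 143))
    xy <- rbind(psc, csc, cscp)
    jit <- .with_seed(seed, matrix(stats::runif(2 * nrow(xy), -4, 4),
                                   ncol = 2))
    xy <- xy + jit
    network <- hospital_network(
      id = c(sprintf("PSC%02d", seq_len(nrow(psc))),
             sprintf("CSC%02d", seq_len(nrow(csc))),
             sprintf("CSCP%02d", seq_len(nrow(cscp)))),
      level = rep(c("PSC", "CSC", "CSC_PLUS"),
                  c(nrow(psc), nrow(csc), nrow(cscp))),
      x = xy$x, y = xy$y
    )
    travel <- travel_model(speed = 1.1, detour = 1.2)
  }
  structure(list(grid = grid, network = network, travel = travel,
                 preset = preset),
            class = "stroke_region")
}

#' @export
print.stroke_region <- function(x, ...) {
  cat(sprintf("<stroke_region '%s': %d cells (%g km^2), %d hospitals (%s)>\n",
              x$preset, nrow(x$grid), attr(x$grid, "total_area"),
              nrow(x$network),
              paste(sprintf("%d %s", table(x$network$level)[
                c("PSC", "CSC", "CSC_PLUS")],
                c("PSC", "CSC", "CSC+")), collapse = ", ")))
  invisible(x)
}

#' Serialise a region to GeoJSON
#'
#' FeatureCollection with the region boundary as a Polygon (properties:
#' preset, cell size, total area) and one Point feature per hospital with
#' its `id` and `level`. Coordinates are planar km; output is
#' byte-deterministic for identical inputs.
#'
#' @param region A [generate_region()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_region_geojson <- function(region, path) {
  stopifnot(inherits(region, "stroke_region"))
  g <- region$grid
  w <- attr(g, "nx") * attr(g, "cell_size")
  h <- attr(g, "ny") * attr(g, "cell_size")
  boundary <- list(
    type = "Feature",
    properties = list(kind = "region", preset = region$preset,
                      cell_size_km = attr(g, "cell_size"),
                      total_area_km2 = attr(g, "total_area")),
    geometry = list(type = "Polygon",
                    coordinates = list(list(c(0, 0), c(w, 0), c(w, h),
                                            c(0, h), c(0, 0))))
  )
  hosp <- lapply(seq_len(nrow(region$network)), function(i) {
    list(type = "Feature",
         properties = list(kind = "hospital",
                           id = region$network$id[i],
                           level = region$network$level[i]),
         geometry = list(type = "Point",
                         coordinates = c(region$network$x[i],
                                         region$network$y[i])))
  })
  fc <- list(type = "FeatureCollection", features = c(list(boundary), hosp))
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = 8), path)
  invisible(path)
}

#' Write the region grid as CSV
#'
#' Columns `cell`, `x`, `y`, `routable`.
#'
#' @param region A [generate_region()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(region, path) {
  stopifnot(inherits(region, "stroke_region"))
  utils::write.csv(as.data.frame(region$grid), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
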