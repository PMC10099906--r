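# MEASO-style regional partition of the Southern Ocean and percent change
# in preferred-habitat area per climate representation and scenario.

#' Default five-sector region set
#'
#' Meridional sectors approximating the MEASO partition (Atlantic,
#' Central Indian, East Indian, West Pacific, East Pacific), bounded at
#' 70 W, 30 E, 90 E, 150 E and 130 W, spanning 30 S to the pole. The
#' authoritative polygons can be supplied instead via
#' [read_regions_geojson()].
#'
#' @return A `region_set`: list of named polygons (closed lon/lat
#'   matrices).
#' @export
default_regions <- function() {
  rect <- function(lon1, lon2) {
    cbind(lon = c(lon1, lon2, lon2, lon1, lon1),
          lat = c(-90, -90, -30, -30, -90))
  }
  polys <- list(
    "Atlantic" = list(rect(-70, 30)),
    "Central Indian" = list(rect(30, 90)),
    "East Indian" = list(rect(90, 150)),
    "West Pacific" = list(rect(150, 180), rect(-180, -130)),
    "East Pacific" = list(rect(-130, -70))
  )
  structure(list(polys = polys), class = "region_set")
}

#' Read a region set from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon/MultiPolygon features; the region
#' name is taken from a `name` (or `region`) property.
#'
#' @param path GeoJSON file path.
#' @return A `region_set`.
#' @export
read_regions_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  stopifnot(identical(gj$type, "FeatureCollection"))
  polys <- list()
  for (ft in gj$features) {
    nm <- ft$properties$name
    if (is.null(nm)) nm <- ft$properties$region
    if (is.null(nm)) stop("feature without a 'name'/'region' property")
    geom <- ft$geometry
    rings <- switch(geom$type,
      Polygon = list(geom$coordinates[[1]]),
      MultiPolygon = lapply(geom$coordinates, function(p) p[[1]]),
      stop("unsupported geometry type: ", geom$type)
    )
    polys[[nm]] <- lapply(rings, function(r) {
      m <- do.call(rbind, lapply(r, function(pt) c(pt[[1]], pt[[2]])))
      colnames(m) <- c("lon", "lat")
      m
    })
  }
  structure(list(polys = polys), class = "region_set")
}

# Even-odd ray-casting point-in-polygon; boundary points on the left/bottom
# edge count as inside so adjacent sectors tile without overlap.
point_in_poly <- function(lon, lat, poly) {
  n <- nrow(poly) - 1
  inside <- rep(FALSE, length(lon))
  for (i in seq_len(n)) {
    x1 <- poly[i, 1]; y1 <- poly[i, 2]
    x2 <- poly[i + 1, 1]; y2 <- poly[i + 1, 2]
    crosses <- ((y1 <= lat) != (y2 <= lat))
    if (any(crosses)) {
      xin <- x1 + (lat - y1) / (y2 - y1) * (x2 - x1)
      inside <- xor(inside, crosses & (lon < xin))
    }
  }
  inside
}

#' Assign grid cells to regions
#'
#' Cells are assigned by their center point; cells inside no polygon stay
#' unlabeled (`NA`); a cell center inside two polygons is an error.
#'
#' @param grid List with `lon`, `lat` cell-center vectors (a `hab_surface`
#'   or `env_stack` works).
#' @param regions A `region_set` (default [default_regions()]).
#' @return Character matrix (`nlat x nlon`) of region labels.
#' @export
assign_regions <- function(grid, regions = default_regions()) {
  nlat <- length(grid$lat); nlon <- length(grid$lon)
  lon <- rep(grid$lon, each = nlat)
  lat <- rep(grid$lat, times = nlon)
  labels <- rep(NA_character_, nlat * nlon)
  for (nm in names(regions$polys)) {
    hit <- Reduce(`|`, lapply(regions$polys[[nm]], function(p) {
      point_in_poly(lon, lat, p)
    }))
    if (any(hit & !is.na(labels))) {
      stop("overlapping region polygons at e.g. lon ",
           lon[which(hit & !is.na(labels))[1]])
    }
    labels[hit] <- nm
  }
  matrix(labels, nlat, nlon)
}

#' Area of a 1-degree (or `res`-degree) grid cell
#'
#' Spherical quadrilateral area
#' `R^2 * dlambda * (sin(lat + dphi/2) - sin(lat - dphi/2))`, R = 6371 km.
#'
#' @param lat Cell-center latitude(s), degrees, |lat| < 90.
#' @param res Cell size, degrees.
#' @return Area(s) in km^2; symmetric in latitude and decreasing poleward.
#' @export
cell_area <- function(lat, res = 1) {
  dl <- deg2rad(res)
  EARTH_RADIUS_KM^2 * dl *
    (sin(deg2rad(lat + res / 2)) - sin(deg2rad(lat - res / 2)))
}

# nlat x nlon matrix of cell areas for a grid.
grid_cell_areas <- function(grid, res = 1) {
  matrix(cell_area(grid$lat, res), length(grid$lat), length(grid$lon))
}

#' Percent change in preferred-habitat area per region
#'
#' Region areas are latitude-weighted sums of cell areas over mask cells;
#' percent change is `100 (future - current) / current`, undefined (and
#' flagged `NA`) where a region holds no current habitat.
#'
#' @param current_mask,future_mask Binary `hab_surface` masks on one grid.
#' @param labels Region label matrix from [assign_regions()].
#' @param areas Optional cell-area matrix (default: geodesic areas from
#'   [cell_area()]); pass a matrix of ones for a cell-count sensitivity
#'   mode.
#' @param taxon,representation,scenario Metadata carried into the records.
#' @return Data frame `taxon, region, representation, scenario,
#'   current_km2, future_km2, pct_change`.
#' @export
percent_area_change <- function(current_mask, future_mask, labels,
                                areas = NULL, taxon = NA,
                                representation = NA, scenario = NA) {
  stopifnot(identical(dim(current_mask$values), dim(future_mask$values)),
            identical(dim(current_mask$values), dim(labels)))
  if (is.null(areas)) areas <- grid_cell_areas(current_mask)
  regs <- sort(unique(as.vector(labels[!is.na(labels)])))
  cur <- current_mask$values; fut <- future_mask$values
  rows <- lapply(regs, function(rg) {
    in_rg <- !is.na(labels) & labels == rg
    a_cur <- sum(areas[in_rg & !is.na(cur) & cur == 1])
    a_fut <- sum(areas[in_rg & !is.na(fut) & fut == 1])
    data.frame(
      taxon = taxon, region = rg, representation = representation,
      scenario = scenario, current_km2 = a_cur, future_km2 = a_fut,
      pct_change = if (a_cur > 0) 100 * (a_fut - a_cur) / a_cur else NA_real_
    )
  })
  do.call(rbind, rows)
}

#' Quartile summaries of regional change across representations
#'
#' Median, 25th/75th percentiles (type-7 linear interpolation), min and max
#' of percent change per (taxon, region, scenario) — the numbers behind a
#' box-and-dots ensemble figure.
#'
#' @param records Data frame from [percent_area_change()] rows.
#' @return Summary data frame, one row per group.
#' @export
summarize_ensemble <- function(records) {
  stopifnot(nrow(records) >= 1)
  key <- interaction(records$taxon, records$region, records$scenario,
                     drop = TRUE)
  rows <- lapply(split(records, key), function(g) {
    q <- stats::quantile(g$pct_change, c(0.25, 0.5, 0.75),
                         na.rm = TRUE, type = 7)
    data.frame(
      taxon = g$taxon[1], region = g$region[1], scenario = g$scenario[1],
      n = sum(!is.na(g$pct_change)),
      min = min(g$pct_change, na.rm = TRUE), q25 = q[[1]],
      median = q[[2]], q75 = q[[3]],
      max = max(g$pct_change, na.rm = TRUE)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$taxon, out$region, out$scenario), ]
}
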