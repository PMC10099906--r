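# Gridded containers. An env_stack holds named covariate layers on a shared
# 1-degree cell-center-registered lon/lat grid, either as daily slices
# (3-d arrays [lat, lon, time]) or a single climatology slice (matrices).
# A hab_surface is a single named layer on the same kind of grid.

ENV_LAYER_VOCAB <- c(
  "sea_surface_height", "ssh_anomaly", "bathymetry", "bathymetry_gradient",
  "sst", "chlorophyll_a", "eddy_kinetic_energy", "mixed_layer_depth",
  "ice_concentration"
)

#' Construct an environmental grid stack
#'
#' @param lon,lat Cell-center coordinate vectors (regularly spaced,
#'   ascending), decimal degrees.
#' @param layers Named list of layers. Each is either a `length(lat)` x
#'   `length(lon)` matrix (climatology) or a 3-d array with a trailing time
#'   dimension matching `dates`. Names must come from the fixed covariate
#'   vocabulary (sea_surface_height, ssh_anomaly, bathymetry,
#'   bathymetry_gradient, sst, chlorophyll_a, eddy_kinetic_energy,
#'   mixed_layer_depth, ice_concentration).
#' @param dates `Date` vector for daily stacks, or `NULL` for a single
#'   climatology slice.
#' @param land_mask Optional logical matrix, `TRUE` on land cells.
#' @return An object of class `env_stack`.
#' @export
env_stack <- function(lon, lat, layers, dates = NULL, land_mask = NULL) {
  stopifnot(is.list(layers), length(layers) > 0, !is.null(names(layers)))
  bad <- setdiff(names(layers), ENV_LAYER_VOCAB)
  if (length(bad) > 0) {
    stop("unknown layer name(s): ", paste(bad, collapse = ", "))
  }
  nlat <- length(lat); nlon <- length(lon)
  for (nm in names(layers)) {
    d <- dim(layers[[nm]])
    if (is.null(dates)) {
      if (!identical(d[1:2], c(nlat, nlon)) || length(d) != 2) {
        stop("layer '", nm, "' does not match the grid")
      }
    } else {
      if (length(d) != 3 || !identical(d, c(nlat, nlon, length(dates)))) {
        stop("layer '", nm, "' does not match the grid/time axis")
      }
    }
  }
  if (!is.null(layers$ice_concentration)) {
    ic <- layers$ice_concentration
    if (any(ic < 0 | ic > 100, na.rm = TRUE)) {
      stop("ice_concentration must lie in [0, 100]")
    }
  }
  structure(
    list(lon = lon, lat = lat, dates = dates, layers = layers,
         land_mask = land_mask),
    class = "env_stack"
  )
}

#' @export
print.env_stack <- function(x, ...) {
  cat("<env_stack> ", length(x$lat), "x", length(x$lon), " grid, ",
      if (is.null(x$dates)) "climatology slice"
      else paste0(length(x$dates), " daily slices"),
      "\n  layers: ", paste(names(x$layers), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Row/column cell indices for points; NA when off-grid. Assumes a regular
# cell-center-registered grid.
cell_indices <- function(stack_or_grid, lon, lat) {
  g <- stack_or_grid
  res_lon <- if (length(g$lon) > 1) diff(g$lon[1:2]) else 1
  res_lat <- if (length(g$lat) > 1) diff(g$lat[1:2]) else 1
  col <- as.integer(round((lon - g$lon[1]) / res_lon)) + 1L
  row <- as.integer(round((lat - g$lat[1]) / res_lat)) + 1L
  col[col < 1L | col > length(g$lon)] <- NA_integer_
  row[row < 1L | row > length(g$lat)] <- NA_integer_
  list(row = row, col = col)
}

#' Construct a gridded surface
#'
#' A single named layer (predicted preference, importance score, a binary
#' mask, ...) on a cell-center-registered lon/lat grid.
#'
#' @param lon,lat Cell-center coordinate vectors, degrees.
#' @param values `length(lat)` x `length(lon)` numeric matrix; `NA` marks
#'   masked (land/ice) cells.
#' @param taxon Optional taxon tag.
#' @param type Free-form content tag (e.g. "preference", "importance").
#' @return An object of class `hab_surface`.
#' @export
hab_surface <- function(lon, lat, values, taxon = NULL, type = "preference") {
  stopifnot(is.matrix(values), nrow(values) == length(lat),
            ncol(values) == length(lon))
  structure(
    list(lon = lon, lat = lat, values = values, taxon = taxon, type = type),
    class = "hab_surface"
  )
}

#' @export
print.hab_surface <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat("<hab_surface> ", x$type, ", ", length(x$lat), "x", length(x$lon),
      " grid, ", length(v), " non-missing cells",
      if (length(v)) sprintf(", range [%.4g, %.4g]", min(v), max(v)) else "",
      "\n", sep = "")
  invisible(x)
}

#' Image plot of a gridded surface
#'
#' @param x A `hab_surface`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.hab_surface <- function(x, ...) {
  graphics::image(x$lon, x$lat, t(x$values), xlab = "lon", ylab = "lat",
                  main = x$type, ...)
  invisible(x)
}

#' Write a surface or stack slice as long-format CSV
#'
#' Plain-text grid serialization (`lon,lat,layer,value` rows), the package's
#' portable on-disk raster format.
#'
#' @param x A `hab_surface` or climatology `env_stack`.
#' @param path Output CSV path.
#' @export
write_grid_csv <- function(x, path) {
  if (inherits(x, "hab_surface")) {
    layers <- stats::setNames(list(x$values), x$type)
    lon <- x$lon; lat <- x$lat
  } else if (inherits(x, "env_stack") && is.null(x$dates)) {
    layers <- x$layers; lon <- x$lon; lat <- x$lat
  } else {
    stop("write_grid_csv() handles surfaces and climatology stacks")
  }
  rows <- do.call(rbind, lapply(names(layers), function(nm) {
    data.frame(
      lon = rep(lon, each = length(lat)),
      lat = rep(lat, times = length(lon)),
      layer = nm,
      value = as.vector(layers[[nm]])
    )
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format CSV grid written by [write_grid_csv()]
#'
#' @param path CSV path.
#' @return A named list of value matrices plus `lon` and `lat` vectors.
#' @export
read_grid_csv <- function(path) {
  d <- utils::read.csv(path)
  lon <- sort(unique(d$lon)); lat <- sort(unique(d$lat))
  out <- lapply(split(d, d$layer), function(s) {
    m <- matrix(NA_real_, length(lat), length(lon))
    idx <- cell_indices(list(lon = lon, lat = lat), s$lon, s$lat)
    m[cbind(idx$row, idx$col)] <- s$value
    m
  })
  c(list(lon = lon, lat = lat), out)
}
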