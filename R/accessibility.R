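# Colony accessibility: probability a grid cell is reachable on a round
# trip, modeled as a monotone decreasing function of great-circle distance
# to the colony, fitted to the binary visited/not-visited cell response
# built from observed plus simulated tracks.

#' Per-cell binary visitation response
#'
#' A cell scores 1 if any observed or null fix falls in it, else 0, paired
#' with the cell-center great-circle distance to the colony.
#'
#' @param fixes Data frame of fixes (`lon`, `lat`) pooled over observed and
#'   null tracks for one colony.
#' @param grid List with `lon`, `lat` cell-center vectors (an `env_stack`
#'   or `hab_surface` works).
#' @param colony_lon,colony_lat Colony coordinates, degrees.
#' @param sea_mask Optional logical matrix (`TRUE` = usable sea cell);
#'   masked cells are excluded from the response.
#' @return Data frame `distance_km`, `visited` (0/1), one row per grid cell.
#' @export
build_access_response <- function(fixes, grid, colony_lon, colony_lat,
                                  sea_mask = NULL) {
  nlat <- length(grid$lat); nlon <- length(grid$lon)
  visited <- matrix(FALSE, nlat, nlon)
  if (nrow(fixes) > 0) {
    idx <- cell_indices(grid, fixes$lon, fixes$lat)
    ok <- !is.na(idx$row) & !is.na(idx$col)
    visited[cbind(idx$row[ok], idx$col[ok])] <- TRUE
  }
  lonm <- matrix(grid$lon, nlat, nlon, byrow = TRUE)
  latm <- matrix(grid$lat, nlat, nlon)
  d <- great_circle_distance(lonm, latm, colony_lon, colony_lat)
  keep <- if (is.null(sea_mask)) rep(TRUE, nlat * nlon) else as.vector(sea_mask)
  data.frame(distance_km = as.vector(d)[keep],
             visited = as.integer(as.vector(visited)[keep]))
}

#' Fit a monotone decreasing accessibility curve
#'
#' Binomial response smoothed under a monotone decreasing constraint:
#' visitation rates are computed in distance bins, pooled-adjacent-violators
#' isotonic regression enforces the decrease, and a monotone Hermite
#' (Hyman-filtered) spline interpolates between bin centers. Output
#' probabilities are clipped to `[0, 1]` and extrapolate as constants.
#'
#' @param response Data frame from [build_access_response()] (or any with
#'   `distance_km` and `visited`).
#' @param bin_km Distance bin width (default 50 km).
#' @param colony_id Optional identifier stored with the curve.
#' @return An `access_curve` object; evaluate it with `predict(curve, d)`.
#' @export
fit_accessibility <- function(response, bin_km = 50, colony_id = NULL) {
  stopifnot(all(c("distance_km", "visited") %in% names(response)))
  d <- response$distance_km
  y <- response$visited
  degenerate <- length(unique(y)) < 2
  bins <- floor(d / bin_km)
  ubins <- sort(unique(bins))
  agg <- vapply(ubins, function(b) mean(y[bins == b]), numeric(1))
  centers <- (ubins + 0.5) * bin_km
  if (degenerate) {
    fn <- local({
      v <- mean(y)
      function(x) rep(v, length(x))
    })
    warning("degenerate accessibility response (single class): flat curve")
  } else if (length(agg) == 1) {
    fn <- local({
      v <- as.numeric(agg[1])
      function(x) rep(v, length(x))
    })
  } else {
    # isotonic decreasing fit: isoreg on reversed order
    iso <- stats::isoreg(centers, -as.numeric(agg))
    yhat <- -iso$yf
    # collapse ties so the spline knots are strictly ordered
    sf <- stats::splinefun(centers, yhat, method = "hyman")
    rng <- range(centers)
    fn <- function(x) {
      x <- pmin(pmax(x, rng[1]), rng[2])
      pmin(pmax(sf(x), 0), 1)
    }
  }
  structure(
    list(colony_id = colony_id, bin_km = bin_km,
         bin_centers = centers, bin_rates = as.numeric(agg),
         degenerate = degenerate, fn = fn,
         n_cells = length(y), n_visited = sum(y)),
    class = "access_curve"
  )
}

#' @export
predict.access_curve <- function(object, distance_km, ...) {
  object$fn(distance_km)
}

#' @export
print.access_curve <- function(x, ...) {
  cat("<access_curve>", if (!is.null(x$colony_id)) x$colony_id else "",
      sprintf("%d cells (%d visited), %g km bins%s\n", x$n_cells,
              x$n_visited, x$bin_km,
              if (x$degenerate) " [degenerate: flat]" else ""))
  invisible(x)
}

#' Plot an accessibility curve
#'
#' @param x An `access_curve`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.access_curve <- function(x, ...) {
  dd <- seq(0, max(x$bin_centers), length.out = 200)
  graphics::plot(dd, predict(x, dd), type = "l", ylim = c(0, 1),
                 xlab = "distance from colony (km)",
                 ylab = "P(accessible)", ...)
  graphics::points(x$bin_centers, x$bin_rates, pch = 16, cex = 0.5)
  invisible(x)
}

#' Write accessibility curves as CSV
#'
#' @param curves A named list of `access_curve`s (or a single curve).
#' @param path Output CSV path.
#' @param distances_km Distances at which to tabulate each curve.
#' @export
write_access_csv <- function(curves, path,
                             distances_km = seq(0, 5000, by = 50)) {
  if (inherits(curves, "access_curve")) curves <- list(curves)
  rows <- do.call(rbind, lapply(seq_along(curves), function(i) {
    cu <- curves[[i]]
    id <- if (!is.null(cu$colony_id)) cu$colony_id else names(curves)[i]
    data.frame(colony_id = id, distance_km = distances_km,
               probability = predict(cu, distances_km))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Combine habitat preference with colony accessibility
#'
#' Per colony, `combined(cell) = preference(cell) * access(distance(cell))`.
#' Multiple colonies aggregate by the cell-wise maximum (unweighted mode,
#' the default) or by the population-weighted mean (weighted mode, a
#' relative density index).
#'
#' @param pref A preference `hab_surface`.
#' @param curves Named list of `access_curve`s, one per colony id.
#' @param colonies Data frame `colony_id, lon, lat` (and `population` for
#'   the weighted mode).
#' @param weights `NULL` for unweighted (max) aggregation, or `"population"`
#'   / a numeric vector of colony weights for the weighted mean.
#' @return A `hab_surface` of combined preference; never exceeds `pref`
#'   cell-wise in unweighted mode.
#' @export
combine_preference_accessibility <- function(pref, curves, colonies,
                                             weights = NULL) {
  stopifnot(inherits(pref, "hab_surface"))
  nlat <- length(pref$lat); nlon <- length(pref$lon)
  lonm <- matrix(pref$lon, nlat, nlon, byrow = TRUE)
  latm <- matrix(pref$lat, nlat, nlon)
  per_colony <- lapply(seq_len(nrow(colonies)), function(i) {
    id <- as.character(colonies$colony_id[i])
    cu <- curves[[id]]
    if (is.null(cu)) stop("missing accessibility curve for colony '", id, "'")
    d <- great_circle_distance(lonm, latm, colonies$lon[i], colonies$lat[i])
    acc <- matrix(predict(cu, as.vector(d)), nlat, nlon)
    pref$values * acc
  })
  if (is.null(weights)) {
    comb <- Reduce(pmax, per_colony)
  } else {
    w <- if (identical(weights, "population")) colonies$population
         else weights
    stopifnot(length(w) == length(per_colony))
    comb <- Reduce(`+`, Map(`*`, per_colony, w)) / sum(w)
  }
  hab_surface(pref$lon, pref$lat, comb, taxon = pref$taxon,
              type = "combined_preference")
}
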