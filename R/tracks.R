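# Track regularization and movement-parameter extraction. Raw tracks are
# per-individual ordered (timestamp, lon, lat) series; regularization
# replaces the hierarchical state-space step used for light-level data with
# deterministic great-circle interpolation onto a fixed 12-h lattice.

validate_track <- function(track) {
  stopifnot(is.data.frame(track),
            all(c("timestamp", "lon", "lat") %in% names(track)))
  if (nrow(track) < 2) stop("track needs at least 2 fixes")
  dt <- diff(as.numeric(track$timestamp))
  if (any(dt == 0)) stop("duplicate timestamps in track")
  if (any(dt < 0)) stop("timestamps must be strictly increasing")
  if (any(track$lat < -90 | track$lat > 90)) stop("latitude out of range")
  invisible(track)
}

#' Regularize a track to a fixed time interval
#'
#' Output fixes sit at exact multiples of `interval_hours` from the first
#' fix; positions come from spherical linear (great-circle) interpolation
#' between the bracketing raw fixes. The first and last raw fixes are always
#' preserved (the last even when it falls off the interval lattice).
#' Interpolated fixes inside data gaps longer than `max_gap_days` are kept
#' but flagged in a logical `gap_flag` column rather than silently trusted.
#'
#' @param track Data frame with `timestamp` (POSIXct), `lon`, `lat`; id
#'   columns are carried through.
#' @param interval_hours Target fix interval (default 12 h).
#' @param max_gap_days Gaps longer than this flag their interpolated fixes.
#' @return Regularized track with a `gap_flag` column. Idempotent.
#' @export
regularize_track <- function(track, interval_hours = 12, max_gap_days = 7) {
  validate_track(track)
  t_raw <- as.numeric(track$timestamp)
  step <- interval_hours * 3600
  t_out <- seq(t_raw[1], t_raw[length(t_raw)], by = step)
  if (t_out[length(t_out)] < t_raw[length(t_raw)]) {
    t_out <- c(t_out, t_raw[length(t_raw)])
  }
  iv <- findInterval(t_out, t_raw, rightmost.closed = TRUE)
  iv <- pmin(pmax(iv, 1L), length(t_raw) - 1L)
  lon <- numeric(length(t_out)); lat <- numeric(length(t_out))
  gap <- logical(length(t_out))
  for (k in seq_along(t_out)) {
    i <- iv[k]
    span <- t_raw[i + 1] - t_raw[i]
    f <- if (span > 0) (t_out[k] - t_raw[i]) / span else 0
    f <- min(max(f, 0), 1)
    p <- slerp_point(track$lon[i], track$lat[i],
                     track$lon[i + 1], track$lat[i + 1], f)
    lon[k] <- p$lon; lat[k] <- p$lat
    gap[k] <- span > max_gap_days * 86400 && f > 0 && f < 1
  }
  out <- data.frame(timestamp = as.POSIXct(t_out, tz = "UTC",
                                           origin = "1970-01-01"),
                    lon = lon, lat = lat, gap_flag = gap)
  for (nm in intersect(c("individual_id", "colony_id", "taxon"), names(track))) {
    out[[nm]] <- track[[nm]][1]
  }
  class(out) <- c("hab_track", "data.frame")
  out
}

#' Movement parameters of a regularized track
#'
#' Step speeds (great-circle distance over elapsed time), signed turning
#' angles (change in initial bearing between successive steps, positive
#' clockwise, in (-180, 180]), trip duration, and maximum great-circle
#' distance from the colony — the parameter set that drives null-track
#' simulation.
#'
#' @param track Regularized track data frame.
#' @param colony_lon,colony_lat Deployment colony coordinates, degrees.
#' @return A `movement_summary` list: `duration_days`, `speeds_kmh`,
#'   `turning_angles_deg`, `max_distance_km`, `start`, `end`, `n_fixes`.
#' @export
movement_summary <- function(track, colony_lon, colony_lat) {
  validate_track(track)
  n <- nrow(track)
  tsec <- as.numeric(track$timestamp)
  d <- great_circle_distance(track$lon[-n], track$lat[-n],
                             track$lon[-1], track$lat[-1])
  speeds <- d / (diff(tsec) / 3600)
  angles <- numeric(0)
  if (n >= 3) {
    b <- initial_bearing(track$lon[-n], track$lat[-n],
                         track$lon[-1], track$lat[-1])
    angles <- angle_diff(b[-(n - 1)], b[-1])
  } else {
    warning("fewer than 3 fixes: no turning angles")
  }
  structure(
    list(
      duration_days = (tsec[n] - tsec[1]) / 86400,
      speeds_kmh = speeds,
      turning_angles_deg = angles,
      max_distance_km = max(great_circle_distance(track$lon, track$lat,
                                                  colony_lon, colony_lat)),
      start = track$timestamp[1], end = track$timestamp[n],
      n_fixes = n
    ),
    class = "movement_summary"
  )
}

#' @export
print.movement_summary <- function(x, ...) {
  cat(sprintf(
    "<movement_summary> %.1f days, %d fixes, max %.0f km from colony,\n  speeds %.2f-%.2f km/h (median %.2f)\n",
    x$duration_days, x$n_fixes, x$max_distance_km,
    min(x$speeds_kmh), max(x$speeds_kmh), stats::median(x$speeds_kmh)
  ))
  invisible(x)
}

#' Write tracks to CSV
#'
#' Dialect: `individual_id,colony_id,taxon,timestamp,lon,lat` with ISO-8601
#' UTC timestamps, plus `label`/`replicate` columns when present (observed
#' tracks: label 1, replicate 0; null tracks: label 0, replicate 1..n).
#'
#' @param tracks A track data frame or list of them.
#' @param path Output CSV path.
#' @export
write_tracks_csv <- function(tracks, path) {
  if (is.data.frame(tracks)) tracks <- list(tracks)
  all_rows <- do.call(rbind, lapply(tracks, function(tr) {
    tr <- as.data.frame(tr)
    tr$timestamp <- format(tr$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    tr
  }))
  utils::write.csv(all_rows, path, row.names = FALSE)
  invisible(path)
}

#' Read tracks from CSV
#'
#' @param path CSV in the dialect of [write_tracks_csv()].
#' @return A list of track data frames, one per individual (and replicate,
#'   for null tracks).
#' @export
read_tracks_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$timestamp <- as.POSIXct(d$timestamp, tz = "UTC",
                            format = "%Y-%m-%dT%H:%M:%SZ")
  key <- d$individual_id
  if (!is.null(d$replicate)) key <- paste(key, d$replicate, sep = "/")
  lapply(split(d, key), function(tr) {
    tr <- tr[order(tr$timestamp), ]
    rownames(tr) <- NULL
    class(tr) <- c("hab_track", "data.frame")
    tr
  })
}
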