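# Constrained null-track simulation: the availability background of the
# case-control design. Each observed track gets n simulated tracks with
# identical timestamps, speeds and turning angles jointly resampled from the
# observed movement summary, a uniformly random initial bearing, and every
# fix constrained to sea, <=80% ice, poleward of 30 S, and within ~the
# observed maximum colony distance.

#' Constraint set for null-track simulation
#'
#' @param lon,lat Grid cell-center vectors for the masks (required when any
#'   mask is supplied).
#' @param land_mask,ice_mask Logical matrices (`TRUE` = forbidden); the ice
#'   mask marks cells with >80% ice concentration.
#' @param lat_band Allowed latitude interval, degrees (default 30 S
#'   northward bound, unbounded poleward — the ice mask supplies the
#'   southern limit).
#' @param max_distance_km Optional cap on distance from the track start.
#' @return A `constraint_set` list.
#' @export
constraint_set <- function(lon = NULL, lat = NULL, land_mask = NULL,
                           ice_mask = NULL, lat_band = c(-90, -30),
                           max_distance_km = NULL) {
  if ((!is.null(land_mask) || !is.null(ice_mask)) &&
      (is.null(lon) || is.null(lat))) {
    stop("masks require the grid lon/lat vectors")
  }
  structure(
    list(lon = lon, lat = lat, land_mask = land_mask, ice_mask = ice_mask,
         lat_band = lat_band, max_distance_km = max_distance_km),
    class = "constraint_set"
  )
}

#' Constraints implied by a synthetic world
#'
#' @param world A `synthetic_world`.
#' @param max_distance_km Optional distance cap.
#' @return A [constraint_set()] using the world's land and ice masks.
#' @export
constraints_from_world <- function(world, max_distance_km = NULL) {
  constraint_set(lon = world$truth$lon, lat = world$truth$lat,
                 land_mask = world$land_mask, ice_mask = world$ice_mask,
                 max_distance_km = max_distance_km)
}

#' Is a point allowed under the constraint set?
#'
#' True iff the point is inside the latitude band (poleward of 30 S by
#' default), at sea, and equatorward of the >80% ice edge. Off-grid points
#' are disallowed whenever masks are defined.
#'
#' @param lon,lat Point coordinates (vectorized), degrees.
#' @param constraints A [constraint_set()].
#' @return Logical vector.
#' @export
point_allowed <- function(lon, lat, constraints) {
  ok <- lat >= constraints$lat_band[1] & lat <= constraints$lat_band[2]
  if (!is.null(constraints$land_mask) || !is.null(constraints$ice_mask)) {
    idx <- cell_indices(constraints, lon, lat)
    on_grid <- !is.na(idx$row) & !is.na(idx$col)
    ok <- ok & on_grid
    lin <- cbind(idx$row[on_grid], idx$col[on_grid])
    if (!is.null(constraints$land_mask)) {
      ok[on_grid] <- ok[on_grid] & !constraints$land_mask[lin]
    }
    if (!is.null(constraints$ice_mask)) {
      ok[on_grid] <- ok[on_grid] & !constraints$ice_mask[lin]
    }
  }
  ok
}

#' Simulate constrained null tracks for one observed track
#'
#' Generates `n` tracks with exactly the observed timestamps. Steps are
#' built by jointly resampling (speed, turning-angle) pairs from the
#' observed movement summary — preserving their pairing and hence
#' within-track autocorrelation — around a uniformly random initial bearing.
#' Each proposed fix must pass [point_allowed()] and stay within 5% of the
#' observed maximum colony distance; violations are resampled (with inward
#' heading reflection for distance-cap breaches) up to `retries` times per
#' step, then the simulation backtracks one step.
#'
#' @param obs Observed (regularized) track data frame.
#' @param summary Its [movement_summary()].
#' @param constraints A [constraint_set()]; its `max_distance_km` defaults
#'   to the summary's observed maximum.
#' @param n Number of null tracks (default 50).
#' @param seed Integer seed.
#' @param retries Per-step resampling budget.
#' @return List of `n` track data frames with `label = 0` and
#'   `replicate = 1..n` columns.
#' @export
simulate_null_tracks <- function(obs, summary, constraints, n = 50,
                                 seed = 1, retries = 100) {
  validate_track(obs)
  set.seed(seed)
  m <- nrow(obs)
  cap <- constraints$max_distance_km
  if (is.null(cap)) cap <- summary$max_distance_km
  cap <- cap * 1.05
  dt_h <- diff(as.numeric(obs$timestamp)) / 3600

  speeds <- summary$speeds_kmh
  turns <- summary$turning_angles_deg
  if (length(turns) == 0) stop("movement summary has no turning angles")
  # pair turn t (at fix k+1) with the speed of the following step
  pair_speed <- speeds[-1]
  pair_turn <- turns
  npair <- length(pair_turn)

  lon <- matrix(NA_real_, n, m); lat <- matrix(NA_real_, n, m)
  lon[, 1] <- obs$lon[1]; lat[, 1] <- obs$lat[1]
  heading <- stats::runif(n, 0, 360)
  # first step uses resampled speeds on the initial bearing
  first_speed <- sample(speeds, n, replace = TRUE)
  backtracks <- integer(n)
  s <- 1L
  pending_first <- TRUE
  while (s < m) {
    if (s == 1L) {
      sp <- if (pending_first) first_speed else sample(speeds, n, replace = TRUE)
      pending_first <- FALSE
      trn <- rep(0, n)
    } else {
      j <- sample.int(npair, n, replace = TRUE)
      sp <- pair_speed[j]
      trn <- pair_turn[j]
    }
    prop_head <- (heading + trn) %% 360
    dist <- sp * dt_h[s]
    active <- rep(TRUE, n)
    new_lon <- numeric(n); new_lat <- numeric(n)
    tries <- 0L
    while (any(active)) {
      a <- which(active)
      dst <- destination_point(lon[a, s], lat[a, s], prop_head[a], dist[a])
      ok <- point_allowed(dst$lon, dst$lat, constraints)
      d0 <- great_circle_distance(dst$lon, dst$lat, obs$lon[1], obs$lat[1])
      over <- d0 > cap
      ok <- ok & !over
      new_lon[a[ok]] <- dst$lon[ok]; new_lat[a[ok]] <- dst$lat[ok]
      heading[a[ok]] <- prop_head[a[ok]]
      active[a[ok]] <- FALSE
      if (!any(active)) break
      tries <- tries + 1L
      if (tries > retries) break
      bad <- which(active)
      # reflect cap-breaching headings inward about the local tangent
      refl <- bad[bad %in% a[over & !ok]]
      if (length(refl) > 0) {
        bcol <- initial_bearing(lon[refl, s], lat[refl, s],
                                obs$lon[1], obs$lat[1])
        prop_head[refl] <- (2 * bcol + 180 - prop_head[refl]) %% 360
      }
      # resample a fresh (speed, turn) pair for the rest
      res <- setdiff(bad, refl)
      if (length(res) > 0) {
        j <- sample.int(npair, length(res), replace = TRUE)
        dist[res] <- pair_speed[j] * dt_h[s]
        prop_head[res] <- (heading[res] + pair_turn[j]) %% 360
      }
    }
    if (any(active)) {
      # step-level backtracking for the stuck replicates
      stuck <- which(active)
      backtracks[stuck] <- backtracks[stuck] + 1L
      if (any(backtracks > 50)) {
        stop("null-track simulation failed for track '",
             obs$individual_id[1], "' after repeated backtracking")
      }
      if (s > 1L) {
        s <- s - 1L
        next
      } else {
        heading[stuck] <- stats::runif(length(stuck), 0, 360)
        next
      }
    }
    lon[, s + 1] <- new_lon; lat[, s + 1] <- new_lat
    s <- s + 1L
  }

  lapply(seq_len(n), function(r) {
    df <- data.frame(
      individual_id = if (!is.null(obs$individual_id)) obs$individual_id[1]
                      else "obs",
      colony_id = if (!is.null(obs$colony_id)) obs$colony_id[1] else NA,
      taxon = if (!is.null(obs$taxon)) obs$taxon[1] else NA,
      timestamp = obs$timestamp,
      lon = lon[r, ], lat = lat[r, ],
      label = 0L, replicate = r,
      stringsAsFactors = FALSE
    )
    class(df) <- c("hab_track", "data.frame")
    df
  })
}
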