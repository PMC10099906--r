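# Covariate matching: nearest-cell, matching-date lookup at 1 degree / daily
# resolution, seafloor-slope derivation, and April-September climatologies.

#' Derive the bathymetry gradient (seafloor slope)
#'
#' Slope in degrees, `atan(|grad depth|)`, from central differences
#' (one-sided at grid edges) with the zonal spacing scaled by `cos(lat)`
#' to metres per degree.
#'
#' @param bathy `nlat x nlon` bathymetry matrix, metres (negative below sea
#'   level).
#' @param lat Latitude cell centers, degrees.
#' @param res Grid resolution, degrees.
#' @return Matrix of slopes, degrees. Invariant to adding a constant depth.
#' @export
bathymetry_gradient <- function(bathy, lat, res = 1) {
  nlat <- nrow(bathy); nlon <- ncol(bathy)
  m_per_deg <- EARTH_RADIUS_KM * 1000 * pi / 180
  ddy <- matrix(0, nlat, nlon)
  if (nlat > 1) {
    ddy[2:(nlat - 1), ] <- (bathy[3:nlat, ] - bathy[1:(nlat - 2), ]) / 2
    ddy[1, ] <- bathy[2, ] - bathy[1, ]
    ddy[nlat, ] <- bathy[nlat, ] - bathy[nlat - 1, ]
  }
  ddx <- matrix(0, nlat, nlon)
  if (nlon > 1) {
    ddx[, 2:(nlon - 1)] <- (bathy[, 3:nlon] - bathy[, 1:(nlon - 2)]) / 2
    ddx[, 1] <- bathy[, 2] - bathy[, 1]
    ddx[, nlon] <- bathy[, nlon] - bathy[, nlon - 1]
  }
  dy <- ddy / (res * m_per_deg)
  dx <- ddx / (res * m_per_deg * cos(deg2rad(matrix(lat, nlat, nlon))))
  rad2deg(atan(sqrt(dx^2 + dy^2)))
}

#' Extract covariates at point locations
#'
#' Pure nearest-cell, matching-date lookup (no interpolation): each point
#' takes the value of its containing 1-degree cell on its calendar date.
#' Rows with any missing covariate are dropped; per-covariate drop counts
#' are attached as the `"drop_report"` attribute.
#'
#' @param points Data frame with `lon`, `lat` and (for daily stacks)
#'   `timestamp`; other columns are carried through.
#' @param stack An [env_stack()]. A climatology stack matches all dates.
#' @return `points` plus one column per covariate layer, minus dropped rows;
#'   attribute `drop_report` holds a named vector of drop counts (including
#'   `off_grid`).
#' @export
extract_covariates <- function(points, stack) {
  stopifnot(inherits(stack, "env_stack"))
  idx <- cell_indices(stack, points$lon, points$lat)
  if (!is.null(stack$dates)) {
    if (is.null(points$timestamp)) stop("daily stack needs point timestamps")
    pdate <- as.Date(points$timestamp, tz = "UTC")
    ti <- match(pdate, stack$dates)
    if (anyNA(ti)) {
      bad <- unique(pdate[is.na(ti)])
      stop("point date(s) outside stack range: ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  } else {
    ti <- NULL
  }
  on_grid <- !is.na(idx$row) & !is.na(idx$col)
  out <- as.data.frame(points)
  drop <- c(off_grid = sum(!on_grid))
  for (nm in names(stack$layers)) {
    v <- rep(NA_real_, nrow(out))
    if (is.null(ti)) {
      v[on_grid] <- stack$layers[[nm]][cbind(idx$row[on_grid], idx$col[on_grid])]
    } else {
      v[on_grid] <- stack$layers[[nm]][cbind(idx$row[on_grid], idx$col[on_grid],
                                             ti[on_grid])]
    }
    miss <- on_grid & is.na(v)
    drop[nm] <- sum(miss)
    out[[nm]] <- v
  }
  keep <- stats::complete.cases(out[names(stack$layers)]) & on_grid
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "drop_report") <- drop
  res
}

#' Build an April-September climatology
#'
#' Per-cell arithmetic mean over all daily slices whose month falls in
#' `months` (and year in `years`, if given); missing values are excluded
#' cell-wise, and cells missing on every date stay missing.
#'
#' @param stack Daily [env_stack()].
#' @param months Integer months to include (default April-September).
#' @param years Optional years filter.
#' @return Climatology `env_stack` (single slice).
#' @export
build_climatology <- function(stack, months = 4:9, years = NULL) {
  stopifnot(inherits(stack, "env_stack"))
  if (is.null(stack$dates)) return(stack)
  sel <- as.integer(format(stack$dates, "%m")) %in% months
  if (!is.null(years)) {
    sel <- sel & as.integer(format(stack$dates, "%Y")) %in% years
  }
  if (!any(sel)) stop("no dates qualify for the climatology")
  layers <- lapply(stack$layers, function(a) {
    sub <- a[, , sel, drop = FALSE]
    m <- apply(sub, c(1, 2), function(v) {
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    })
    m
  })
  env_stack(stack$lon, stack$lat, layers, dates = NULL,
            land_mask = stack$land_mask)
}

#' Assemble the case-control table
#'
#' Binds observed tracks (label 1) and their null tracks (label 0), attaches
#' covariates by nearest cell and matching date, and drops rows with missing
#' covariates.
#'
#' @param obs_tracks List of observed (regularized) track data frames.
#' @param null_tracks List (per observed track) of lists of null tracks, as
#'   returned by [simulate_null_tracks()].
#' @param stack Daily [env_stack()] for covariate matching.
#' @return Case-control data frame (`individual_id`, `colony_id`, `label`,
#'   `timestamp`, `lon`, `lat`, one column per covariate) with a
#'   `drop_report` attribute.
#' @export
build_case_control <- function(obs_tracks, null_tracks, stack) {
  obs <- do.call(rbind, lapply(obs_tracks, function(tr) {
    d <- as.data.frame(tr)[c("individual_id", "colony_id", "taxon",
                             "timestamp", "lon", "lat")]
    d$label <- 1L; d$replicate <- 0L
    d
  }))
  nul <- do.call(rbind, lapply(null_tracks, function(group) {
    do.call(rbind, lapply(group, function(tr) {
      as.data.frame(tr)[c("individual_id", "colony_id", "taxon",
                          "timestamp", "lon", "lat", "label", "replicate")]
    }))
  }))
  pts <- rbind(obs, nul)
  extract_covariates(pts, stack)
}

#' Write an extraction report as JSON
#'
#' @param table Output of [extract_covariates()] / [build_case_control()].
#' @param path Output JSON path.
#' @export
write_extraction_report <- function(table, path) {
  rep <- attr(table, "drop_report")
  jsonlite::write_json(
    list(rows_kept = nrow(table), drops = as.list(rep)),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}
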