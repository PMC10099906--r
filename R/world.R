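# Synthetic Southern-Ocean-like world with a known ground-truth preference
# function. Fields are zonally banded (SST/SSH linear in latitude) plus
# smooth spatial noise; colonies sit on sub-grid-scale islands; tracks are
# habitat-biased correlated random walks departing from and returning to
# their colony. Everything is deterministic under the configured seed.

#' Configuration for the synthetic world
#'
#' Defaults describe a 30 x 30 degree subantarctic sector over one austral
#' winter (April-September), with sea surface temperature falling 0.5 degC
#' per degree of latitude poleward and sea surface height falling 0.05 m per
#' degree, a Gaussian preference peaked at 5 degC / -0.2 m (a subantarctic
#' frontal band), two colonies, and 12-h-resolution 90-day post-moult trips.
#'
#' @param lon_min,lon_max,lat_min,lat_max Grid extent, degrees; 1-degree
#'   cells centred on half degrees. Must lie poleward of 30 S.
#' @param year Synthetic year; daily fields span Apr 1 - Sep 30.
#' @param sst_gradient SST increase per degree latitude equatorward
#'   (degC per degree).
#' @param sst_at_40s SST at 40 S, degC.
#' @param ssh_gradient SSH increase per degree latitude equatorward
#'   (m per degree).
#' @param mld_gradient Mixed-layer-depth increase per degree latitude
#'   equatorward (m per degree).
#' @param ssh_at_40s SSH at 40 S, m.
#' @param noise_sd Named numeric vector of spatial noise standard deviations
#'   per layer (sst degC, sea_surface_height m, ssh_anomaly m,
#'   chlorophyll_a on log scale, eddy_kinetic_energy cm^2 s^-2,
#'   mixed_layer_depth m, bathymetry m).
#' @param noise_scale Global multiplier on all noise terms and the seasonal
#'   SST cycle; 0 gives exactly zonal, time-constant fields.
#' @param seasonal_amp Amplitude of the seasonal SST cycle, degC.
#' @param land_frac Fraction of grid cells turned into one-cell islands.
#' @param ice_edge_lat Latitude where ice concentration crosses 50%.
#' @param ice_width Logistic width of the ice edge, degrees.
#' @param colonies Data frame `colony_id, lon, lat, population`. Colonies are
#'   treated as sub-grid islands: their cells remain sea in the land mask.
#' @param mu_sst,sigma_sst True preference optimum and tolerance in SST, degC.
#' @param mu_ssh,sigma_ssh True preference optimum and tolerance in SSH, m.
#' @param n_individuals Number of tracked individuals to simulate.
#' @param duration_days Trip duration, days.
#' @param step_hours Fix interval, hours.
#' @param mean_speed_kmh,speed_sd_kmh Step speed distribution, km/h.
#' @param turn_concentration von-Mises-style concentration of the correlated
#'   random walk prior on turning angles.
#' @param pref_bias Softmax weight on the true preference sensed ahead of
#'   each candidate heading.
#' @param lookahead_steps How many mean step lengths ahead the walker
#'   senses preference when weighing candidate headings (a crude proxy for
#'   memory/perception; 1 = destination cell only).
#' @param delta_t Future warming applied to SST, degC.
#' @param n_reps Number of pseudo climate representations.
#' @param rep_noise_sd Per-representation SST noise, degC.
#' @param daily If `FALSE`, generate only climatology slices (no time axis).
#' @param seed Integer seed controlling every random draw.
#' @return A `world_config` list.
#' @export
world_config <- function(lon_min = 0, lon_max = 30,
                         lat_min = -70, lat_max = -40,
                         year = 2019,
                         sst_gradient = 0.5, sst_at_40s = 12,
                         ssh_gradient = 0.05, ssh_at_40s = 0.5,
                         mld_gradient = 0.8,
                         noise_sd = c(sst = 0.8, sea_surface_height = 0.2,
                                      ssh_anomaly = 0.05, chlorophyll_a = 0.4,
                                      eddy_kinetic_energy = 30,
                                      mixed_layer_depth = 12,
                                      bathymetry = 600),
                         noise_scale = 1, seasonal_amp = 0.75,
                         land_frac = 0.03,
                         ice_edge_lat = -67, ice_width = 1.5,
                         colonies = data.frame(
                           colony_id = c("c1", "c2"),
                           lon = c(10.5, 20.5), lat = c(-60.5, -60.5),
                           population = c(1000, 600)
                         ),
                         mu_sst = 5, sigma_sst = 2,
                         mu_ssh = -0.2, sigma_ssh = 0.7,
                         n_individuals = 50, duration_days = 90,
                         step_hours = 12,
                         mean_speed_kmh = 3, speed_sd_kmh = 1,
                         turn_concentration = 2, pref_bias = 12,
                         lookahead_steps = 3,
                         delta_t = 1.5, n_reps = 8, rep_noise_sd = 0.1,
                         daily = TRUE, seed = 1) {
  if (lat_max > -30) {
    stop("world extent must lie poleward of 30 S (lat_max <= -30)")
  }
  stopifnot(lon_max > lon_min, lat_max > lat_min,
            sigma_sst > 0, sigma_ssh > 0)
  cfg <- as.list(environment())
  class(cfg) <- "world_config"
  cfg
}

# Smooth mean-zero noise field with marginal sd approximately `sd`:
# white noise passed twice through a 3x3 moving average, then rescaled.
smooth_noise <- function(nlat, nlon, sd) {
  if (sd <= 0) return(matrix(0, nlat, nlon))
  z <- matrix(stats::rnorm(nlat * nlon), nlat, nlon)
  blur <- function(m) {
    p <- rbind(m[1, ], m, m[nlat, ])
    p <- cbind(p[, 1], p, p[, nlon])
    (p[1:nlat, 1:nlon] + p[1:nlat, 2:(nlon + 1)] + p[1:nlat, 3:(nlon + 2)] +
       p[2:(nlat + 1), 1:nlon] + p[2:(nlat + 1), 2:(nlon + 1)] +
       p[2:(nlat + 1), 3:(nlon + 2)] +
       p[3:(nlat + 2), 1:nlon] + p[3:(nlat + 2), 2:(nlon + 1)] +
       p[3:(nlat + 2), 3:(nlon + 2)]) / 9
  }
  z <- blur(blur(z))
  z <- z - mean(z)
  s <- stats::sd(z)
  if (s > 0) z * (sd / s) else z
}

#' Ground-truth habitat preference
#'
#' Product of two Gaussians in SST and SSH:
#' `p = exp(-(sst - mu_sst)^2 / (2 sigma_sst^2)) *
#'      exp(-(ssh - mu_ssh)^2 / (2 sigma_ssh^2))`.
#' Values lie in `[0, 1]` with the peak at (`mu_sst`, `mu_ssh`).
#'
#' @param covariates Named list (or data frame) with elements `sst` (degC)
#'   and `sea_surface_height` (m); vectors or matrices.
#' @param params A `world_config` (or any list with `mu_sst`, `sigma_sst`,
#'   `mu_ssh`, `sigma_ssh`).
#' @return Preference on the probability scale, same shape as the inputs.
#' @export
true_preference <- function(covariates, params) {
  for (nm in c("sst", "sea_surface_height")) {
    if (is.null(covariates[[nm]])) {
      stop("missing covariate '", nm, "' required by true_preference()")
    }
  }
  sst <- covariates$sst
  ssh <- covariates$sea_surface_height
  exp(-(sst - params$mu_sst)^2 / (2 * params$sigma_sst^2)) *
    exp(-(ssh - params$mu_ssh)^2 / (2 * params$sigma_ssh^2))
}

#' Generate the synthetic world
#'
#' Builds daily covariate stacks (all nine layers), land and ice masks, an
#' April-September climatology, and the ground-truth preference surface.
#' Deterministic given `config$seed`.
#'
#' @param config A [world_config()].
#' @return A `synthetic_world` list with elements `config`, `current`
#'   (daily `env_stack`, or climatology if `config$daily` is `FALSE`),
#'   `clim` (climatology `env_stack`), `land_mask`, `ice_mask` (logical
#'   matrices), `colonies`, and `truth` (`hab_surface` of true preference).
#' @export
make_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  set.seed(config$seed)
  lon <- seq(config$lon_min + 0.5, config$lon_max - 0.5, by = 1)
  lat <- seq(config$lat_min + 0.5, config$lat_max - 0.5, by = 1)
  nlat <- length(lat); nlon <- length(lon)
  latm <- matrix(lat, nlat, nlon)

  ns <- function(nm) config$noise_scale * config$noise_sd[[nm]]

  sst0 <- config$sst_at_40s + config$sst_gradient * (latm + 40)
  ssh0 <- config$ssh_at_40s + config$ssh_gradient * (latm + 40)
  sst_clim <- sst0 + smooth_noise(nlat, nlon, ns("sst"))
  ssh_clim <- ssh0 + smooth_noise(nlat, nlon, ns("sea_surface_height"))
  ssha_clim <- smooth_noise(nlat, nlon, ns("ssh_anomaly"))
  chl_clim <- exp(log(0.3) + smooth_noise(nlat, nlon, ns("chlorophyll_a")))
  eke_clim <- pmax(60 + smooth_noise(nlat, nlon, ns("eddy_kinetic_energy")), 5)
  mld_clim <- pmax(80 + config$mld_gradient * (latm + 55) +
                     smooth_noise(nlat, nlon, ns("mixed_layer_depth")), 10)
  bathy <- -4000 + smooth_noise(nlat, nlon, ns("bathymetry"))
  ice_clim <- 100 / (1 + exp((latm - config$ice_edge_lat) / config$ice_width))
  ice_clim <- pmax(pmin(ice_clim, 100), 0)

  # one-cell islands; colony cells and their neighbours stay open water
  land <- matrix(FALSE, nlat, nlon)
  n_land <- round(config$land_frac * nlat * nlon)
  if (n_land > 0) {
    land[sample(nlat * nlon, n_land)] <- TRUE
  }
  cidx <- cell_indices(list(lon = lon, lat = lat),
                       config$colonies$lon, config$colonies$lat)
  if (anyNA(cidx$row)) stop("colony outside the grid extent")
  for (i in seq_along(cidx$row)) {
    r <- cidx$row[i]; c <- cidx$col[i]
    land[max(1, r - 1):min(nlat, r + 1), max(1, c - 1):min(nlon, c + 1)] <- FALSE
  }
  bathy[land] <- 200

  clim_layers <- list(
    sea_surface_height = ssh_clim, ssh_anomaly = ssha_clim,
    bathymetry = bathy, sst = sst_clim, chlorophyll_a = chl_clim,
    eddy_kinetic_energy = eke_clim, mixed_layer_depth = mld_clim,
    ice_concentration = ice_clim
  )
  clim_layers$bathymetry_gradient <- bathymetry_gradient(bathy, lat)
  clim_layers <- clim_layers[ENV_LAYER_VOCAB]
  # land cells carry no ocean covariates
  for (nm in setdiff(ENV_LAYER_VOCAB, c("bathymetry", "bathymetry_gradient"))) {
    clim_layers[[nm]][land] <- NA_real_
  }

  dates <- seq(as.Date(sprintf("%d-04-01", config$year)),
               as.Date(sprintf("%d-09-30", config$year)), by = "day")
  if (config$daily) {
    nt <- length(dates)
    doy <- as.numeric(dates - dates[1])
    seas <- config$noise_scale * config$seasonal_amp *
      cos(2 * pi * doy / 365)
    daily_layers <- lapply(clim_layers, function(m) {
      array(m, dim = c(nlat, nlon, nt))
    })
    sst_arr <- daily_layers$sst
    for (t in seq_len(nt)) sst_arr[, , t] <- sst_arr[, , t] + seas[t]
    daily_layers$sst <- sst_arr
    current <- env_stack(lon, lat, daily_layers, dates = dates,
                         land_mask = land)
  }
  clim <- env_stack(lon, lat, clim_layers, dates = NULL, land_mask = land)
  if (!config$daily) current <- clim

  truth_vals <- true_preference(
    list(sst = sst_clim, sea_surface_height = ssh_clim), config
  )
  truth_vals[land | ice_clim > 80] <- NA_real_
  truth <- hab_surface(lon, lat, truth_vals, taxon = "synthetic_eudyptes",
                       type = "true_preference")

  structure(
    list(config = config, current = current, clim = clim,
         land_mask = land, ice_mask = ice_clim > 80,
         colonies = config$colonies, truth = truth),
    class = "synthetic_world"
  )
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("<synthetic_world> ", length(x$truth$lat), "x", length(x$truth$lon),
      " grid, ", nrow(x$colonies), " colonies, ",
      sum(x$land_mask), " land cells, ", sum(x$ice_mask),
      " ice cells (>80%)\n", sep = "")
  invisible(x)
}

# Preference lookup used by the track simulator (clim truth surface, NA -> 0).
world_pref_at <- function(world, lon, lat) {
  idx <- cell_indices(world$truth, lon, lat)
  p <- rep(0, length(lon))
  ok <- !is.na(idx$row) & !is.na(idx$col)
  v <- world$truth$values[cbind(idx$row[ok], idx$col[ok])]
  v[is.na(v)] <- -1 # masked cells are forbidden, not just unattractive
  p[ok] <- v
  p[!ok] <- -1
  p
}

#' Simulate habitat-biased tracks
#'
#' Correlated random walk at the configured fix interval: candidate headings
#' are weighted by a von-Mises-style persistence prior times a softmax in the
#' destination cell's true preference; masked (land, >80% ice, off-grid)
#' destinations are forbidden. The walk departs from its colony and is
#' steered back so the final fix lies within one grid cell of the colony.
#'
#' @param world A `synthetic_world`.
#' @param n Number of individuals (default from the world config).
#' @param seed Seed (default: world seed + 1).
#' @return List of track data frames
#'   (`individual_id, colony_id, taxon, timestamp, lon, lat`).
#' @export
simulate_tracks <- function(world, n = world$config$n_individuals,
                            seed = world$config$seed + 1) {
  cfg <- world$config
  set.seed(seed)
  n_steps <- as.integer(cfg$duration_days * 24 / cfg$step_hours)
  step_h <- cfg$step_hours
  mean_step <- cfg$mean_speed_kmh * step_h
  dates0 <- if (is.null(world$current$dates)) {
    as.Date(sprintf("%d-04-01", cfg$year))
  } else world$current$dates[1]
  max_start <- max(0L, 182L - as.integer(cfg$duration_days))
  turns <- seq(-135, 135, length.out = 15)
  prior <- exp(cfg$turn_concentration * cos(deg2rad(turns)))

  lapply(seq_len(n), function(i) {
    col_i <- ((i - 1) %% nrow(world$colonies)) + 1
    colony <- world$colonies[col_i, ]
    start_off <- if (max_start > 0) sample.int(max_start, 1) - 1L else 0L
    t0 <- as.POSIXct(dates0, tz = "UTC") + start_off * 86400
    ts <- t0 + (0:n_steps) * step_h * 3600
    lon <- numeric(n_steps + 1); lat <- numeric(n_steps + 1)
    lon[1] <- colony$lon; lat[1] <- colony$lat
    heading <- stats::runif(1, 0, 360)
    returning <- FALSE
    for (s in seq_len(n_steps)) {
      speed <- max(0.2, stats::rnorm(1, cfg$mean_speed_kmh, cfg$speed_sd_kmh))
      dist <- speed * step_h
      d2col <- great_circle_distance(lon[s], lat[s], colony$lon, colony$lat)
      remaining <- n_steps - s + 1
      if (!returning && d2col >= 0.7 * remaining * mean_step) returning <- TRUE
      if (returning || (s > n_steps - 2 && d2col > 1)) {
        # hard return: great-circle legs home, deflected around masked cells
        b0 <- initial_bearing(lon[s], lat[s], colony$lon, colony$lat)
        placed <- FALSE
        for (off in c(0, 20, -20, 40, -40, 60, -60, 90, -90)) {
          dst <- destination_point(lon[s], lat[s], b0 + off, min(dist, d2col))
          if (min(dist, d2col) < 1e-9 ||
              world_pref_at(world, dst$lon, dst$lat) >= 0) {
            lon[s + 1] <- dst$lon; lat[s + 1] <- dst$lat
            heading <- (b0 + off) %% 360
            placed <- TRUE
            break
          }
        }
        if (!placed) { # shorten the leg rather than cross land
          for (off in c(0, 45, -45, 90, -90, 135, -135, 180)) {
            dst <- destination_point(lon[s], lat[s], b0 + off,
                                     min(dist, d2col) / 4)
            if (world_pref_at(world, dst$lon, dst$lat) >= 0) {
              lon[s + 1] <- dst$lon; lat[s + 1] <- dst$lat
              heading <- (b0 + off) %% 360
              placed <- TRUE
              break
            }
          }
        }
        if (!placed) { # boxed in: hold position this step
          lon[s + 1] <- lon[s]; lat[s + 1] <- lat[s]
        }
        next
      }
      cand_head <- (heading + turns) %% 360
      dst <- destination_point(rep(lon[s], 15), rep(lat[s], 15),
                               cand_head, rep(dist, 15))
      pref <- world_pref_at(world, dst$lon, dst$lat)
      # preference is sensed several mean steps ahead of each heading
      ahead <- destination_point(rep(lon[s], 15), rep(lat[s], 15), cand_head,
                                 rep(cfg$lookahead_steps * mean_step, 15))
      pref_ahead <- world_pref_at(world, ahead$lon, ahead$lat)
      sensed <- pmax(pref, pref_ahead)
      w <- prior * exp(cfg$pref_bias * sensed)
      # soft pull home over the final fifth of the trip
      frac <- s / n_steps
      if (frac > 0.8 && d2col > 1) {
        bcol <- initial_bearing(lon[s], lat[s], colony$lon, colony$lat)
        ramp <- (frac - 0.8) / 0.2
        w <- w * exp(3 * ramp * cos(deg2rad(cand_head - bcol)))
      }
      w[pref < 0] <- 0
      if (all(w == 0)) {
        # boxed in; bounded retries with a shorter step, then give up
        ok <- FALSE
        for (r in 1:25) {
          dist2 <- dist / (1 + r / 5)
          dst <- destination_point(rep(lon[s], 15), rep(lat[s], 15),
                                   cand_head, rep(dist2, 15))
          pref <- world_pref_at(world, dst$lon, dst$lat)
          if (any(pref >= 0)) {
            w <- prior * as.numeric(pref >= 0)
            ok <- TRUE
            break
          }
        }
        if (!ok) stop("track simulation stuck (colony surrounded by land?) ",
                      "for individual ", i)
      }
      k <- sample.int(15, 1, prob = w)
      lon[s + 1] <- dst$lon[k]; lat[s + 1] <- dst$lat[k]
      heading <- cand_head[k]
    }
    df <- data.frame(
      individual_id = sprintf("ind%03d", i),
      colony_id = colony$colony_id,
      taxon = "synthetic_eudyptes",
      timestamp = ts, lon = lon, lat = lat,
      stringsAsFactors = FALSE
    )
    class(df) <- c("hab_track", "data.frame")
    df
  })
}

#' Build future climates and the ground-truth future preferred band
#'
#' Warms the climatological SST by `delta_t` uniformly and produces one
#' future stack per pseudo climate representation, differing only by a
#' seeded smooth SST noise field (mimicking inter-model spread). The
#' ground-truth future mask thresholds the closed-form true preference on
#' the noise-free warmed fields at the same percentile used for the current
#' preferred mask.
#'
#' @param world A `synthetic_world`.
#' @param delta_t Warming, degC (>= 0). Default from the world config.
#' @param n_reps Number of representations.
#' @param rep_noise_sd Per-representation SST noise sd, degC.
#' @param q Percentile (0-100) defining "preferred" for the truth masks.
#' @param scenario Scenario tag attached to every representation.
#' @param seed Seed for representation noise.
#' @return List with `reps` (list of `climate_representation`: `name`,
#'   `scenario`, `current`, `future` climatology `env_stack`s), and
#'   `truth_current` / `truth_future` binary `hab_surface` masks.
#' @export
make_future_climate <- function(world, delta_t = world$config$delta_t,
                                n_reps = world$config$n_reps,
                                rep_noise_sd = world$config$rep_noise_sd,
                                q = 90, scenario = "synthetic",
                                seed = world$config$seed + 2) {
  stopifnot(delta_t >= 0, n_reps >= 1)
  set.seed(seed)
  clim <- world$clim
  nlat <- length(clim$lat); nlon <- length(clim$lon)

  warmed <- clim$layers
  warmed$sst <- warmed$sst + delta_t

  # representations: warmed fields + representation-specific SST noise;
  # odd representations lack chlorophyll (inter-model variable coverage)
  reps <- lapply(seq_len(n_reps), function(r) {
    lay <- warmed
    lay$sst <- lay$sst + smooth_noise(nlat, nlon, rep_noise_sd)
    keep <- setdiff(ENV_LAYER_VOCAB, "ice_concentration")
    if (r %% 2 == 1) keep <- setdiff(keep, "chlorophyll_a")
    structure(
      list(name = sprintf("rep%02d", r), scenario = scenario,
           current = env_stack(clim$lon, clim$lat, clim$layers[keep],
                               land_mask = clim$land_mask),
           future = env_stack(clim$lon, clim$lat, lay[keep],
                              land_mask = clim$land_mask)),
      class = "climate_representation"
    )
  })

  truth_mask <- function(sst_field) {
    p <- true_preference(
      list(sst = sst_field, sea_surface_height = clim$layers$sea_surface_height),
      world$config
    )
    p[is.na(world$truth$values)] <- NA_real_
    imp <- percentile_transform(hab_surface(clim$lon, clim$lat, p))
    top_percentile_mask(imp, q = q)
  }
  list(
    reps = reps,
    truth_current = truth_mask(clim$layers$sst),
    truth_future = truth_mask(warmed$sst)
  )
}
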