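# Shared fixtures, built once per test run and memoized. Problem sizes are
# desk-scale study conditions: 50 individuals x 30-day trips x 50 nulls for
# parameter recovery; a noise-free 60-day configuration for the warming
# projection.

.fx <- new.env(parent = emptyenv())

# Parameter-recovery study: default (noisy) world, 50 tracks, 50 nulls each,
# case-control table and the fitted preference model.
fx_recovery <- function() {
  if (is.null(.fx$recovery)) {
    cfg <- world_config(n_individuals = 50, duration_days = 30)
    world <- make_world(cfg)
    tracks <- simulate_tracks(world)
    cons <- constraints_from_world(world)
    t_null0 <- Sys.time()
    summaries <- lapply(tracks, function(tr) {
      colony <- world$colonies[world$colonies$colony_id == tr$colony_id[1], ]
      movement_summary(tr, colony$lon, colony$lat)
    })
    nulls <- lapply(seq_along(tracks), function(i) {
      simulate_null_tracks(tracks[[i]], summaries[[i]], cons,
                           n = 50, seed = 100 + i)
    })
    null_secs <- as.numeric(difftime(Sys.time(), t_null0, units = "secs"))
    table <- build_case_control(tracks, nulls, world$current)
    fit <- fit_brt(table, brt_config(max_trees = 1500, n_folds = 5),
                   seed = 3)
    .fx$recovery <- list(
      world = world, tracks = tracks, summaries = summaries, nulls = nulls,
      constraints = cons, table = table, fit = fit, null_secs = null_secs
    )
  }
  .fx$recovery
}

# Noise-free warming study: only SST varies (flat SSH and mixed-layer
# fields) and the optimum sits off the cell lattice so decile ranks have no
# cross-row ties; the analytic future band shifts poleward by exactly
# delta-T / gradient = 2 degrees. Run without the accessibility overlay
# (preference vs analytic band).
fx_poleward <- function() {
  if (is.null(.fx$poleward)) {
    .fx$poleward <- run_pipeline(
      config = world_config(noise_scale = 0, ssh_gradient = 0,
                            mld_gradient = 0, mu_sst = 4.6,
                            n_individuals = 40, duration_days = 60,
                            n_reps = 4, rep_noise_sd = 0, delta_t = 1),
      brt = brt_config(max_trees = 800, n_folds = 5),
      seed = 11, n_null = 30, use_access = FALSE
    )
  }
  .fx$poleward
}

# Small noisy world for cheap structural tests.
fx_world_small <- function() {
  if (is.null(.fx$world_small)) {
    .fx$world_small <- make_world(
      world_config(n_individuals = 8, duration_days = 20, seed = 4)
    )
  }
  .fx$world_small
}

# Regular 12-h equatorial toy track.
toy_track <- function(lons, lats, start = "2019-04-01 00:00:00",
                      step_hours = 12, id = "t1", colony = "c1") {
  data.frame(
    individual_id = id, colony_id = colony, taxon = "toy",
    timestamp = as.POSIXct(start, tz = "UTC") +
      (seq_along(lons) - 1) * step_hours * 3600,
    lon = lons, lat = lats,
    stringsAsFactors = FALSE
  )
}

# Balanced separable-ish case-control toy table for BRT tests.
toy_cc_table <- function(n = 500, n_ind = 10, noise = 0, seed = 1,
                         colony = "c1", flip = FALSE) {
  set.seed(seed)
  sst <- stats::runif(n, -2, 2)
  ssh <- stats::rnorm(n)
  lab <- as.integer(sst + stats::rnorm(n, sd = max(noise, 1e-9)) > 0)
  if (flip) lab <- 1L - lab
  data.frame(
    individual_id = sprintf("%s_i%02d", colony, rep_len(seq_len(n_ind), n)),
    colony_id = colony, label = lab,
    sst = sst, sea_surface_height = ssh
  )
}
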