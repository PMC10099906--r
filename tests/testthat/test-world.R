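# Synthetic world generator: determinism, field construction, the
# closed-form preference, track construction, and future warming.

test_that("the world is bit-identical under a fixed seed", {
  cfg <- world_config(n_individuals = 2, duration_days = 10, seed = 17)
  w1 <- make_world(cfg); w2 <- make_world(cfg)
  expect_identical(w1$clim$layers, w2$clim$layers)
  expect_identical(w1$land_mask, w2$land_mask)
  expect_identical(simulate_tracks(w1, seed = 5), simulate_tracks(w2, seed = 5))
})

test_that("zero-noise SST is exactly linear in latitude", {
  cfg <- world_config(noise_scale = 0, land_frac = 0, daily = FALSE)
  w <- make_world(cfg)
  sst <- w$clim$layers$sst
  lat <- w$clim$lat
  for (j in seq_along(w$clim$lon)) {
    expect_equal(sst[, j], 12 + 0.5 * (lat + 40), tolerance = 1e-12)
  }
  expect_error(make_world(world_config(lat_max = -10)), "poleward of 30 S")
})

test_that("true preference follows the closed-form Gaussian product", {
  p <- world_config()
  expect_equal(true_preference(list(sst = 5, sea_surface_height = -0.2), p), 1)
  expect_equal(
    true_preference(list(sst = 5 + p$sigma_sst, sea_surface_height = -0.2), p),
    exp(-0.5), tolerance = 1e-12
  )
  # symmetry about the optimum
  for (x in c(0.5, 1, 3)) {
    expect_equal(
      true_preference(list(sst = 5 + x, sea_surface_height = -0.2), p),
      true_preference(list(sst = 5 - x, sea_surface_height = -0.2), p)
    )
  }
  expect_error(true_preference(list(sst = 5), p), "sea_surface_height")
  w <- fx_world_small()
  expect_true(all(w$truth$values >= 0 & w$truth$values <= 1, na.rm = TRUE))
})

test_that("tracks start and end at the colony with 12-h spacing", {
  w <- fx_world_small()
  cfg2 <- world_config(n_individuals = 3, duration_days = 60, seed = 4)
  w60 <- make_world(cfg2)
  tracks <- simulate_tracks(w60, n = 3, seed = 9)
  cons <- constraints_from_world(w60)
  for (tr in tracks) {
    expect_equal(nrow(tr), 121) # 60 d at 12 h
    expect_equal(as.numeric(diff(tr$timestamp), units = "hours"),
                 rep(12, 120))
    colony <- w60$colonies[w60$colonies$colony_id == tr$colony_id[1], ]
    expect_lt(great_circle_distance(tr$lon[1], tr$lat[1],
                                    colony$lon, colony$lat), 111.2)
    expect_lt(great_circle_distance(tr$lon[121], tr$lat[121],
                                    colony$lon, colony$lat), 111.2)
    # every fix respects the sea / ice / latitude constraints
    expect_true(all(point_allowed(tr$lon, tr$lat, cons)))
  }
})

test_that("tracks prefer high-preference water relative to random sea", {
  w <- fx_world_small()
  tracks <- simulate_tracks(w, n = 8, seed = 2)
  on_track <- mean(unlist(lapply(tracks, function(tr) {
    habshift:::world_pref_at(w, tr$lon, tr$lat)
  })))
  sea <- w$truth$values[!is.na(w$truth$values)]
  set.seed(99)
  null_means <- replicate(1000, mean(sample(sea, 50, replace = TRUE)))
  # one-sided Monte-Carlo: track preference above the random-sea null
  expect_gt(on_track, stats::quantile(null_means, 0.99))
})

test_that("warming shifts the true preferred band poleward by dT/gradient", {
  # SSH made uninformative so the band is set by SST alone; the optimum is
  # placed off the cell lattice so decile ranks have no cross-row ties
  cfg <- world_config(noise_scale = 0, land_frac = 0, daily = FALSE,
                      sigma_ssh = 1e6, mu_sst = 4.6)
  w <- make_world(cfg)
  fut0 <- make_future_climate(w, delta_t = 0, n_reps = 2, rep_noise_sd = 0)
  expect_equal(fut0$truth_future$values, fut0$truth_current$values)
  expect_equal(fut0$reps[[1]]$future$layers$sst,
               fut0$reps[[1]]$current$layers$sst)
  fut1 <- make_future_climate(w, delta_t = 1, n_reps = 2, rep_noise_sd = 0)
  shift <- mask_centroid_lat(fut1$truth_current) -
    mask_centroid_lat(fut1$truth_future)
  expect_equal(shift, 1 / 0.5, tolerance = 0.05) # 2 degrees poleward
  # the warmed band never extends equatorward of the current north edge
  north_edge <- function(m) {
    latm <- matrix(m$lat, length(m$lat), length(m$lon))
    max(latm[which(m$values == 1)])
  }
  expect_lte(north_edge(fut1$truth_future), north_edge(fut1$truth_current))
})
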