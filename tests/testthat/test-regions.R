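# Regional partition, geodesic cell areas, and percent change accounting.

test_that("cell area matches the spherical quadrilateral closed form", {
  expect_equal(cell_area(0), 6371^2 * (pi / 180) *
                 (sin(pi / 360) - sin(-pi / 360)), tolerance = 1e-12)
  expect_equal(cell_area(0), 12363.7, tolerance = 1e-4)
  expect_equal(cell_area(55), cell_area(-55))
  lats <- seq(-0.5, -89.5, by = -1)
  expect_true(all(diff(cell_area(lats)) < 0))
})

test_that("cells are assigned to exactly one region by center point", {
  grid <- list(lon = seq(-179.5, 179.5), lat = seq(-69.5, -40.5))
  lab <- assign_regions(grid)
  expect_true(all(!is.na(lab)))
  expect_equal(sort(unique(as.vector(lab))),
               sort(c("Atlantic", "Central Indian", "East Indian",
                      "West Pacific", "East Pacific")))
  # sector cell counts match boundary widths (100, 60, 60, 80, 60 degrees)
  counts <- table(lab[1, ])
  expect_equal(unname(counts[c("Atlantic", "Central Indian", "East Indian",
                               "West Pacific", "East Pacific")]),
               c(100, 60, 60, 80, 60), ignore_attr = TRUE)
  # cells north of 30 S are unlabeled
  lab2 <- assign_regions(list(lon = c(0.5), lat = c(-20.5)))
  expect_true(is.na(lab2[1, 1]))
})

test_that("region areas sum exactly to the total mask area", {
  grid <- list(lon = seq(-179.5, 179.5), lat = seq(-69.5, -40.5))
  set.seed(9)
  v <- matrix(stats::rbinom(360 * 30, 1, 0.2), 30, 360)
  mask <- hab_surface(grid$lon, grid$lat, v)
  lab <- assign_regions(mask)
  areas <- matrix(cell_area(grid$lat), 30, 360)
  rec <- percent_area_change(mask, mask, lab)
  expect_equal(sum(rec$current_km2), sum(areas[v == 1]),
               tolerance = 1e-12)
  # identical masks: zero percent change in every region
  expect_equal(rec$pct_change, rep(0, nrow(rec)))
})

test_that("percent change follows the area-weighted definition", {
  # 3-sector toy grid against a literal cell-by-cell hand computation
  lon <- seq(0.5, 5.5); lat <- seq(-65.5, -60.5)
  regions <- structure(list(polys = list(
    R1 = list(cbind(lon = c(0, 2, 2, 0, 0), lat = c(-90, -90, -30, -30, -90))),
    R2 = list(cbind(lon = c(2, 4, 4, 2, 2), lat = c(-90, -90, -30, -30, -90))),
    R3 = list(cbind(lon = c(4, 6, 6, 4, 4), lat = c(-90, -90, -30, -30, -90)))
  )), class = "region_set")
  lab <- assign_regions(list(lon = lon, lat = lat), regions)
  set.seed(13)
  cur <- matrix(stats::rbinom(36, 1, 0.5), 6, 6)
  fut <- matrix(stats::rbinom(36, 1, 0.5), 6, 6)
  rec <- percent_area_change(hab_surface(lon, lat, cur),
                             hab_surface(lon, lat, fut), lab)
  for (k in 1:3) {
    rg <- paste0("R", k)
    a_cur <- a_fut <- 0
    for (i in 1:6) for (j in 1:6) {
      if (lab[i, j] == rg) {
        a <- cell_area(lat[i])
        if (cur[i, j] == 1) a_cur <- a_cur + a
        if (fut[i, j] == 1) a_fut <- a_fut + a
      }
    }
    expect_equal(rec$pct_change[rec$region == rg],
                 100 * (a_fut - a_cur) / a_cur, tolerance = 1e-9)
  }
  # scale-free: multiplying all areas by a constant changes nothing
  areas <- matrix(cell_area(lat), 6, 6)
  rec2 <- percent_area_change(hab_surface(lon, lat, cur),
                              hab_surface(lon, lat, fut), lab,
                              areas = areas * 7.3)
  expect_equal(rec2$pct_change, rec$pct_change, tolerance = 1e-12)
  # removing half the (equal-area) cells of one region halves it
  lat_eq <- rep(-55.5, 1)
  cur1 <- matrix(1, 1, 6); fut1 <- matrix(c(1, 1, 1, 0, 0, 0), 1, 6)
  lab1 <- matrix("R1", 1, 6)
  rec3 <- percent_area_change(hab_surface(lon, lat_eq, cur1),
                              hab_surface(lon, lat_eq, fut1), lab1)
  expect_equal(rec3$pct_change, -50)
})

test_that("ensemble summaries use type-7 quartiles and ignore order", {
  rec <- data.frame(taxon = "t", region = "R", representation = letters[1:4],
                    scenario = "s", current_km2 = 1, future_km2 = 1,
                    pct_change = c(-4, -2, 0, 2))
  s <- summarize_ensemble(rec)
  expect_equal(s$median, -1)
  expect_equal(s$q25, stats::quantile(c(-4, -2, 0, 2), 0.25, type = 7)[[1]])
  expect_equal(s$q75, stats::quantile(c(-4, -2, 0, 2), 0.75, type = 7)[[1]])
  expect_equal(s$min, -4); expect_equal(s$max, 2)
  s2 <- summarize_ensemble(rec[c(3, 1, 4, 2), ])
  expect_equal(s2, s)
  same <- rec; same$pct_change <- 5
  s3 <- summarize_ensemble(same)
  expect_true(all(unlist(s3[c("min", "q25", "median", "q75", "max")]) == 5))
})

test_that("GeoJSON region sets round-trip through the reader", {
  gj <- list(
    type = "FeatureCollection",
    features = list(list(
      type = "Feature", properties = list(name = "Box"),
      geometry = list(type = "Polygon", coordinates = list(list(
        list(0, -60), list(10, -60), list(10, -50), list(0, -50),
        list(0, -60)
      )))
    ))
  )
  path <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, path, auto_unbox = TRUE)
  rs <- read_regions_geojson(path)
  lab <- assign_regions(list(lon = c(5.5, 15.5), lat = c(-55.5)), rs)
  expect_equal(as.vector(lab), c("Box", NA))
})
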