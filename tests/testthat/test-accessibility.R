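# Monotone accessibility curves and the preference x accessibility
# combination.

test_that("the visitation response marks exactly the visited cells", {
  grid <- list(lon = seq(0.5, 9.5), lat = seq(-59.5, -50.5))
  fixes <- data.frame(lon = c(0.6, 0.6, 5.5), lat = c(-59.4, -59.5, -55.5))
  resp <- build_access_response(fixes, grid, 0.5, -59.5)
  expect_equal(sum(resp$visited), 2) # two distinct cells
  expect_equal(nrow(resp), 100)
  none <- build_access_response(fixes[0, ], grid, 0.5, -59.5)
  expect_equal(sum(none$visited), 0)
})

test_that("a step-function response is recovered on both plateaus", {
  d <- seq(5, 1995, by = 10)
  resp <- data.frame(distance_km = d, visited = as.integer(d < 500))
  cu <- fit_accessibility(resp)
  dd <- seq(0, 2000, by = 10)
  p <- predict(cu, dd)
  expect_true(all(p[dd < 450] > 0.99))
  expect_true(all(p[dd > 1000] < 0.01))
  # monotone non-increasing everywhere on the grid
  expect_true(all(diff(p) <= 1e-9))
})

test_that("uniform visitation yields a flat curve at the rate", {
  set.seed(12)
  n <- 4000
  d <- stats::runif(n, 0, 2000)
  p0 <- 0.3
  resp <- data.frame(distance_km = d, visited = stats::rbinom(n, 1, p0))
  cu <- fit_accessibility(resp)
  dd <- seq(50, 1950, by = 50)
  sd_bin <- sqrt(p0 * (1 - p0) / (n / 40))
  expect_true(all(abs(predict(cu, dd) - p0) < 2 * sd_bin + 0.05))
  expect_true(all(diff(predict(cu, dd)) <= 1e-9))
})

test_that("degenerate single-class responses give flagged flat curves", {
  resp <- data.frame(distance_km = seq(10, 500, by = 10), visited = 1L)
  expect_warning(cu <- fit_accessibility(resp), "degenerate")
  expect_true(cu$degenerate)
  expect_equal(predict(cu, c(0, 100, 1e4)), rep(1, 3))
})

test_that("combination multiplies preference by accessibility", {
  lon <- seq(0.5, 19.5); lat <- seq(-60.5, -51.5)
  set.seed(3)
  pref <- hab_surface(lon, lat, matrix(stats::runif(200), 10, 20))
  colonies <- data.frame(colony_id = c("a", "b"), lon = c(2.5, 17.5),
                         lat = c(-56.5, -56.5), population = c(3, 1))
  flat1 <- structure(list(colony_id = "a", fn = function(x) rep(1, length(x)),
                          degenerate = FALSE), class = "access_curve")
  flat0 <- structure(list(colony_id = "b",
                          fn = function(x) as.numeric(x < 300)),
                     class = "access_curve")
  # access identically 1 -> combined equals preference exactly
  comb1 <- combine_preference_accessibility(
    pref, list(a = flat1, b = flat1), colonies
  )
  expect_equal(comb1$values, pref$values)
  # hard cutoff at 300 km -> zero beyond 300 km of both colonies
  comb0 <- combine_preference_accessibility(
    pref, list(a = flat0, b = flat0), colonies
  )
  lonm <- matrix(lon, 10, 20, byrow = TRUE); latm <- matrix(lat, 10, 20)
  dmin <- pmin(
    great_circle_distance(lonm, latm, colonies$lon[1], colonies$lat[1]),
    great_circle_distance(lonm, latm, colonies$lon[2], colonies$lat[2])
  )
  expect_true(all(comb0$values[dmin > 300] == 0))
  # combination never increases preference; colony order does not matter
  expect_true(all(comb0$values <= pref$values + 1e-12))
  comb_rev <- combine_preference_accessibility(
    pref, list(b = flat0, a = flat0), colonies[2:1, ]
  )
  expect_equal(comb_rev$values, comb0$values)
  # weighted mode: weights 3:1 with equal curves = (3 s1 + s2) / 4
  s1 <- pref$values * matrix(predict(flat0, great_circle_distance(
    lonm, latm, colonies$lon[1], colonies$lat[1])), 10, 20)
  s2 <- pref$values * matrix(predict(flat0, great_circle_distance(
    lonm, latm, colonies$lon[2], colonies$lat[2])), 10, 20)
  combw <- combine_preference_accessibility(
    pref, list(a = flat0, b = flat0), colonies, weights = "population"
  )
  expect_equal(combw$values, (3 * s1 + s2) / 4)
  expect_error(
    combine_preference_accessibility(pref, list(a = flat1), colonies),
    "missing accessibility curve"
  )
})
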