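# Normalization, PCA reduction, k-NN analogue classification (with a
# brute-force oracle) and ensemble combination.

test_that("normalization is a pooled 0-1 affine map and idempotent", {
  cur <- cbind(sst = c(-2, 0, 2), sea_surface_height = c(0, 5, 10))
  out <- normalize_variables(cur)
  expect_equal(out$current[, "sst"], c(0, 0.5, 1))
  expect_equal(apply(out$current, 2, min), c(sst = 0, sea_surface_height = 0))
  expect_equal(apply(out$current, 2, max), c(sst = 1, sea_surface_height = 1))
  again <- normalize_variables(out$current)
  expect_equal(again$current, out$current)
  # pooled scale: future extends the range, so current max maps below 1
  fut <- cur; fut[, "sst"] <- fut[, "sst"] + 2
  pooled <- normalize_variables(cur, fut)
  expect_equal(max(pooled$current[, "sst"]), 2 / 3)
  expect_equal(max(pooled$future[, "sst"]), 1)
  # constant variables are dropped with a warning
  cur2 <- cbind(sst = c(1, 2, 3), bathymetry = c(7, 7, 7))
  expect_warning(out2 <- normalize_variables(cur2), "constant")
  expect_equal(colnames(out2$current), "sst")
})

test_that("PCA retains the fewest components reaching the threshold", {
  set.seed(6)
  one <- matrix(stats::runif(100), ncol = 1)
  colnames(one) <- "sst"
  r1 <- reduce_dimensions(one)
  expect_equal(r1$n_components, 1)
  expect_equal(r1$variance_explained, 1)
  # exact collinearity collapses to one component
  x <- stats::runif(200)
  col2 <- cbind(a = x, b = 2 * x)
  expect_equal(reduce_dimensions(col2)$n_components, 1)
  # independent equal-variance pair needs both components
  ind <- cbind(a = stats::rnorm(4000), b = stats::rnorm(4000))
  expect_equal(reduce_dimensions(ind)$n_components, 2)
  # future cells are projected with current-period loadings
  r <- reduce_dimensions(col2, future = col2[1:5, , drop = FALSE] * 1)
  expect_equal(r$future, r$current[1:5, , drop = FALSE])
})

test_that("the 6-cell toy problem classifies by brute-force distances", {
  cur <- matrix(c(0.0, 0.1, 0.2, 0.8, 0.9, 1.0), ncol = 1)
  lab <- c(1, 1, 1, 0, 0, 0)
  fut <- matrix(0.15, ncol = 1)
  expect_equal(knn_analog_classify(cur, lab, fut, k = 3), 1L)
  expect_equal(knn_analog_classify(cur, lab, matrix(0.85), k = 3), 0L)
  # unanimity: all current preferred
  expect_equal(knn_analog_classify(cur, rep(1, 6), fut, k = 5), 1L)
  # identity: future = current with k = 1 reproduces the labels
  expect_equal(knn_analog_classify(cur, lab, cur, k = 1), as.integer(lab))
  expect_error(knn_analog_classify(cur, lab, fut, k = 7), "k exceeds")
})

# independent oracle: literal per-cell loop with explicit distance sums
knn_oracle <- function(cur, lab, fut, k) {
  vapply(seq_len(nrow(fut)), function(i) {
    d <- vapply(seq_len(nrow(cur)), function(j) {
      sqrt(sum((fut[i, ] - cur[j, ])^2))
    }, numeric(1))
    nn <- order(d, seq_along(d))[seq_len(k)]
    as.integer(sum(lab[nn]) * 2 > k)
  }, integer(1))
}

test_that("vectorized k-NN matches the brute-force oracle", {
  set.seed(31)
  for (rep in 1:5) {
    n_cur <- sample(50:300, 1)
    n_fut <- sample(20:200, 1)
    p <- sample(1:4, 1)
    cur <- matrix(stats::runif(n_cur * p), n_cur, p)
    lab <- stats::rbinom(n_cur, 1, 0.3)
    fut <- matrix(stats::runif(n_fut * p), n_fut, p)
    expect_identical(knn_analog_classify(cur, lab, fut, k = 5),
                     knn_oracle(cur, lab, fut, 5))
  }
})

test_that("ensemble combination applies the majority rule and partitions", {
  g <- function(v) hab_surface(c(0.5, 1.5), c(-50.5, -49.5),
                               matrix(v, 2, 2))
  proj <- function(v, nm) {
    structure(list(name = nm, scenario = "synthetic", layer = g(v),
                   k = 5, n_components = 1, variance_explained = 1),
              class = "analogue_projection")
  }
  cur <- g(c(1, 1, 0, 0))
  # 8 identical projections equal any single one
  same <- lapply(1:8, function(i) proj(c(1, 0, 1, 0), paste0("r", i)))
  comb <- ensemble_combine(same, cur)
  expect_equal(comb$future_mask$values, same[[1]]$layer$values)
  # 5/3 split -> majority wins
  split <- c(lapply(1:5, function(i) proj(c(1, 0, 0, 0), paste0("y", i))),
             lapply(1:3, function(i) proj(c(0, 0, 0, 0), paste0("n", i))))
  comb2 <- ensemble_combine(split, cur)
  expect_equal(comb2$future_mask$values[1, 1], 1)
  expect_equal(comb2$agreement$values[1, 1], 5)
  # categories partition every sea cell exactly once
  expect_true(all(comb2$category$values %in% 0:3))
  # retained / gained / lost / never coding
  comb3 <- ensemble_combine(list(proj(c(1, 0, 1, 0), "a")), cur)
  expect_equal(as.vector(comb3$category$values), c(3, 1, 2, 0))
  bad <- list(proj(c(1, 0, 0, 0), "a"),
              structure(list(name = "b", scenario = "other",
                             layer = g(c(1, 0, 0, 0))),
                        class = "analogue_projection"))
  expect_error(ensemble_combine(bad, cur), "mix scenarios")
})
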