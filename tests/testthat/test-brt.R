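# Boosted-tree preference model: separability, metrics, fold integrity,
# blocking validation and partial dependence on constructed tables.

test_that("a separable table is fit to training AUC 1 deterministically", {
  tab <- toy_cc_table(n = 500, noise = 0)
  fit <- fit_brt(tab, brt_config(max_trees = 300, tree_step = 50,
                                 n_folds = 5), seed = 2)
  expect_equal(fit$train_auc, 1.0, tolerance = 1e-4)
  expect_equal(sum(fit$importance), 100, tolerance = 0.01)
  expect_gt(fit$importance["sst"], fit$importance["sea_surface_height"])
  fit2 <- fit_brt(tab, brt_config(max_trees = 300, tree_step = 50,
                                  n_folds = 5), seed = 2)
  expect_identical(fit$n_trees, fit2$n_trees)
  expect_equal(predict(fit, tab), predict(fit2, tab))
})

test_that("random labels give chance-level cross-validated AUC", {
  set.seed(5)
  tab <- toy_cc_table(n = 2000, n_ind = 20)
  tab$label <- sample(tab$label) # sever the covariate link
  fit <- fit_brt(tab, brt_config(max_trees = 200, tree_step = 50,
                                 n_folds = 5), seed = 6)
  expect_lt(abs(fit$cv$auc_mean - 0.5), 0.05)
})

test_that("AUC and deviance behave at the extremes", {
  y <- rep(c(1, 0), each = 50)
  expect_equal(habshift:::auc_rank(y, y), 1.0)
  # constant prediction at the prevalence explains no deviance
  expect_equal(habshift:::bernoulli_deviance(y, mean(y)),
               habshift:::bernoulli_deviance(y, rep(mean(y), 100)))
  tab <- toy_cc_table(n = 400)
  tab$sst <- 0; tab$sea_surface_height <- 0 # no usable signal
  fit <- fit_brt(tab, brt_config(max_trees = 100, tree_step = 50,
                                 n_folds = 4), seed = 1)
  expect_lt(fit$pct_deviance_explained, 1)
})

test_that("folds partition individuals and degenerate inputs error", {
  tab <- toy_cc_table(n = 400, n_ind = 6)
  expect_warning(
    fit <- fit_brt(tab, brt_config(max_trees = 100, tree_step = 100,
                                   n_folds = 10), seed = 1),
    "fewer individuals than folds"
  )
  fold_of <- fit$cv$fold_of
  expect_length(fold_of, 6)
  expect_true(all(table(names(fold_of)) == 1)) # one fold per individual
  one_class <- tab; one_class$label <- 1L
  expect_error(fit_brt(one_class), "single class")
})

test_that("blocking validation transfers between exchangeable colonies and
           fails on a disjoint one", {
  tab <- rbind(toy_cc_table(n = 600, noise = 0.5, seed = 1, colony = "A"),
               toy_cc_table(n = 600, noise = 0.5, seed = 2, colony = "B"))
  bv <- blocking_validation(tab, brt_config(max_trees = 200, tree_step = 50,
                                            n_folds = 5),
                            seed = 3, n_trees = 200)
  # confusion cells conserve the held-out row count
  for (colny in names(bv)) {
    expect_equal(sum(bv[[colny]]$confusion), bv[[colny]]$n)
  }
  # identical generating process -> comparable held-out accuracy
  expect_lt(abs(bv$A$accuracy - bv$B$accuracy), 0.05)
  # a colony with the covariate-label relation inverted transfers badly
  tab2 <- rbind(toy_cc_table(n = 600, noise = 0.5, seed = 1, colony = "A"),
                toy_cc_table(n = 600, noise = 0.5, seed = 2, colony = "B"),
                toy_cc_table(n = 600, noise = 0.5, seed = 3, colony = "C",
                             flip = TRUE))
  bv2 <- blocking_validation(tab2, brt_config(max_trees = 200,
                                              tree_step = 50, n_folds = 5),
                             seed = 3, n_trees = 200)
  expect_lt(bv2$C$accuracy, bv2$A$accuracy - 0.2)
})

test_that("partial dependence is centered and flat for noise variables", {
  tab <- toy_cc_table(n = 1500, noise = 0.3, seed = 8)
  fit <- fit_brt(tab, brt_config(max_trees = 300, tree_step = 50,
                                 n_folds = 5), seed = 4)
  pd_sig <- partial_dependence(fit, "sst")
  pd_nse <- partial_dependence(fit, "sea_surface_height")
  expect_equal(mean(pd_sig$effect), 0, tolerance = 1e-10)
  expect_equal(mean(pd_nse$effect), 0, tolerance = 1e-10)
  # the informative variable dominates the uninformative one
  expect_gt(diff(range(pd_sig$effect)), 5 * diff(range(pd_nse$effect)))
  # monotone signal: effect increases with sst
  expect_gt(stats::cor(pd_sig$value, pd_sig$effect), 0.8)
  expect_error(partial_dependence(fit, "bathymetry"), "not in the model")
})
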