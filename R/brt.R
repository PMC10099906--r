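# Case-control boosted regression tree habitat-preference model.
# Bernoulli loss on observed (1) vs simulated (0) locations, learning rate
# 0.01, bag fraction 0.5, tree complexity (interaction depth) 5, optimal
# tree count chosen by k-fold cross-validation blocked on individual.
# xgboost is the gradient-boosting engine.

#' Boosted regression tree configuration
#'
#' Defaults follow common practice for presence-background tracking data:
#' slow learning (0.01), half-data bagging, depth-5 trees, Bernoulli loss,
#' and 10-fold cross-validation grouped by individual so no animal spans
#' folds. Candidate tree counts run from `tree_step` to `max_trees` in steps
#' of `tree_step`.
#'
#' @param learning_rate Shrinkage per tree.
#' @param bag_fraction Row subsample fraction per tree.
#' @param tree_complexity Tree interaction depth.
#' @param max_trees Largest candidate tree count.
#' @param tree_step Grid step for the tree-count search.
#' @param n_folds Cross-validation folds (grouped by individual).
#' @return A `brt_config` list.
#' @export
brt_config <- function(learning_rate = 0.01, bag_fraction = 0.5,
                       tree_complexity = 5, max_trees = 5000,
                       tree_step = 100, n_folds = 10) {
  stopifnot(learning_rate > 0, bag_fraction > 0, bag_fraction <= 1,
            tree_complexity >= 1, max_trees >= tree_step, tree_step >= 1)
  structure(
    list(learning_rate = learning_rate, bag_fraction = bag_fraction,
         tree_complexity = tree_complexity, max_trees = max_trees,
         tree_step = tree_step, n_folds = n_folds, family = "bernoulli"),
    class = "brt_config"
  )
}

# Rank-statistic AUC (Mann-Whitney).
auc_rank <- function(labels, scores) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

bernoulli_deviance <- function(y, p) {
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  -2 * sum(y * log(p) + (1 - y) * log(1 - p))
}

default_covariates <- function(table) {
  intersect(setdiff(ENV_LAYER_VOCAB, "ice_concentration"), names(table))
}

xgb_pars <- function(cfg, seed) {
  xgboost::xgb.params(
    objective = "binary:logistic",
    learning_rate = cfg$learning_rate,
    subsample = cfg$bag_fraction,
    max_depth = cfg$tree_complexity,
    eval_metric = "logloss",
    tree_method = "hist",
    nthread = 1,
    seed = seed
  )
}

#' Fit the case-control habitat preference model
#'
#' Individuals are partitioned into `n_folds` groups; per fold, an ensemble
#' is grown to `max_trees` and the held-out Bernoulli deviance recorded per
#' iteration. The tree count minimizing mean held-out deviance over the
#' candidate grid is selected, per-fold held-out AUCs are computed at that
#' count, and the final ensemble is refit on all data.
#'
#' @param table Case-control data frame with `label` (0/1),
#'   `individual_id`, and covariate columns.
#' @param config A [brt_config()].
#' @param seed Integer seed (controls fold assignment and bagging).
#' @param covariates Covariate column names (default: the standard layer
#'   vocabulary minus ice concentration, intersected with `table`).
#' @param n_trees Optional fixed tree count: skips cross-validation and fits
#'   directly (used by colony-blocking refits).
#' @return An object of class `habitat_brt`: the fitted ensemble, selected
#'   tree count, relative importances (percent, summing to 100), per-fold
#'   CV AUC, training deviance explained and pseudo-R-squared, and a
#'   background sample for partial dependence.
#' @export
fit_brt <- function(table, config = brt_config(), seed = 1,
                    covariates = NULL, n_trees = NULL) {
  if (is.null(covariates)) covariates <- default_covariates(table)
  stopifnot(length(covariates) > 0, "label" %in% names(table))
  y <- as.numeric(table$label)
  if (length(unique(y)) < 2) stop("case-control table has a single class")
  x <- as.matrix(table[covariates])
  storage.mode(x) <- "double"

  cv <- NULL
  if (is.null(n_trees)) {
    ids <- unique(table$individual_id)
    k <- config$n_folds
    if (length(ids) < k) {
      warning("fewer individuals than folds; reducing folds to ", length(ids))
      k <- length(ids)
    }
    if (k < 2) stop("need at least 2 individuals for cross-validation")
    set.seed(seed)
    fold_of <- sample(rep_len(seq_len(k), length(ids)))
    names(fold_of) <- ids
    row_fold <- fold_of[as.character(table$individual_id)]

    grid <- seq(config$tree_step, config$max_trees, by = config$tree_step)
    loss <- matrix(NA_real_, k, config$max_trees)
    fold_auc <- numeric(k)
    fold_models <- vector("list", k)
    for (f in seq_len(k)) {
      tr <- row_fold != f
      dtr <- xgboost::xgb.DMatrix(x[tr, , drop = FALSE], label = y[tr])
      dva <- xgboost::xgb.DMatrix(x[!tr, , drop = FALSE], label = y[!tr])
      bst <- xgboost::xgb.train(
        params = xgb_pars(config, seed + f), data = dtr,
        nrounds = config$max_trees, evals = list(valid = dva), verbose = 0
      )
      el <- as.data.frame(attributes(bst)$evaluation_log)
      loss[f, el$iter] <- el$valid_logloss
      fold_models[[f]] <- bst
    }
    mean_loss <- colMeans(loss)
    n_trees <- grid[which.min(mean_loss[grid])]
    for (f in seq_len(k)) {
      va <- row_fold == f
      p <- predict(fold_models[[f]], x[va, , drop = FALSE],
                   iterationrange = c(1, n_trees))
      fold_auc[f] <- auc_rank(y[va], p)
    }
    cv <- list(
      n_folds = k, fold_of = fold_of, grid = grid,
      mean_heldout_deviance = 2 * mean_loss[grid], # per-obs scale x2
      fold_auc = fold_auc,
      auc_mean = mean(fold_auc), auc_sd = stats::sd(fold_auc)
    )
  }

  dall <- xgboost::xgb.DMatrix(x, label = y)
  booster <- xgboost::xgb.train(
    params = xgb_pars(config, seed), data = dall,
    nrounds = n_trees, verbose = 0
  )

  imp_tab <- xgboost::xgb.importance(model = booster)
  imp <- stats::setNames(rep(0, length(covariates)), covariates)
  imp[imp_tab$Feature] <- imp_tab$Gain
  imp <- 100 * imp / sum(imp)

  p_train <- predict(booster, x)
  dev_null <- bernoulli_deviance(y, mean(y))
  dev_res <- bernoulli_deviance(y, p_train)
  set.seed(seed)
  bg <- x[sample(nrow(x), min(2000L, nrow(x))), , drop = FALSE]

  structure(
    list(
      booster = booster, n_trees = n_trees, config = config,
      covariates = covariates, importance = imp, cv = cv,
      pct_deviance_explained = 100 * (1 - dev_res / dev_null),
      r_squared = if (stats::sd(p_train) > 0) stats::cor(y, p_train)^2 else 0,
      train_auc = auc_rank(y, p_train),
      n_obs = nrow(x), n_cases = sum(y == 1),
      background = bg, seed = seed
    ),
    class = "habitat_brt"
  )
}

#' Predict from a fitted habitat preference model
#'
#' @param object A `habitat_brt`.
#' @param newdata Data frame (or matrix) containing the model covariates.
#' @param type `"response"` (probability of relative preference) or
#'   `"link"` (log-odds margin).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.habitat_brt <- function(object, newdata,
                                type = c("response", "link"), ...) {
  type <- match.arg(type)
  x <- as.matrix(as.data.frame(newdata)[object$covariates])
  storage.mode(x) <- "double"
  predict(object$booster, x, outputmargin = (type == "link"))
}

#' @export
print.habitat_brt <- function(x, ...) {
  cat("Boosted regression tree habitat preference model\n")
  cat(sprintf("  %d trees (lr %.3g, bag %.2g, depth %d), %d rows (%d cases)\n",
              x$n_trees, x$config$learning_rate, x$config$bag_fraction,
              x$config$tree_complexity, x$n_obs, x$n_cases))
  if (!is.null(x$cv)) {
    cat(sprintf("  CV AUC %.3f +/- %.3f (%d folds by individual)\n",
                x$cv$auc_mean, x$cv$auc_sd, x$cv$n_folds))
  }
  cat(sprintf("  deviance explained %.1f%%, R2 %.3f\n",
              x$pct_deviance_explained, x$r_squared))
  invisible(x)
}

#' @export
summary.habitat_brt <- function(object, ...) {
  imp <- sort(object$importance, decreasing = TRUE)
  out <- list(metrics = evaluate_model(object), importance = imp)
  class(out) <- "summary.habitat_brt"
  out
}

#' @export
print.summary.habitat_brt <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "trees %d | deviance explained %.1f%% | R2 %.3f | CV AUC %.3f +/- %.3f\n",
    m$n_trees, m$pct_deviance_explained, m$r_squared,
    m$cv_auc_mean, m$cv_auc_sd
  ))
  cat("relative importance (%):\n")
  for (nm in names(x$importance)) {
    cat(sprintf("  %-22s %6.1f\n", nm, x$importance[nm]))
  }
  invisible(x)
}

#' Model performance metrics
#'
#' Deviance explained `= 100 (1 - residual/null Bernoulli deviance)`,
#' pseudo-R-squared (squared Pearson correlation between label and fitted
#' probability), and cross-validated AUC (rank statistic on held-out
#' folds).
#'
#' @param fit A `habitat_brt`.
#' @param table Optional table to recompute training-scale metrics on
#'   (defaults to the metrics stored at fit time).
#' @return A one-row data frame: `n_trees`, `pct_deviance_explained`,
#'   `r_squared`, `cv_auc_mean`, `cv_auc_sd`.
#' @export
evaluate_model <- function(fit, table = NULL) {
  stopifnot(inherits(fit, "habitat_brt"))
  dev <- fit$pct_deviance_explained
  r2 <- fit$r_squared
  if (!is.null(table)) {
    y <- as.numeric(table$label)
    p <- predict(fit, table)
    dev <- 100 * (1 - bernoulli_deviance(y, p) / bernoulli_deviance(y, mean(y)))
    r2 <- if (stats::sd(p) > 0) stats::cor(y, p)^2 else 0
  }
  data.frame(
    n_trees = fit$n_trees,
    pct_deviance_explained = dev,
    r_squared = r2,
    cv_auc_mean = if (!is.null(fit$cv)) fit$cv$auc_mean else NA_real_,
    cv_auc_sd = if (!is.null(fit$cv)) fit$cv$auc_sd else NA_real_
  )
}

#' Colony-level blocking validation
#'
#' For each colony the model is refit with that colony held out, held-out
#' predictions are thresholded at 0.5 (the case-control prevalence is fixed
#' by design, so the threshold is reported, not optimized), and a 2x2
#' confusion matrix with sensitivity/specificity/accuracy is returned.
#'
#' @param table Case-control table with a `colony_id` column.
#' @param config A [brt_config()].
#' @param seed Integer seed.
#' @param covariates Covariate columns (default as in [fit_brt()]).
#' @param n_trees Fixed tree count for the refits (default: one shared CV
#'   selection on the full table).
#' @param threshold Classification threshold (default 0.5).
#' @return List per colony: `confusion` (2x2 matrix, predicted x observed),
#'   `sensitivity`, `specificity`, `accuracy`, `n`, `single_class` flag.
#' @export
blocking_validation <- function(table, config = brt_config(), seed = 1,
                                covariates = NULL, n_trees = NULL,
                                threshold = 0.5) {
  colonies <- unique(table$colony_id)
  if (length(colonies) < 2) stop("blocking validation needs >= 2 colonies")
  if (is.null(covariates)) covariates <- default_covariates(table)
  if (is.null(n_trees)) {
    n_trees <- fit_brt(table, config, seed, covariates)$n_trees
  }
  out <- lapply(colonies, function(col) {
    train <- table[table$colony_id != col, ]
    test <- table[table$colony_id == col, ]
    fit <- fit_brt(train, config, seed, covariates, n_trees = n_trees)
    p <- predict(fit, test)
    pred <- as.integer(p >= threshold)
    obs <- as.integer(test$label)
    cm <- matrix(c(
      sum(pred == 1 & obs == 1), sum(pred == 1 & obs == 0),
      sum(pred == 0 & obs == 1), sum(pred == 0 & obs == 0)
    ), 2, 2, byrow = TRUE,
    dimnames = list(predicted = c("1", "0"), observed = c("1", "0")))
    single <- length(unique(obs)) < 2
    list(
      colony = col, confusion = cm, n = nrow(test),
      sensitivity = cm[1, 1] / sum(obs == 1),
      specificity = cm[2, 2] / sum(obs == 0),
      accuracy = (cm[1, 1] + cm[2, 2]) / nrow(test),
      auc = auc_rank(obs, p),
      single_class = single
    )
  })
  names(out) <- colonies
  out
}

#' Partial-dependence response curve
#'
#' Standard partial dependence on the link (log-odds) scale: the variable is
#' clamped to each grid value across a background sample of the training
#' data, predictions are averaged, and the curve is centered to mean zero.
#'
#' @param fit A `habitat_brt`.
#' @param variable Covariate name.
#' @param grid Values at which to evaluate (default: 41 points spanning the
#'   background range of the variable).
#' @return Data frame `value`, `effect` (centered log-odds), of class
#'   `partial_dependence`.
#' @export
partial_dependence <- function(fit, variable, grid = NULL) {
  stopifnot(inherits(fit, "habitat_brt"))
  if (!variable %in% fit$covariates) {
    stop("variable '", variable, "' is not in the model")
  }
  bg <- fit$background
  if (is.null(grid)) {
    r <- range(bg[, variable])
    grid <- seq(r[1], r[2], length.out = 41)
  }
  eff <- vapply(grid, function(v) {
    bg[, variable] <- v
    mean(predict(fit$booster, bg, outputmargin = TRUE))
  }, numeric(1))
  out <- data.frame(value = grid, effect = eff - mean(eff))
  class(out) <- c("partial_dependence", "data.frame")
  out
}

#' Plot partial-dependence curves
#'
#' @param x A `habitat_brt`.
#' @param variables Covariates to plot (default: the four most important).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.habitat_brt <- function(x, variables = NULL, ...) {
  if (is.null(variables)) {
    variables <- names(sort(x$importance, decreasing = TRUE))
    variables <- utils::head(variables, 4)
  }
  old <- graphics::par(mfrow = c(ceiling(length(variables) / 2),
                                 min(2, length(variables))))
  on.exit(graphics::par(old))
  for (v in variables) {
    pd <- partial_dependence(x, v)
    graphics::plot(pd$value, pd$effect, type = "l",
                   xlab = v, ylab = "fitted effect (log-odds)", ...)
    graphics::abline(h = 0, lty = 3)
  }
  invisible(x)
}
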