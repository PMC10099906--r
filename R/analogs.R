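# Climate-analogue projection: normalize covariates to 0-1 on a scale
# pooled over current and future periods, reduce to the fewest principal
# components explaining >= 95% of current-period variance, then classify
# each future cell by the majority preferred/not-preferred label of its
# k = 5 nearest current cells (Euclidean distance in PC + accessibility
# space), and combine projections across climate representations.

# Cell-value matrix (n_sea_cells x n_vars) from a climatology stack,
# dropping the ice constraint layer and masked cells.
stack_cell_matrix <- function(stack, vars = NULL) {
  stopifnot(inherits(stack, "env_stack"), is.null(stack$dates))
  if (is.null(vars)) {
    vars <- setdiff(names(stack$layers), "ice_concentration")
  }
  x <- vapply(vars, function(nm) as.vector(stack$layers[[nm]]),
              numeric(length(stack$lat) * length(stack$lon)))
  colnames(x) <- vars
  x
}

#' Normalize variables to 0-1 on a pooled scale
#'
#' Per variable, `x' = (x - min) / (max - min)` with the min/max pooled over
#' the current and future matrices so the two periods share one scale.
#' Constant variables cannot be scaled and are dropped with a warning.
#'
#' @param current,future Numeric matrices with identical column names
#'   (cells x variables); `future` may be `NULL`.
#' @return List `current`, `future` (normalized matrices) and `scaling`
#'   (data frame of the min/max used per variable, the audit record).
#' @export
normalize_variables <- function(current, future = NULL) {
  stopifnot(is.matrix(current))
  if (!is.null(future)) stopifnot(identical(colnames(current), colnames(future)))
  pooled <- if (is.null(future)) current else rbind(current, future)
  mins <- apply(pooled, 2, min, na.rm = TRUE)
  maxs <- apply(pooled, 2, max, na.rm = TRUE)
  const <- !is.finite(mins) | !is.finite(maxs) | (maxs - mins) <= 0
  if (any(const)) {
    warning("dropping constant variable(s): ",
            paste(colnames(current)[const], collapse = ", "))
  }
  keep <- which(!const)
  if (length(keep) == 0) stop("no scalable variables remain")
  scale1 <- function(m) {
    sweep(sweep(m[, keep, drop = FALSE], 2, mins[keep]), 2,
          (maxs - mins)[keep], "/")
  }
  list(
    current = scale1(current),
    future = if (is.null(future)) NULL else scale1(future),
    scaling = data.frame(variable = colnames(current)[keep],
                         min = mins[keep], max = maxs[keep],
                         row.names = NULL)
  )
}

#' Reduce normalized variables to principal components
#'
#' PCA is fitted on the current-period cells (centered, already on a common
#' 0-1 scale); the retained dimensionality is the smallest number of
#' components whose cumulative explained variance reaches `threshold`.
#' Future cells are projected with the same loadings — the embedding never
#' sees the future shift.
#'
#' @param current,future Normalized matrices from [normalize_variables()].
#' @param threshold Cumulative variance fraction to retain (default 0.95).
#' @return List `current`, `future` (score matrices), `n_components`,
#'   `variance_explained` (cumulative, retained), `rotation`, `center`.
#' @export
reduce_dimensions <- function(current, future = NULL, threshold = 0.95) {
  ok <- stats::complete.cases(current)
  if (sum(ok) < ncol(current)) stop("fewer complete cells than variables")
  pc <- stats::prcomp(current[ok, , drop = FALSE], center = TRUE,
                      scale. = FALSE)
  cumvar <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  m <- which(cumvar >= threshold)[1]
  if (is.na(m)) m <- length(cumvar)
  project <- function(x) {
    sc <- matrix(NA_real_, nrow(x), m)
    okx <- stats::complete.cases(x)
    sc[okx, ] <- sweep(x[okx, , drop = FALSE], 2, pc$center) %*%
      pc$rotation[, seq_len(m), drop = FALSE]
    sc
  }
  list(
    current = project(current),
    future = if (is.null(future)) NULL else project(future),
    n_components = m,
    variance_explained = cumvar[m],
    rotation = pc$rotation[, seq_len(m), drop = FALSE],
    center = pc$center
  )
}

#' k-nearest-neighbour analogue classification
#'
#' Each future cell takes the majority preferred/not-preferred label of its
#' `k` nearest current-period cells under Euclidean distance in principal
#' component space, with accessibility (scaled 0-1) appended as one extra
#' feature dimension. Distance ties are broken by lowest current-cell
#' index; with odd `k` the vote cannot tie.
#'
#' @param current_scores Matrix of current-cell PC scores (rows with `NA`
#'   are excluded from the reference set).
#' @param current_labels Binary vector (1 = preferred) from the
#'   top-percentile mask, aligned with `current_scores` rows.
#' @param future_scores Matrix of future-cell PC scores.
#' @param current_access,future_access Optional accessibility in `[0, 1]`
#'   per cell, appended as a feature.
#' @param k Number of neighbours (default 5, odd).
#' @return Integer vector of future-cell labels (`NA` where the future cell
#'   has no scores).
#' @export
knn_analog_classify <- function(current_scores, current_labels,
                                future_scores, current_access = NULL,
                                future_access = NULL, k = 5) {
  cur <- as.matrix(current_scores)
  fut <- as.matrix(future_scores)
  if (!is.null(current_access)) {
    cur <- cbind(cur, current_access)
    fut <- cbind(fut, future_access)
  }
  ok_cur <- stats::complete.cases(cur) & !is.na(current_labels)
  ref <- cur[ok_cur, , drop = FALSE]
  lab <- current_labels[ok_cur]
  if (k > nrow(ref)) stop("k exceeds the number of labelled current cells")
  ok_fut <- stats::complete.cases(fut)
  out <- rep(NA_integer_, nrow(fut))
  if (!any(ok_fut)) return(out)
  q <- fut[ok_fut, , drop = FALSE]
  # squared Euclidean distances via the expansion |a-b|^2 = |a|^2+|b|^2-2ab
  d2 <- outer(rowSums(q^2), rowSums(ref^2), "+") - 2 * tcrossprod(q, ref)
  votes <- apply(d2, 1, function(dr) {
    nn <- order(dr, seq_along(dr))[seq_len(k)] # ties: lowest cell index
    as.integer(sum(lab[nn]) * 2 > k)
  })
  out[ok_fut] <- votes
  out
}

#' Project one climate representation
#'
#' Runs the full normalize / PCA / k-NN chain for a single climate
#' representation: shared 0-1 scaling pooled over periods, PCA on the
#' current period, and majority-of-5 analogue classification of every
#' future cell against the current preferred-habitat labels.
#'
#' @param rep A `climate_representation` (with `current` and `future`
#'   climatology stacks).
#' @param current_mask Binary preferred-habitat `hab_surface` (from
#'   [top_percentile_mask()]) on the current climate.
#' @param access Optional accessibility `hab_surface` in `[0, 1]`.
#' @param k Neighbours (default 5).
#' @param threshold PCA variance threshold (default 0.95).
#' @return An `analogue_projection`: binary `layer` (`hab_surface`),
#'   `name`, `scenario`, `k`, `n_components`, `variance_explained`.
#' @export
project_representation <- function(rep, current_mask, access = NULL,
                                   k = 5, threshold = 0.95) {
  cur_x <- stack_cell_matrix(rep$current)
  fut_x <- stack_cell_matrix(rep$future)
  suppressWarnings(norm <- normalize_variables(cur_x, fut_x))
  red <- reduce_dimensions(norm$current, norm$future, threshold)
  acc_cur <- acc_fut <- NULL
  if (!is.null(access)) {
    acc_cur <- as.vector(access$values)
    acc_fut <- acc_cur # accessibility is a static colony-distance property
  }
  labels <- as.vector(current_mask$values)
  cls <- knn_analog_classify(red$current, labels, red$future,
                             acc_cur, acc_fut, k = k)
  vals <- matrix(as.numeric(cls), length(current_mask$lat),
                 length(current_mask$lon))
  vals[is.na(current_mask$values)] <- NA_real_
  structure(
    list(
      name = rep$name, scenario = rep$scenario,
      layer = hab_surface(current_mask$lon, current_mask$lat, vals,
                          taxon = current_mask$taxon,
                          type = "preferred_habitat_like"),
      k = k, n_components = red$n_components,
      variance_explained = red$variance_explained
    ),
    class = "analogue_projection"
  )
}

#' @export
print.analogue_projection <- function(x, ...) {
  v <- x$layer$values
  cat(sprintf(
    "<analogue_projection> %s/%s: %d of %d cells preferred-like (k=%d, %d PCs, %.1f%% var)\n",
    x$name, x$scenario, sum(v == 1, na.rm = TRUE), sum(!is.na(v)),
    x$k, x$n_components, 100 * x$variance_explained
  ))
  invisible(x)
}

#' Combine analogue projections across climate representations
#'
#' Per cell, counts the representations classifying it preferred-like; the
#' cell is future-preferred when the count exceeds half the representations
#' (simple majority). Cells are then categorized against the current mask:
#' retained (1 -> 1), gained (0 -> 1), lost (1 -> 0), never (0 -> 0).
#'
#' @param projections List of `analogue_projection`s sharing grid and
#'   scenario.
#' @param current_mask Binary current preferred-habitat `hab_surface`.
#' @return List with `agreement` (`hab_surface` of counts), `future_mask`
#'   (majority binary `hab_surface`), `category` (`hab_surface` coded
#'   0 never / 1 lost / 2 gained / 3 retained), `n_reps`, `scenario`.
#' @export
ensemble_combine <- function(projections, current_mask) {
  stopifnot(length(projections) >= 1)
  scen <- unique(vapply(projections, function(p) p$scenario, character(1)))
  if (length(scen) != 1) stop("projections mix scenarios: ",
                              paste(scen, collapse = ", "))
  layers <- lapply(projections, function(p) p$layer$values)
  agree <- Reduce(`+`, layers)
  n <- length(layers)
  fut <- ifelse(is.na(agree), NA_real_, as.numeric(agree > n / 2))
  cur <- current_mask$values
  cat_code <- ifelse(is.na(cur) | is.na(fut), NA_real_,
                     ifelse(cur == 1 & fut == 1, 3,
                            ifelse(cur == 0 & fut == 1, 2,
                                   ifelse(cur == 1 & fut == 0, 1, 0))))
  g <- current_mask
  list(
    agreement = hab_surface(g$lon, g$lat, agree, g$taxon, "agreement_count"),
    future_mask = hab_surface(g$lon, g$lat, fut, g$taxon, "future_preferred"),
    category = hab_surface(g$lon, g$lat, cat_code, g$taxon,
                           "change_category"),
    n_reps = n, scenario = scen
  )
}
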