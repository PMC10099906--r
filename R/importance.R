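# Ocean-wide prediction from climatologies and the percentile transform to
# a 0-100 habitat importance score, comparable across taxa.

#' Predict a preference surface from a climatology
#'
#' Evaluates the fitted habitat model in every non-masked grid cell of a
#' climatology stack and (optionally) multiplies in colony accessibility.
#'
#' @param fit A `habitat_brt`.
#' @param clim Climatology [env_stack()] containing every model covariate.
#' @param curves Optional named list of `access_curve`s (with `colonies`)
#'   to combine with, via [combine_preference_accessibility()].
#' @param colonies Colony data frame (required with `curves`).
#' @param weights Aggregation mode passed through to the combiner.
#' @return A preference `hab_surface`; masked cells stay missing.
#' @export
predict_surface <- function(fit, clim, curves = NULL, colonies = NULL,
                            weights = NULL) {
  stopifnot(inherits(fit, "habitat_brt"), inherits(clim, "env_stack"),
            is.null(clim$dates))
  missing_cov <- setdiff(fit$covariates, names(clim$layers))
  if (length(missing_cov) > 0) {
    stop("climatology lacks model covariate(s): ",
         paste(missing_cov, collapse = ", "))
  }
  nlat <- length(clim$lat); nlon <- length(clim$lon)
  x <- vapply(fit$covariates, function(nm) as.vector(clim$layers[[nm]]),
              numeric(nlat * nlon))
  ok <- stats::complete.cases(x)
  vals <- rep(NA_real_, nlat * nlon)
  if (any(ok)) {
    xm <- x[ok, , drop = FALSE]
    storage.mode(xm) <- "double"
    vals[ok] <- predict(fit$booster, xm)
  }
  v <- matrix(vals, nlat, nlon)
  if (!is.null(clim$land_mask)) v[clim$land_mask] <- NA_real_
  ice <- clim$layers$ice_concentration
  if (!is.null(ice)) v[ice > 80] <- NA_real_
  out <- hab_surface(clim$lon, clim$lat, v, type = "preference")
  if (!is.null(curves)) {
    if (is.null(colonies)) stop("curves supplied without colonies")
    out <- combine_preference_accessibility(out, curves, colonies, weights)
  }
  out
}

#' Percentile transform to a habitat importance score
#'
#' `score(cell) = 100 * rank(value, ties = mean) / n_non_missing`: an
#' order-preserving map onto 0-100 whose empirical distribution is uniform
#' up to ties, making maps comparable between taxa.
#'
#' @param s A preference `hab_surface`.
#' @return An importance `hab_surface` with scores in `(0, 100]`.
#' @export
percentile_transform <- function(s) {
  stopifnot(inherits(s, "hab_surface"))
  v <- as.vector(s$values)
  ok <- !is.na(v)
  if (!any(ok)) stop("surface has no non-missing cells")
  sc <- rep(NA_real_, length(v))
  sc[ok] <- 100 * rank(v[ok], ties.method = "average") / sum(ok)
  hab_surface(s$lon, s$lat, matrix(sc, length(s$lat), length(s$lon)),
              taxon = s$taxon, type = "importance")
}

#' Top-percentile preferred-habitat mask
#'
#' Binary mask of cells whose importance score exceeds `q`; with distinct
#' values this selects `(100 - q)%` of the non-missing cells (exact up to
#' ties).
#'
#' @param imp An importance `hab_surface` from [percentile_transform()].
#' @param q Percentile threshold in `[0, 100)`; default 90 (the top
#'   decile). `q = 0` selects every non-missing cell.
#' @return A binary `hab_surface` (1 = preferred, 0 = not, NA = masked).
#' @export
top_percentile_mask <- function(imp, q = 90) {
  stopifnot(inherits(imp, "hab_surface"), q >= 0, q < 100)
  m <- ifelse(is.na(imp$values), NA_real_,
              as.numeric(imp$values > q))
  hab_surface(imp$lon, imp$lat, m, taxon = imp$taxon, type = "preferred_mask")
}
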