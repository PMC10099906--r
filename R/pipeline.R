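# End-to-end orchestrator over the synthetic world: tracks -> nulls ->
# covariates -> preference model -> accessibility -> importance map ->
# analogue projection -> regional change. One seed controls every stage;
# outputs are plain-text CSV/JSON so repeated runs are byte-comparable.

#' Jaccard overlap of two binary masks
#'
#' @param a,b Binary `hab_surface` masks on one grid.
#' @return `|a & b| / |a | b|` over cells non-missing in both.
#' @export
jaccard_overlap <- function(a, b) {
  va <- as.vector(a$values); vb <- as.vector(b$values)
  ok <- !is.na(va) & !is.na(vb)
  inter <- sum(va[ok] == 1 & vb[ok] == 1)
  uni <- sum(va[ok] == 1 | vb[ok] == 1)
  if (uni == 0) return(NA_real_)
  inter / uni
}

#' Area-weighted centroid latitude of a binary mask
#'
#' @param mask Binary `hab_surface`.
#' @return Latitude of the mask's area-weighted centroid, degrees.
#' @export
mask_centroid_lat <- function(mask) {
  latm <- matrix(mask$lat, length(mask$lat), length(mask$lon))
  w <- grid_cell_areas(mask)
  sel <- !is.na(mask$values) & mask$values == 1
  if (!any(sel)) return(NA_real_)
  sum(latm[sel] * w[sel]) / sum(w[sel])
}

#' Accessibility surface over a grid
#'
#' Cell-wise maximum (or population-weighted mean) of the per-colony
#' accessibility curves evaluated at cell-to-colony great-circle distance.
#'
#' @param curves Named list of `access_curve`s per colony id.
#' @param colonies Colony data frame.
#' @param grid List with `lon`/`lat` cell centers.
#' @param weights As in [combine_preference_accessibility()].
#' @return A `hab_surface` of accessibility in `[0, 1]`.
#' @export
access_surface <- function(curves, colonies, grid, weights = NULL) {
  ones <- hab_surface(grid$lon, grid$lat,
                      matrix(1, length(grid$lat), length(grid$lon)),
                      type = "ones")
  out <- combine_preference_accessibility(ones, curves, colonies, weights)
  out$type <- "accessibility"
  out
}

#' Run the full pipeline on a synthetic world
#'
#' Generates the world, simulates tracks, builds the constrained null-track
#' background (50 per track by default), assembles the case-control table,
#' fits the boosted-tree preference model with individual-blocked
#' cross-validation, fits per-colony monotone accessibility curves,
#' predicts and percentile-transforms the importance map, projects the
#' preferred-habitat mask onto every pseudo climate representation via
#' k-nearest-neighbour analogues, combines them by majority, and summarizes
#' regional percent area change. Every random draw derives from `seed`.
#'
#' @param config A [world_config()].
#' @param brt A [brt_config()].
#' @param seed Master seed (overrides `config$seed`).
#' @param n_null Null tracks per observed track (default 50).
#' @param q Preferred-habitat percentile threshold (default 90).
#' @param k Analogue neighbours (default 5).
#' @param use_access Combine preference with accessibility and feed the
#'   accessibility feature to the analogue matcher.
#' @param out_dir Optional directory for CSV/JSON outputs.
#' @return A list with every intermediate product plus `metrics`
#'   (Table-style model statistics), `records` / `summary` (regional
#'   change), `jaccard_truth`, and `poleward_shift_deg` (positive =
#'   predicted future habitat moved poleward).
#' @export
run_pipeline <- function(config = world_config(), brt = brt_config(),
                         seed = config$seed, n_null = 50, q = 90, k = 5,
                         use_access = TRUE, out_dir = NULL) {
  config$seed <- seed
  world <- make_world(config)
  tracks <- simulate_tracks(world, seed = seed + 1)
  constraints <- constraints_from_world(world)
  summaries <- lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    colony <- world$colonies[world$colonies$colony_id == tr$colony_id[1], ]
    movement_summary(tr, colony$lon, colony$lat)
  })
  nulls <- lapply(seq_along(tracks), function(i) {
    simulate_null_tracks(tracks[[i]], summaries[[i]], constraints,
                         n = n_null, seed = seed + 100 + i)
  })
  table <- build_case_control(tracks, nulls, world$current)
  fit <- fit_brt(table, brt, seed = seed + 2)
  metrics <- evaluate_model(fit)

  sea_mask <- !(world$land_mask | world$ice_mask)
  curves <- list()
  for (ci in seq_len(nrow(world$colonies))) {
    colony <- world$colonies[ci, ]
    sel <- vapply(tracks, function(tr) tr$colony_id[1] == colony$colony_id,
                  logical(1))
    fixes <- do.call(rbind, c(
      lapply(tracks[sel], function(tr) as.data.frame(tr)[c("lon", "lat")]),
      lapply(unlist(nulls[sel], recursive = FALSE),
             function(tr) as.data.frame(tr)[c("lon", "lat")])
    ))
    resp <- build_access_response(fixes, world$truth, colony$lon, colony$lat,
                                  sea_mask = sea_mask)
    curves[[as.character(colony$colony_id)]] <-
      fit_accessibility(resp, colony_id = as.character(colony$colony_id))
  }

  pref <- predict_surface(fit, world$clim,
                          curves = if (use_access) curves else NULL,
                          colonies = if (use_access) world$colonies else NULL)
  importance <- percentile_transform(pref)
  current_mask <- top_percentile_mask(importance, q = q)

  future <- make_future_climate(world, q = q, seed = seed + 3)
  acc_surf <- if (use_access) {
    access_surface(curves, world$colonies, world$truth)
  } else NULL
  projections <- lapply(future$reps, function(rp) {
    project_representation(rp, current_mask, access = acc_surf, k = k)
  })
  combined <- ensemble_combine(projections, current_mask)

  labels <- assign_regions(world$truth)
  records <- do.call(rbind, lapply(projections, function(p) {
    percent_area_change(current_mask, p$layer, labels,
                        taxon = "synthetic_eudyptes",
                        representation = p$name, scenario = p$scenario)
  }))
  summary_tab <- summarize_ensemble(records)

  jac <- jaccard_overlap(combined$future_mask, future$truth_future)
  shift <- mask_centroid_lat(current_mask) -
    mask_centroid_lat(combined$future_mask)

  out <- list(
    world = world, tracks = tracks, nulls = nulls, table = table,
    fit = fit, metrics = metrics, curves = curves, pref = pref,
    importance = importance, current_mask = current_mask,
    future = future, projections = projections, combined = combined,
    labels = labels, records = records, summary = summary_tab,
    jaccard_truth = jac, poleward_shift_deg = shift
  )
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

# Writes the pipeline's CSV/JSON artifacts; file set and formats are fixed
# so two runs with one seed are byte-identical.
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(out_dir, x)
  write_tracks_csv(res$tracks, fp("tracks_observed.csv"))
  write_tracks_csv(unlist(res$nulls, recursive = FALSE),
                   fp("tracks_null.csv"))
  utils::write.csv(res$metrics, fp("model_metrics.csv"), row.names = FALSE)
  imp <- data.frame(variable = names(res$fit$importance),
                    importance_pct = as.numeric(res$fit$importance))
  utils::write.csv(imp, fp("variable_importance.csv"), row.names = FALSE)
  write_access_csv(res$curves, fp("access_curves.csv"))
  write_grid_csv(res$importance, fp("importance_surface.csv"))
  write_grid_csv(res$current_mask, fp("current_mask.csv"))
  write_grid_csv(res$combined$future_mask, fp("future_mask.csv"))
  write_grid_csv(res$combined$category, fp("change_category.csv"))
  utils::write.csv(res$records, fp("regional_change.csv"), row.names = FALSE)
  utils::write.csv(res$summary, fp("regional_summary.csv"),
                   row.names = FALSE)
  write_extraction_report(res$table, fp("extraction_report.json"))
  invisible(out_dir)
}
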