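# habshift

Habitat preference and climate-driven habitat redistribution for
central-place marine predators, built around the post-moult migration of
crested (*Eudyptes*) penguins in the Southern Ocean.

Penguin tracking tells us where birds went; it does not tell us which ocean
conditions they *preferred*, nor where those conditions will be at the end
of the century. `habshift` implements the full inferential chain:

1. **Availability (case-control) design.** Observed tracks (label 1) are
   contrasted with 50 simulated "null" tracks each (label 0) that keep the
   observed dates, trip duration, speeds, turning-angle structure and
   maximum colony range but move with random headings, constrained to sea,
   south of 30°S, north of the >80% sea-ice edge.
2. **Preference model.** Boosted regression trees on the binary response
   (Bernoulli loss; learning rate 0.01, bag fraction 0.5, tree complexity
   5), tree count selected by k-fold cross-validation blocked on
   individual. Outputs are relative preference, variable importances,
   partial-dependence response curves and colony-level blocking
   validations.
3. **Accessibility.** P(cell visited | distance to colony) fitted under a
   monotone-decreasing constraint (binned isotonic regression + monotone
   spline) and multiplied into the preference surface.
4. **Importance maps.** Predictions on April–September climatologies,
   percentile-transformed to a 0–100 habitat importance score comparable
   across taxa; "preferred habitat" is the top decile.
5. **Climate-analogue projection.** Covariates normalized 0–1 on a scale
   pooled over periods, PCA to ≥95% variance (fitted on the current period
   only), and each future-climate cell classified by the majority
   preferred/not-preferred label of its 5 nearest current-climate cells
   (Euclidean distance, accessibility appended as a feature). Projections
   from multiple climate representations are combined by majority into
   retained / gained / lost habitat.
6. **Regional change.** Geodesic habitat area per MEASO-style sector
   (Atlantic, Central Indian, East Indian, West Pacific, East Pacific) and
   percent change per representation and scenario, with quartile summaries.

Because the motivating study's tracking archives and climate fields cannot
ship with a package, `habshift` includes a synthetic world generator
(`make_world()`) with zonally banded SST/SSH fields, colonies on sub-grid
islands, habitat-biased correlated-random-walk tracks, and a closed-form
ground-truth preference (Gaussian in SST and SSH), so the entire pipeline
is testable against known answers.

## Worked example

```r
library(habshift)
res <- run_pipeline(
  config = world_config(n_individuals = 20, duration_days = 30, n_reps = 4),
  brt = brt_config(max_trees = 500, n_folds = 5),
  seed = 1, n_null = 20
)
print(res$fit)
#> Boosted regression tree habitat preference model
#>   200 trees (lr 0.01, bag 0.5, depth 5), 25620 rows (1220 cases)
#>   CV AUC 0.797 +/- 0.050 (5 folds by individual)
#>   deviance explained 24.9%, R2 0.168
summary(res$fit)
#> trees 200 | deviance explained 24.9% | R2 0.168 | CV AUC 0.797 +/- 0.050
#> relative importance (%):
#>   sst                      44.0
#>   mixed_layer_depth        18.9
#>   sea_surface_height       11.3
#>   ssh_anomaly               9.4
#>   ...
res$summary
#>                taxon   region  scenario n  min  q25 median  q75  max
#> 1 synthetic_eudyptes Atlantic synthetic 4 2.65 2.65   5.88 9.12 9.12
```

The model recovers the generator's engineered structure: SST (whose true
optimum is 5 °C) ranks first in importance, and the cross-validated AUC
approaches the 0.8+ range once the study runs at full size (50 individuals,
45-day trips, 50 nulls each — the demo above is deliberately small). The
regional table gives percent change in preferred-habitat area across the
pseudo climate representations.

Useful entry points: `regularize_track()`, `movement_summary()`,
`simulate_null_tracks()`, `extract_covariates()`, `build_climatology()`,
`fit_brt()` (with `predict`/`summary`/`plot`/`partial_dependence()`),
`fit_accessibility()`, `predict_surface()`, `percentile_transform()`,
`top_percentile_mask()`, `project_representation()`, `ensemble_combine()`,
`assign_regions()`, `percent_area_change()`, `summarize_ensemble()`, and
the `run_pipeline()` orchestrator. The methods vignette
(`vignettes/habitat-preference-redistribution.Rmd`) documents the models,
assumptions and design choices.

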