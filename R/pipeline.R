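#' Run a complete virtual warming study end-to-end
#'
#' Chains the whole pipeline on simulated data with known ground truth:
#' simulate a species pool, warming landscape and community time-series;
#' estimate thermal profiles from simulated occurrence records (or take the
#' true ones); apply the inclusion filters; standardise sampling effort by
#' rarefaction; fit per-site thermophilisation rates; assemble driver
#' predictors; compute fate contrasts; and fit the driver model.
#'
#' @param scenario A [simulation_scenario()].
#' @param seed Base RNG seed (defaults to the scenario's).
#' @param config An [analysis_config()].
#' @param estimate_profiles Estimate STIs from simulated occurrences
#'   (`TRUE`, the full pipeline) or use the pool's true values (`FALSE`,
#'   isolates the community-level machinery).
#' @param n_occ_records Occurrence records per species when estimating.
#' @param spatial Spatial structure for the driver model (`"gauss"` or
#'   `"none"`).
#' @param fit_driver Fit the driver model (the slowest step)?
#' @return List: `scenario`, `pool`, `grid`, `sites`, `observations` (after
#'   filtering), `filter_report`, `profiles`, `prepped` (rarefied series),
#'   `rates`, `predictors`, `fates`, and `driver` (a `model_fit`, when
#'   requested).
#' @export
run_warming_study <- function(scenario = simulation_scenario(),
                              seed = scenario$rng_seed,
                              config = analysis_config(),
                              estimate_profiles = TRUE,
                              n_occ_records = 200,
                              spatial = "gauss",
                              fit_driver = TRUE) {
  sim <- simulate_dataset(scenario, seed = seed,
                          occurrences = estimate_profiles,
                          n_occ_records = n_occ_records)
  profiles <- if (estimate_profiles) {
    occ <- clean_occurrences(sim$occurrences)
    build_thermal_profiles(occ, sim$grid,
                           min_records = config$min_sti_records)
  } else true_profiles(sim$pool)
  filt <- filter_communities(sim$observations, profiles, config)
  prepped <- rarefy_timeseries(filt$observations, profiles, config,
                               seed = seed + 10L)
  meta_cols <- c("site_id", "study_id", "taxon_group", "realm",
                 "latitude", "longitude", "baseline_temp", "true_warming")
  rates <- site_rates(prepped, site_info = sim$sites[meta_cols])
  traits <- data.frame(species = sim$pool$species,
                       body_size_m = sim$pool$body_size_m,
                       stringsAsFactors = FALSE)
  predictors <- suppressWarnings(
    assemble_predictors(rates, sim$grid, profiles, traits,
                        filt$observations))
  fates <- fate_contrast_table(filt$observations, profiles)
  out <- list(scenario = scenario, pool = sim$pool, grid = sim$grid,
              sites = sim$sites, observations = filt$observations,
              filter_report = filt$report, profiles = profiles,
              prepped = prepped, rates = rates, predictors = predictors,
              fates = fates)
  if (fit_driver && nrow(predictors) > 0L)
    out$driver <- driver_model(predictors, scope = "realm",
                               spatial = spatial, config = config)
  out
}
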