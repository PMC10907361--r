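# Shared in-code fixtures: tiny grids, profile tables and observation
# builders used across the module tests.

# grid from a bio01 matrix; bio10/bio11 at +/- amplitude unless supplied
make_grid <- function(bio01, origin_lat = 10, origin_lon = 0, cell_size = 1,
                      amplitude = 8, annual = NULL) {
  layers <- list(bio01 = bio01, bio10 = bio01 + amplitude,
                 bio11 = bio01 - amplitude)
  if (!is.null(annual))
    for (y in names(annual)) layers[[paste0("annual_", y)]] <- annual[[y]]
  temperature_grid(origin_lat, origin_lon, cell_size, layers)
}

# profiles table from named STI (and optional breadth) vectors
make_profiles <- function(sti, breadth = NULL) {
  data.frame(species = names(sti), sti = as.numeric(sti),
             niche_breadth = if (is.null(breadth)) NA_real_
             else as.numeric(breadth[names(sti)]),
             n_records = 10L, provenance = "species",
             stringsAsFactors = FALSE)
}

# long-format observation rows for one site
make_obs <- function(site_id, year, species, sample_id = "s1",
                     study_id = "st1", taxon_group = "plants",
                     realm = "terrestrial", latitude = 9.5, longitude = 0.5,
                     abundance = NA_real_) {
  data.frame(site_id = site_id, study_id = study_id,
             taxon_group = taxon_group, realm = realm,
             latitude = latitude, longitude = longitude,
             year = as.integer(year), sample_id = sample_id,
             species = species, abundance = abundance,
             stringsAsFactors = FALSE)
}

# small, fast scenario for simulation-backed tests
fast_scenario <- function(...) {
  args <- list(n_sites = 40, n_species = 60, years = 2000:2011,
               grid_nrow = 20, grid_ncol = 20)
  do.call(simulation_scenario, utils::modifyList(args, list(...)))
}

# exact binomial upper tail by direct enumeration (independent oracle)
enum_binom_upper <- function(k, n) sum(choose(n, k:n)) / 2^n
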