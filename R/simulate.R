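#' Generate a virtual species pool with known thermal traits
#'
#' Each virtual species carries a true species temperature index (STI, degC),
#' a true thermal niche breadth (degC) and a body size (m). STIs are drawn
#' from a normal distribution, breadths and body sizes from log-normals.
#' Species are grouped into genera in blocks of `genus_size` so genus-level
#' aggregation has a testable ground truth.
#'
#' @param n_species Number of species (>= 1).
#' @param sti_mean,sti_sd Mean and sd (degC) of the true-STI normal
#'   distribution; `sti_sd = 0` is allowed and degenerate.
#' @param breadth_meanlog,breadth_sdlog Log-normal parameters of the true
#'   niche breadth (degC).
#' @param size_meanlog,size_sdlog Log-normal parameters of body size (m).
#' @param genus_size Species per genus block.
#' @param seed RNG seed; the pool is a pure function of the arguments.
#' @return Data.frame with columns `species`, `genus`, `true_sti`,
#'   `true_breadth`, `body_size_m`.
#' @examples
#' pool <- generate_species_pool(10, seed = 1)
#' @export
generate_species_pool <- function(n_species,
                                  sti_mean = 10, sti_sd = 4,
                                  breadth_meanlog = log(8), breadth_sdlog = 0.25,
                                  size_meanlog = log(0.1), size_sdlog = 0.6,
                                  genus_size = 5, seed = 1L) {
  if (n_species < 1) stop("n_species must be >= 1", call. = FALSE)
  if (sti_sd < 0 || breadth_sdlog < 0 || size_sdlog < 0)
    stop("distribution scales must be non-negative", call. = FALSE)
  with_seed(seed, {
    genus <- sprintf("Genus%03d", (seq_len(n_species) - 1L) %/% genus_size + 1L)
    data.frame(
      species = sprintf("%s sp%03d", genus, seq_len(n_species)),
      genus = genus,
      true_sti = stats::rnorm(n_species, sti_mean, sti_sd),
      true_breadth = stats::rlnorm(n_species, breadth_meanlog, breadth_sdlog),
      body_size_m = stats::rlnorm(n_species, size_meanlog, size_sdlog),
      stringsAsFactors = FALSE)
  })
}

#' Thermal profiles from a pool's ground truth
#'
#' Repackages a virtual pool as a profile table in the shape produced by the
#' occurrence-based estimators, for use where the true values are wanted
#' (e.g. isolating community-level machinery from STI-estimation error).
#'
#' @param pool Output of [generate_species_pool()].
#' @return Data.frame with `species`, `sti`, `niche_breadth`, `n_records`,
#'   `provenance = "species"`.
#' @export
true_profiles <- function(pool) {
  data.frame(species = pool$species, sti = pool$true_sti,
             niche_breadth = pool$true_breadth,
             n_records = NA_integer_, provenance = "species",
             stringsAsFactors = FALSE)
}

#' Define a warming-study simulation scenario
#'
#' Fixes the design of a virtual monitoring study: how many sites and species,
#' the monitored years, the landscape's baseline temperature gradient and
#' seasonal amplitude, the per-site warming rate, the occupancy model width
#' and detection probability, and the (heterogeneous) within-year sampling
#' effort. Defaults describe a temperate multi-site scheme: 120 sites
#' followed for 15 years with per-site warming drawn uniformly from
#' 0-0.06 degC/yr.
#'
#' @param n_sites Number of monitored sites.
#' @param n_species Species-pool size the communities draw from.
#' @param years Inclusive vector of monitored calendar years.
#' @param warming_rate degC/yr; a scalar applied to every cell, or a length-2
#'   range from which each cell's true warming slope is drawn uniformly.
#' @param baseline_temp_range Length-2 range (degC) of the latitudinal
#'   baseline gradient (coldest in the north).
#' @param amplitude Seasonal half-amplitude (degC): bio10 = bio01 + amplitude,
#'   bio11 = bio01 - amplitude, so cell-wise breadth is `2 * amplitude`. A
#'   scalar applies everywhere; a length-2 range varies linearly across
#'   latitude rows (strongest seasonality at the northern edge), so species
#'   occupying different latitudes differ in realised niche breadth.
#' @param min_site_years Minimum monitored span per site: each site enters
#'   the scheme at a random year (staggered entry) leaving at least this
#'   many monitored years, so series lengths vary across sites as they do in
#'   collated monitoring data. Set to `length(years)` for simultaneous
#'   entry.
#' @param occupancy_width_factor k: occupancy width = true_breadth / k
#'   (default 4).
#' @param samples_per_year Length-2 integer range (or scalar) of distinct
#'   samples taken per site-year, drawn uniformly; exercises rarefaction.
#' @param detection_prob Probability in (0, 1] multiplying occupancy.
#' @param annual_noise_sd sd (degC) of i.i.d. interannual cell temperature
#'   noise.
#' @param abundance Logical; when `TRUE`, presences carry an abundance
#'   `1 + rpois(abundance_scale * occupancy)`.
#' @param abundance_scale Mean-abundance scale when `abundance = TRUE`.
#' @param grid_nrow,grid_ncol,origin_lat,origin_lon,cell_size Landscape grid
#'   geometry.
#' @param n_studies Number of study blocks the sites are assigned to (random
#'   intercept grouping downstream).
#' @param taxon_group,realm Labels stamped on the simulated communities.
#' @param rng_seed Default seed for generators run from this scenario.
#' @return List of class `"simulation_scenario"`.
#' @export
simulation_scenario <- function(n_sites = 120,
                                n_species = 150,
                                years = 2000:2014,
                                warming_rate = c(0, 0.06),
                                baseline_temp_range = c(4, 16),
                                amplitude = c(6, 10),
                                min_site_years = 8L,
                                occupancy_width_factor = 4,
                                samples_per_year = c(2L, 4L),
                                detection_prob = 0.8,
                                annual_noise_sd = 0.3,
                                abundance = FALSE,
                                abundance_scale = 20,
                                grid_nrow = 40, grid_ncol = 40,
                                origin_lat = 60, origin_lon = 5,
                                cell_size = 0.25,
                                n_studies = max(2L, n_sites %/% 10L),
                                taxon_group = "plants",
                                realm = "terrestrial",
                                rng_seed = 1L) {
  years <- sort(as.integer(years))
  if (diff(range(years)) < 5)
    stop("scenario years must span at least 5 years", call. = FALSE)
  if (detection_prob <= 0 || detection_prob > 1)
    stop("detection_prob must lie in (0, 1]", call. = FALSE)
  if (!length(warming_rate) %in% 1:2)
    stop("warming_rate must be a scalar or a length-2 range", call. = FALSE)
  if (occupancy_width_factor <= 0)
    stop("occupancy_width_factor must be positive", call. = FALSE)
  if (length(samples_per_year) == 1L)
    samples_per_year <- rep(samples_per_year, 2L)
  if (!length(amplitude) %in% 1:2 || any(amplitude < 0))
    stop("amplitude must be a non-negative scalar or length-2 range",
         call. = FALSE)
  min_site_years <- as.integer(min(min_site_years, length(years)))
  if (min_site_years < 6L)
    stop("min_site_years must allow a span of at least 5 years",
         call. = FALSE)
  if (n_sites > grid_nrow * grid_ncol)
    stop("more sites than grid cells", call. = FALSE)
  structure(list(
    n_sites = as.integer(n_sites), n_species = as.integer(n_species),
    years = years, warming_rate = warming_rate,
    baseline_temp_range = baseline_temp_range, amplitude = amplitude,
    min_site_years = min_site_years,
    occupancy_width_factor = occupancy_width_factor,
    samples_per_year = as.integer(samples_per_year),
    detection_prob = detection_prob, annual_noise_sd = annual_noise_sd,
    abundance = isTRUE(abundance), abundance_scale = abundance_scale,
    grid_nrow = as.integer(grid_nrow), grid_ncol = as.integer(grid_ncol),
    origin_lat = origin_lat, origin_lon = origin_lon, cell_size = cell_size,
    n_studies = as.integer(n_studies),
    taxon_group = taxon_group, realm = realm,
    rng_seed = as.integer(rng_seed)),
    class = "simulation_scenario")
}

#' Generate a warming landscape
#'
#' Builds the climatological layers (`bio01` latitudinal gradient, `bio10` /
#' `bio11` at plus/minus the seasonal half-amplitude) and one annual-mean
#' layer per scenario year: `bio01 + slope * (year - years[1]) + noise`, with
#' a per-cell warming slope (scalar, or drawn uniformly from the scenario's
#' range) and i.i.d. N(0, annual_noise_sd^2) interannual noise. The true
#' per-cell warming slopes are attached as attribute `"cell_warming"`.
#'
#' @param scenario A [simulation_scenario()].
#' @param seed RNG seed (defaults to the scenario's).
#' @return A [temperature_grid()] with attribute `"cell_warming"` (matrix,
#'   degC/yr).
#' @export
generate_landscape <- function(scenario, seed = scenario$rng_seed) {
  nr <- scenario$grid_nrow; nc <- scenario$grid_ncol
  # cell-centroid latitudes, north to south; warmest at the southern edge
  lat_frac <- (seq_len(nr) - 0.5) / nr
  base_col <- scenario$baseline_temp_range[1] +
    (scenario$baseline_temp_range[2] - scenario$baseline_temp_range[1]) * lat_frac
  bio01 <- matrix(base_col, nrow = nr, ncol = nc)
  # seasonal half-amplitude, constant or strongest at the (northern) top row
  amp_col <- if (length(scenario$amplitude) == 1L) rep(scenario$amplitude, nr)
  else scenario$amplitude[2] -
    (scenario$amplitude[2] - scenario$amplitude[1]) * lat_frac
  amp <- matrix(amp_col, nrow = nr, ncol = nc)
  with_seed(seed, {
    W <- if (length(scenario$warming_rate) == 1L)
      matrix(scenario$warming_rate, nr, nc)
    else matrix(stats::runif(nr * nc, scenario$warming_rate[1],
                             scenario$warming_rate[2]), nr, nc)
    layers <- list(bio01 = bio01,
                   bio10 = bio01 + amp,
                   bio11 = bio01 - amp)
    for (y in scenario$years) {
      noise <- if (scenario$annual_noise_sd > 0)
        matrix(stats::rnorm(nr * nc, 0, scenario$annual_noise_sd), nr, nc)
      else 0
      layers[[annual_layer_name(y)]] <-
        bio01 + W * (y - scenario$years[1L]) + noise
    }
    g <- temperature_grid(scenario$origin_lat, scenario$origin_lon,
                          scenario$cell_size, layers)
    attr(g, "cell_warming") <- W
    g
  })
}

#' Generate species occurrence records over a landscape
#'
#' Places records for each species by sampling grid cells with probability
#' proportional to a Gaussian thermal suitability
#' `exp(-(bio01 - true_sti)^2 / (2 * (true_breadth / k)^2))`, with uniform
#' position within the chosen cell. Optionally injects exact duplicates and
#' invalid coordinates so that record cleaning has something to do.
#'
#' @param pool Output of [generate_species_pool()].
#' @param grid A [temperature_grid()] with a `bio01` layer.
#' @param n_records_per_species Records per species (before injection).
#' @param k Occupancy width factor (width = breadth / k).
#' @param year_range Optional length-2 inclusive range from which record years
#'   are drawn uniformly; `NULL` leaves years absent.
#' @param duplicate_fraction Fraction of extra rows that exactly duplicate an
#'   existing record.
#' @param invalid_fraction Fraction of extra rows given out-of-bounds
#'   coordinates.
#' @param seed RNG seed.
#' @return Data.frame of occurrence records (`species`, `latitude`,
#'   `longitude`, `year`, `basis`). Species with near-zero suitability
#'   everywhere yield no records, with a warning.
#' @export
generate_occurrences <- function(pool, grid, n_records_per_species = 200,
                                 k = 4, year_range = c(1975L, 2019L),
                                 duplicate_fraction = 0,
                                 invalid_fraction = 0, seed = 1L) {
  bio01 <- grid$layers$bio01
  ok_cell <- which(is.finite(bio01))
  if (!length(ok_cell)) stop("grid bio01 has no data cells", call. = FALSE)
  temps <- bio01[ok_cell]
  rowi <- (ok_cell - 1L) %% grid$n_rows + 1L
  coli <- (ok_cell - 1L) %/% grid$n_rows + 1L
  with_seed(seed, {
    parts <- vector("list", nrow(pool))
    for (s in seq_len(nrow(pool))) {
      width <- pool$true_breadth[s] / k
      suit <- exp(-(temps - pool$true_sti[s])^2 / (2 * width^2))
      if (sum(suit) < 1e-12) {
        warning("species '", pool$species[s],
                "' has ~zero suitability everywhere; no records generated",
                call. = FALSE)
        next
      }
      idx <- sample.int(length(temps), n_records_per_species,
                        replace = TRUE, prob = suit)
      u <- stats::runif(n_records_per_species)
      v <- stats::runif(n_records_per_species)
      parts[[s]] <- data.frame(
        species = pool$species[s],
        latitude = grid$origin_lat - (rowi[idx] - 1L + u) * grid$cell_size,
        longitude = grid$origin_lon + (coli[idx] - 1L + v) * grid$cell_size,
        year = if (is.null(year_range)) NA_integer_ else
          sample(seq.int(year_range[1L], year_range[2L]),
                 n_records_per_species, replace = TRUE),
        basis = "HUMAN_OBSERVATION",
        stringsAsFactors = FALSE)
    }
    rec <- do.call(rbind, parts)
    if (!is.null(rec) && duplicate_fraction > 0) {
      n_dup <- ceiling(duplicate_fraction * nrow(rec))
      rec <- rbind(rec, rec[sample.int(nrow(rec), n_dup, replace = TRUE), ])
    }
    if (!is.null(rec) && invalid_fraction > 0) {
      n_bad <- ceiling(invalid_fraction * nrow(rec))
      bad <- rec[sample.int(nrow(rec), n_bad, replace = TRUE), ]
      bad$latitude <- stats::runif(n_bad, 91, 120)
      rec <- rbind(rec, bad)
    }
    if (is.null(rec))
      rec <- data.frame(species = character(), latitude = numeric(),
                        longitude = numeric(), year = integer(),
                        basis = character(), stringsAsFactors = FALSE)
    rownames(rec) <- NULL
    rec
  })
}

#' Generate a community time-series with known ground truth
#'
#' Sites are placed at the centroids of distinct random grid cells and
#' assigned to study blocks. In year t at site i with realised annual-mean
#' temperature T_it (warming + interannual noise, from the landscape), species
#' s is present with probability
#' `detection_prob * exp(-(T_it - true_sti_s)^2 / (2 * (true_breadth_s/k)^2))`.
#' Each presence is recorded in one of the site-year's sample units (the
#' number of units is drawn uniformly from the scenario's effort range), so
#' pooling samples recovers the realised community and subsampling loses
#' species — exactly what rarefaction must standardise. Expected community
#' temperature index rises with T_it, so the expected thermophilisation rate
#' has the sign of the warming rate.
#'
#' @param pool Output of [generate_species_pool()]; its first
#'   `scenario$n_species` rows are used.
#' @param grid Output of [generate_landscape()] (needs annual layers and the
#'   `"cell_warming"` attribute).
#' @param scenario A [simulation_scenario()].
#' @param seed RNG seed (defaults to the scenario's).
#' @return List of class `"community_simulation"`: `observations` (long-format
#'   community table) and `sites` (per-site truth: coordinates, study,
#'   baseline temperature, true warming slope).
#' @export
generate_community_timeseries <- function(pool, grid, scenario,
                                          seed = scenario$rng_seed) {
  if (nrow(pool) < scenario$n_species)
    stop("pool smaller than scenario n_species", call. = FALSE)
  pool <- pool[seq_len(scenario$n_species), , drop = FALSE]
  years <- scenario$years
  k <- scenario$occupancy_width_factor
  W <- attr(grid, "cell_warming")
  with_seed(seed, {
    cells <- sample.int(grid$n_rows * grid$n_cols, scenario$n_sites)
    rowi <- (cells - 1L) %% grid$n_rows + 1L
    coli <- (cells - 1L) %/% grid$n_rows + 1L
    lat <- grid$origin_lat - (rowi - 0.5) * grid$cell_size
    lon <- grid$origin_lon + (coli - 0.5) * grid$cell_size
    no_data <- !is.finite(grid$layers$bio01[cbind(rowi, coli)])
    if (any(no_data)) {
      warning(sum(no_data), " site(s) fell in no-data cells and were skipped",
              call. = FALSE)
    }
    keep <- which(!no_data)
    n_sites <- length(keep)
    sites <- data.frame(
      site_id = sprintf("S%04d", seq_len(n_sites)),
      study_id = sprintf("study%03d",
                         sample(rep_len(seq_len(scenario$n_studies), n_sites))),
      taxon_group = scenario$taxon_group, realm = scenario$realm,
      latitude = lat[keep], longitude = lon[keep],
      row = rowi[keep], col = coli[keep],
      baseline_temp = grid$layers$bio01[cbind(rowi[keep], coli[keep])],
      true_warming = if (is.null(W)) NA_real_ else
        W[cbind(rowi[keep], coli[keep])],
      stringsAsFactors = FALSE)
    # realised site x year temperatures (include noise via the annual layers)
    Tmat <- sapply(years, function(y)
      grid$layers[[annual_layer_name(y)]][cbind(sites$row, sites$col)])
    Tmat <- matrix(Tmat, nrow = n_sites)
    width <- pool$true_breadth / k
    # staggered entry: monitored years = a random suffix of the study years
    max_start <- length(years) - scenario$min_site_years + 1L
    start_idx <- if (max_start > 1L)
      sample.int(max_start, n_sites, replace = TRUE)
    else rep(1L, n_sites)
    sites$first_monitored <- years[start_idx]
    parts <- vector("list", n_sites)
    for (i in seq_len(n_sites)) {
      # presence probability matrix: years x species
      P <- scenario$detection_prob *
        exp(-outer(Tmat[i, ], pool$true_sti, "-")^2 /
              rep(2 * width^2, each = length(years)))
      P[seq_len(start_idx[i] - 1L), ] <- 0  # before this site entered
      pres <- which(matrix(stats::runif(length(P)), nrow(P)) < P,
                    arr.ind = TRUE)
      if (!nrow(pres)) next
      n_samp <- sample(seq.int(scenario$samples_per_year[1L],
                               scenario$samples_per_year[2L]),
                       length(years), replace = TRUE)
      samp <- vapply(pres[, 1L], function(yi)
        sample.int(n_samp[yi], 1L), integer(1L))
      ab <- if (scenario$abundance)
        1 + stats::rpois(nrow(pres),
                         scenario$abundance_scale *
                           P[pres] / scenario$detection_prob)
      else NA_real_
      parts[[i]] <- data.frame(
        site_id = sites$site_id[i], study_id = sites$study_id[i],
        taxon_group = scenario$taxon_group, realm = scenario$realm,
        latitude = sites$latitude[i], longitude = sites$longitude[i],
        year = years[pres[, 1L]],
        sample_id = sprintf("smp%d", samp),
        species = pool$species[pres[, 2L]],
        abundance = ab, stringsAsFactors = FALSE)
    }
    observations <- do.call(rbind, parts)
    if (is.null(observations))
      observations <- data.frame(site_id = character(), study_id = character(),
                                 taxon_group = character(), realm = character(),
                                 latitude = numeric(), longitude = numeric(),
                                 year = integer(), sample_id = character(),
                                 species = character(), abundance = numeric(),
                                 stringsAsFactors = FALSE)
    rownames(observations) <- NULL
    structure(list(observations = observations, sites = sites),
              class = "community_simulation")
  })
}

#' @export
print.community_simulation <- function(x, ...) {
  cat(sprintf("community_simulation: %d sites, %d observation rows, %d-%d\n",
              nrow(x$sites), nrow(x$observations),
              min(x$observations$year), max(x$observations$year)))
  invisible(x)
}

#' Simulate a complete virtual warming study
#'
#' Convenience wrapper running [generate_species_pool()],
#' [generate_landscape()] and [generate_community_timeseries()] under one
#' seed, optionally with occurrence records for STI estimation.
#'
#' @param scenario A [simulation_scenario()].
#' @param seed Base RNG seed (defaults to the scenario's); sub-generators use
#'   fixed offsets of it.
#' @param occurrences Logical; also generate occurrence records
#'   (`n_occ_records` per species).
#' @param n_occ_records Records per species when `occurrences = TRUE`.
#' @return List with `pool`, `grid`, `sites`, `observations`, and optionally
#'   `occurrences`.
#' @export
simulate_dataset <- function(scenario, seed = scenario$rng_seed,
                             occurrences = FALSE, n_occ_records = 200) {
  pool <- generate_species_pool(scenario$n_species, seed = seed)
  grid <- generate_landscape(scenario, seed = seed + 1L)
  sim <- generate_community_timeseries(pool, grid, scenario, seed = seed + 2L)
  out <- list(pool = pool, grid = grid, sites = sim$sites,
              observations = sim$observations)
  if (occurrences)
    out$occurrences <- generate_occurrences(
      pool, grid, n_records_per_species = n_occ_records,
      k = scenario$occupancy_width_factor, seed = seed + 3L)
  out
}
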