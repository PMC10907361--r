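#' Apply community inclusion filters
#'
#' Applies, in order: (1) drop observation years before `min_year`; then
#' exclude any site whose remaining record (2) spans fewer than
#' `min_span_years` (last year minus first year), (3) holds fewer than
#' `min_species` distinct species over the whole series, or (4) has thermal
#' profiles for less than `min_sti_coverage` of its distinct species. Only
#' the first triggered rule is reported per excluded site. Filtering is
#' idempotent, and kept + excluded sites partition the input.
#'
#' @param observations Validated community observations (long format).
#' @param profiles Thermal profile table (`species` column is matched by
#'   name; genus/complex entries count).
#' @param config An [analysis_config()].
#' @return List: `observations` (rows of kept sites, pre-`min_year` years
#'   removed), `report` (data.frame `site_id`, `rule`, `detail` for excluded
#'   sites), `kept_sites` (character vector).
#' @export
filter_communities <- function(observations, profiles,
                               config = analysis_config()) {
  obs <- observations[observations$year >= config$min_year, , drop = FALSE]
  all_sites <- unique(observations$site_id)
  report <- list()
  kept <- character()
  profiled <- unique(profiles$species)
  for (s in all_sites) {
    sub <- obs[obs$site_id == s, , drop = FALSE]
    if (!nrow(sub)) {
      report[[s]] <- c("min_year",
                       sprintf("no observations in or after %d",
                               config$min_year))
      next
    }
    span <- max(sub$year) - min(sub$year)
    if (span < config$min_span_years) {
      report[[s]] <- c("min_span", sprintf("span %d < %g yr", span,
                                           config$min_span_years))
      next
    }
    spp <- unique(sub$species)
    if (length(spp) < config$min_species) {
      report[[s]] <- c("min_species", sprintf("%d < %g species", length(spp),
                                              config$min_species))
      next
    }
    cov <- mean(spp %in% profiled)
    if (cov < config$min_sti_coverage) {
      report[[s]] <- c("sti_coverage", sprintf("coverage %.3f < %g", cov,
                                               config$min_sti_coverage))
      next
    }
    kept <- c(kept, s)
  }
  rep_df <- if (length(report))
    data.frame(site_id = names(report),
               rule = vapply(report, `[`, "", 1L),
               detail = vapply(report, `[`, "", 2L),
               stringsAsFactors = FALSE)
  else data.frame(site_id = character(), rule = character(),
                  detail = character(), stringsAsFactors = FALSE)
  rownames(rep_df) <- NULL
  out_obs <- obs[obs$site_id %in% kept, , drop = FALSE]
  rownames(out_obs) <- NULL
  list(observations = out_obs, report = rep_df, kept_sites = kept)
}

#' Pooled per-year species sets of one site
#'
#' Unions species over a year's sample units.
#'
#' @param observations Observation rows of a single site.
#' @return Named list (by year, ascending) of character vectors of species.
#' @export
species_sets <- function(observations) {
  yrs <- sort(unique(observations$year))
  out <- lapply(yrs, function(y)
    sort(unique(observations$species[observations$year == y])))
  names(out) <- yrs
  out
}

# Derived per-year variables on a set of observation rows (one site, any
# subset of samples): richness and occurrence-based CTI.
year_variables <- function(obs, sti_lookup, min_coverage) {
  yrs <- sort(unique(obs$year))
  res <- matrix(NA_real_, length(yrs), 4L,
                dimnames = list(NULL, c("richness", "cti", "n_species_used",
                                        "coverage")))
  for (i in seq_along(yrs)) {
    spp <- unique(obs$species[obs$year == yrs[i]])
    res[i, "richness"] <- length(spp)
    if (!is.null(sti_lookup)) {
      sti <- sti_lookup[spp]
      used <- !is.na(sti)
      cov <- mean(used)
      res[i, "coverage"] <- cov
      res[i, "n_species_used"] <- sum(used)
      if (sum(used) > 0L && cov >= min_coverage)
        res[i, "cti"] <- mean(sti[used])
    }
  }
  list(years = yrs, vars = res)
}

#' Rarefaction-based sampling-effort standardisation
#'
#' For each site in `rarefy_studies`, finds m = the minimum number of
#' distinct sample units in any year of the series, then repeatedly
#' (`config$n_rarefaction_reps` times, replicate r seeded `seed + r`) draws m
#' sample units without replacement from every year, pools species, and
#' computes the derived per-year variables (species richness, and
#' occurrence-based CTI when `profiles` is supplied). The per-site-year
#' output is the median of each variable across replicates — an attained
#' value, since the replicate count is odd. Sites in other studies pass
#' through unrarefied (all samples pooled). Years with zero samples are
#' dropped with a warning.
#'
#' @param observations Filtered community observations.
#' @param profiles Optional thermal profile table for CTI computation.
#' @param config An [analysis_config()].
#' @param seed Base RNG seed (default `config$rng_seed`).
#' @param rarefy_studies Character vector of `study_id`s to standardise;
#'   `NULL` (default) standardises every study.
#' @return Data.frame, one row per kept site-year: `site_id`, `year`,
#'   `richness`, `cti`, `n_species_used`, `coverage`, `rarefied` (logical),
#'   `m_samples`.
#' @export
rarefy_timeseries <- function(observations, profiles = NULL,
                              config = analysis_config(),
                              seed = config$rng_seed,
                              rarefy_studies = NULL) {
  sti_lookup <- if (!is.null(profiles))
    stats::setNames(profiles$sti, profiles$species)
  parts <- list()
  for (s in unique(observations$site_id)) {
    sub <- observations[observations$site_id == s, , drop = FALSE]
    do_rarefy <- is.null(rarefy_studies) ||
      any(sub$study_id %in% rarefy_studies)
    if (!do_rarefy) {
      yv <- year_variables(sub, sti_lookup, config$min_sti_coverage)
      parts[[s]] <- data.frame(site_id = s, year = yv$years, yv$vars,
                               rarefied = FALSE, m_samples = NA_integer_,
                               stringsAsFactors = FALSE)
      next
    }
    n_samp <- tapply(sub$sample_id, sub$year,
                     function(x) length(unique(x)))
    m <- min(n_samp)
    yrs <- sort(unique(sub$year))
    reps <- config$n_rarefaction_reps
    acc <- array(NA_real_, c(length(yrs), 4L, reps))
    for (r in seq_len(reps)) {
      drawn <- with_seed(seed + r, {
        keep_rows <- logical(nrow(sub))
        for (y in yrs) {
          in_y <- sub$year == y
          ids <- unique(sub$sample_id[in_y])
          take <- if (length(ids) > m) sample(ids, m) else ids
          keep_rows[in_y & sub$sample_id %in% take] <- TRUE
        }
        keep_rows
      })
      yv <- year_variables(sub[drawn, , drop = FALSE], sti_lookup,
                           config$min_sti_coverage)
      acc[match(yv$years, yrs), , r] <- yv$vars
    }
    med <- apply(acc, c(1L, 2L), stats::median, na.rm = FALSE)
    colnames(med) <- c("richness", "cti", "n_species_used", "coverage")
    parts[[s]] <- data.frame(site_id = s, year = yrs, med, rarefied = TRUE,
                             m_samples = as.integer(m),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, parts)
  if (is.null(out))
    out <- data.frame(site_id = character(), year = integer(),
                      richness = numeric(), cti = numeric(),
                      n_species_used = numeric(), coverage = numeric(),
                      rarefied = logical(), m_samples = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
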