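#' Site-level temperature trend
#'
#' OLS slope of mean annual temperature on year over the window in which
#' community change was observed at the site.
#'
#' @param years,temperature Numeric vectors (paired).
#' @param window Optional length-2 inclusive year range to restrict to.
#' @return Slope in degC/yr.
#' @examples
#' site_temperature_trend(c(2000, 2010), c(10, 11))  # 0.1
#' @export
site_temperature_trend <- function(years, temperature, window = NULL) {
  ok <- is.finite(years) & is.finite(temperature)
  if (!is.null(window))
    ok <- ok & years >= window[1L] & years <= window[2L]
  years <- years[ok]; temperature <- temperature[ok]
  if (length(unique(years)) < 2L)
    stop("temperature trend needs at least 2 distinct years in the window",
         call. = FALSE)
  unname(stats::coef(stats::lm(temperature ~ years))[2L])
}

#' Assemble per-site predictors for the driver models
#'
#' Joins each site's thermophilisation rate with its hypothesised drivers:
#' the site temperature trend over the community's own observation window,
#' the baseline (climatological) mean annual temperature, community mean
#' body size and mean thermal niche breadth (unweighted means over the
#' species recorded at the site, where trait/profile data exist), total
#' distinct species richness and series length. Trait coverage below
#' `trait_coverage_warn` triggers a warning and flags the site.
#'
#' @param rates Output of [site_rates()] with `latitude`/`longitude` columns.
#' @param grid A [temperature_grid()] with annual layers (temperature trend)
#'   and a `bio01` layer (baseline fallback).
#' @param profiles Thermal profile table (`species`, `sti`, `niche_breadth`).
#' @param traits Trait table (`species`, `body_size_m`), or `NULL`.
#' @param observations The (filtered) community observations the rates came
#'   from.
#' @param baseline_window Length-2 year range over which annual layers are
#'   averaged for the baseline temperature (default 1980-2010); years absent
#'   from the grid are ignored, and `bio01` is used if none overlap.
#' @param trait_coverage_warn Warn when a site's trait coverage falls below
#'   this fraction (default 0.7).
#' @return Data.frame of `SiteResult` rows: rate + predictors + coverage
#'   diagnostics (`trait_coverage`, `profile_coverage`, `flagged`).
#' @export
assemble_predictors <- function(rates, grid, profiles, traits, observations,
                                baseline_window = c(1980, 2010),
                                trait_coverage_warn = 0.7) {
  sti_lookup <- stats::setNames(profiles$sti, profiles$species)
  br_lookup <- if ("niche_breadth" %in% names(profiles))
    stats::setNames(profiles$niche_breadth, profiles$species)
  size_lookup <- if (!is.null(traits))
    stats::setNames(traits$body_size_m, traits$species)
  bl_years <- grid_years(grid)
  bl_years <- bl_years[bl_years >= baseline_window[1L] &
                         bl_years <= baseline_window[2L]]
  obs_split <- split(observations, observations$site_id)
  rows <- lapply(seq_len(nrow(rates)), function(i) {
    r <- rates[i, ]
    o <- obs_split[[r$site_id]]
    spp <- unique(o$species)
    ann <- annual_series(grid, r$latitude, r$longitude)
    ann <- ann[ann$year >= r$first_year & ann$year <= r$last_year, ]
    temp_change <- if (sum(is.finite(ann$temperature)) >= 2L)
      site_temperature_trend(ann$year, ann$temperature) else NA_real_
    cell <- locate_cell(grid, r$latitude, r$longitude)
    baseline <- if (length(bl_years)) {
      v <- vapply(bl_years, function(y)
        grid_values(grid, annual_layer_name(y), cell$row, cell$col),
        numeric(1L))
      mean(v, na.rm = TRUE)
    } else grid_values(grid, "bio01", cell$row, cell$col)
    sizes <- if (is.null(size_lookup)) rep(NA_real_, length(spp))
    else size_lookup[spp]
    trait_cov <- mean(!is.na(sizes))
    breadths <- if (is.null(br_lookup)) rep(NA_real_, length(spp))
    else br_lookup[spp]
    data.frame(
      site_id = r$site_id,
      realm = if ("realm" %in% names(r)) r$realm else NA_character_,
      taxon_group = if ("taxon_group" %in% names(r)) r$taxon_group
      else NA_character_,
      study_id = if ("study_id" %in% names(r)) r$study_id else NA_character_,
      latitude = r$latitude, longitude = r$longitude,
      rate = r$slope, temp_change = temp_change, baseline_temp = baseline,
      mean_body_size = if (all(is.na(sizes))) NA_real_
      else mean(sizes, na.rm = TRUE),
      mean_niche_breadth = if (all(is.na(breadths))) NA_real_
      else mean(breadths, na.rm = TRUE),
      richness = length(spp),
      series_length = r$last_year - r$first_year,
      trait_coverage = trait_cov,
      profile_coverage = mean(spp %in% profiles$species),
      flagged = trait_cov < trait_coverage_warn,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  n_flag <- sum(out$flagged, na.rm = TRUE)
  if (n_flag > 0L)
    warning(n_flag, " site(s) have body-size trait coverage below ",
            trait_coverage_warn, call. = FALSE)
  out
}

#' z-score standardisation
#'
#' `(x - mean) / sd` with the sample (n-1) standard deviation; `NA`s are
#' ignored in the moments and preserved in the output.
#'
#' @param x Numeric vector with at least 2 distinct finite values.
#' @param name Variable name used in the zero-variance error message.
#' @return Standardised vector (mean 0, sample sd 1).
#' @examples
#' zscore(1:3)  # -1 0 1
#' @export
zscore <- function(x, name = deparse(substitute(x))) {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0)
    stop("zscore: '", name, "' has zero variance", call. = FALSE)
  (x - mean(x, na.rm = TRUE)) / s
}

#' Pairwise predictor correlations with collinearity warnings
#'
#' @param x Numeric data.frame or matrix of predictors.
#' @param warn_threshold Absolute Pearson r above which a warning is raised
#'   (default 0.7).
#' @return Correlation matrix (`NA` for constant columns, with a message in
#'   attribute `"flags"`); attribute `"warnings"` lists the offending pairs.
#' @export
predictor_correlations <- function(x, warn_threshold = 0.7) {
  x <- as.data.frame(x)
  num <- vapply(x, is.numeric, TRUE)
  x <- x[num]
  const <- vapply(x, function(v) stats::sd(v, na.rm = TRUE) == 0 ||
                    !is.finite(stats::sd(v, na.rm = TRUE)), TRUE)
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  r[const, ] <- NA_real_; r[, const] <- NA_real_
  diag(r) <- ifelse(const, NA_real_, 1)
  high <- which(abs(r) > warn_threshold & upper.tri(r), arr.ind = TRUE)
  pairs <- if (nrow(high))
    sprintf("%s ~ %s (r = %.3f)", rownames(r)[high[, 1L]],
            colnames(r)[high[, 2L]], r[high])
  else character()
  if (length(pairs))
    warning("predictor correlation above ", warn_threshold, ": ",
            paste(pairs, collapse = "; "), call. = FALSE)
  attr(r, "warnings") <- pairs
  attr(r, "flags") <- names(x)[const]
  r
}
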