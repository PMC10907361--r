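#' Community temperature index (occurrence-based)
#'
#' CTI is the unweighted mean STI over the community's species, using species
#' with a thermal profile (species-level, genus-mean or complex-mean). When
#' the profiled fraction falls below `min_coverage` the point is rejected
#' (`cti = NA`) rather than computed on an unrepresentative subset.
#'
#' @param species Character vector of species present.
#' @param profiles Thermal profile table with `species` and `sti` columns.
#' @param min_coverage Minimum profiled fraction to accept the point.
#' @return List: `cti` (degC or `NA`), `n_used`, `coverage`.
#' @examples
#' pr <- data.frame(species = c("a", "b", "c"), sti = c(10, 12, 14))
#' compute_cti(c("a", "b", "c"), pr)$cti  # 12
#' @export
compute_cti <- function(species, profiles, min_coverage = 0.75) {
  stopifnot(length(species) > 0L)
  species <- unique(species)
  sti <- profiles$sti[match(species, profiles$species)]
  used <- !is.na(sti)
  coverage <- mean(used)
  cti <- if (sum(used) > 0L && coverage >= min_coverage)
    mean(sti[used]) else NA_real_
  list(cti = cti, n_used = sum(used), coverage = coverage)
}

#' Community temperature index (abundance-weighted)
#'
#' `cti_w = sum(a_i * STI_i) / sum(a_i)` over profiled species. Species with
#' zero abundance contribute nothing; if all profiled species have zero
#' abundance the point is rejected.
#'
#' @param abundance Named numeric vector (names = species) of non-negative
#'   abundances.
#' @inheritParams compute_cti
#' @return List: `cti` (`NA` when rejected), `n_used`, `coverage`.
#' @export
compute_cti_weighted <- function(abundance, profiles, min_coverage = 0.75) {
  stopifnot(length(abundance) > 0L, !is.null(names(abundance)))
  if (any(abundance < 0, na.rm = TRUE))
    stop("abundances must be non-negative", call. = FALSE)
  ab <- tapply(abundance, names(abundance), sum)  # collapse repeated species
  sti <- profiles$sti[match(names(ab), profiles$species)]
  used <- !is.na(sti) & !is.na(ab)
  coverage <- mean(!is.na(sti))
  w <- ab[used]
  cti <- if (sum(w) > 0 && coverage >= min_coverage)
    sum(w * sti[used]) / sum(w) else NA_real_
  list(cti = as.numeric(cti), n_used = sum(used & ab > 0),
       coverage = coverage)
}

#' Per-site-year CTI series
#'
#' Computes the occurrence-based (and, when abundances are present and
#' `weighted = TRUE`, abundance-weighted) CTI for every site-year by pooling
#' each year's samples.
#'
#' @param observations Community observations (long format).
#' @param profiles Thermal profile table.
#' @param min_coverage Minimum profiled fraction per point.
#' @param weighted Also compute the abundance-weighted variant?
#' @return Data.frame: `site_id`, `year`, `cti`, `n_species_used`,
#'   `coverage` (and `cti_weighted` when requested).
#' @export
cti_series <- function(observations, profiles, min_coverage = 0.75,
                       weighted = FALSE) {
  key <- interaction(observations$site_id, observations$year, drop = TRUE)
  idx <- split(seq_len(nrow(observations)), key)
  rows <- lapply(idx, function(ii) {
    o <- observations[ii, , drop = FALSE]
    occ <- compute_cti(o$species, profiles, min_coverage)
    out <- data.frame(site_id = o$site_id[1L], year = o$year[1L],
                      cti = occ$cti, n_species_used = occ$n_used,
                      coverage = occ$coverage, stringsAsFactors = FALSE)
    if (weighted) {
      ab <- tapply(o$abundance, o$species, sum)
      out$cti_weighted <- if (all(is.na(ab))) NA_real_
      else compute_cti_weighted(stats::setNames(as.numeric(ab), names(ab)),
                                profiles, min_coverage)$cti
    }
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$site_id, out$year), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Thermophilisation rate of one CTI series
#'
#' The ordinary-least-squares slope of CTI on calendar year: positive slopes
#' are thermophilisation (warm-affinity species gaining prevalence), negative
#' slopes cryophilisation.
#'
#' @param years Numeric vector of calendar years.
#' @param cti Numeric vector of CTI values (`NA` points are dropped).
#' @param center Center years before fitting (slope is unaffected; useful for
#'   numerical hygiene at extreme year values)?
#' @return List: `slope` (degC/yr), `intercept`, `se` (slope standard error,
#'   `NA` with < 3 points), `n_years`.
#' @examples
#' thermophilisation_rate(c(2000, 2005), c(12, 14))$slope  # 0.4
#' @export
thermophilisation_rate <- function(years, cti, center = FALSE) {
  ok <- is.finite(years) & is.finite(cti)
  years <- years[ok]; cti <- cti[ok]
  if (length(unique(years)) < 2L)
    stop("thermophilisation rate needs at least 2 distinct years",
         call. = FALSE)
  if (length(years) < 3L)
    warning("fewer than 3 points: slope has no residual degrees of freedom",
            call. = FALSE)
  x <- if (center) years - mean(years) else years
  fit <- stats::lm(cti ~ x)
  # exact-linear series are legal: silence the perfect-fit note
  cf <- suppressWarnings(summary(fit))$coefficients
  se <- if (nrow(cf) >= 2L && length(years) > 2L) cf[2L, 2L] else NA_real_
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       se = unname(se), n_years = length(years))
}

#' Per-site thermophilisation rates
#'
#' Fits [thermophilisation_rate()] to each site's CTI series (e.g. the median
#' series from [rarefy_timeseries()] or the pooled series from
#' [cti_series()]) and attaches site metadata.
#'
#' @param series Data.frame with `site_id`, `year`, `cti` columns.
#' @param site_info Optional data.frame keyed by `site_id` with metadata
#'   columns to carry through (e.g. `realm`, `taxon_group`, `study_id`,
#'   `latitude`, `longitude`).
#' @param min_points Minimum usable points per site (default 2; sites below
#'   are skipped).
#' @return Data.frame: `site_id`, `slope`, `se`, `n_years`, `first_year`,
#'   `last_year`, plus any metadata columns.
#' @export
site_rates <- function(series, site_info = NULL, min_points = 2L) {
  parts <- lapply(split(series, series$site_id), function(s) {
    ok <- is.finite(s$cti)
    if (length(unique(s$year[ok])) < min_points) return(NULL)
    r <- suppressWarnings(thermophilisation_rate(s$year[ok], s$cti[ok]))
    data.frame(site_id = s$site_id[1L], slope = r$slope, se = r$se,
               n_years = r$n_years, first_year = min(s$year[ok]),
               last_year = max(s$year[ok]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  if (is.null(out))
    return(data.frame(site_id = character(), slope = numeric(),
                      se = numeric(), n_years = integer(),
                      first_year = integer(), last_year = integer(),
                      stringsAsFactors = FALSE))
  if (!is.null(site_info)) {
    meta <- site_info[!duplicated(site_info$site_id), , drop = FALSE]
    out <- merge(out, meta, by = "site_id", all.x = TRUE, sort = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Correlation between occurrence-based and abundance-weighted CTI
#'
#' @param cti_occurrence,cti_weighted Paired numeric vectors (site-years).
#' @return List: `r` (Pearson, `NA` when undefined), `n` (complete pairs),
#'   `reason` (`NULL`, or why r is undefined).
#' @export
compare_cti_variants <- function(cti_occurrence, cti_weighted) {
  ok <- is.finite(cti_occurrence) & is.finite(cti_weighted)
  n <- sum(ok)
  if (n < 3L)
    return(list(r = NA_real_, n = n, reason = "fewer than 3 paired points"))
  if (stats::sd(cti_occurrence[ok]) == 0 || stats::sd(cti_weighted[ok]) == 0)
    return(list(r = NA_real_, n = n, reason = "zero variance in a variant"))
  list(r = stats::cor(cti_occurrence[ok], cti_weighted[ok]), n = n,
       reason = NULL)
}
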