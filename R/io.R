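#' Read a long-format community time-series table
#'
#' Reads a CSV with one row per (site, year, sample, species) observation,
#' validates coordinates and mandatory fields, and collapses exact duplicate
#' keys (summing abundance where present). Column names can be remapped via
#' `dialect` to accommodate source-specific headers.
#'
#' Mandatory columns (after remapping): `site_id`, `study_id`, `taxon_group`,
#' `realm`, `latitude`, `longitude`, `year`, `sample_id`, `species`;
#' `abundance` is optional. Rows failing a validity check (coordinates out of
#' bounds or unparseable, empty species, missing year) are rejected, not
#' fatal; the attached report records each rejection with its reason.
#'
#' @param path CSV file path.
#' @param dialect Optional named character vector mapping standard column
#'   names to the file's column names, e.g. `c(site_id = "PlotID")`.
#' @return A data.frame of validated observations with attribute `"report"`:
#'   a list with `n_read`, `n_kept`, `n_collapsed` and a data.frame
#'   `rejections` (`row`, `reason`).
#' @export
read_community_table <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(dialect)) {
    for (std in names(dialect)) {
      if (!dialect[[std]] %in% names(raw))
        stop("dialect maps '", std, "' to missing column '", dialect[[std]],
             "'", call. = FALSE)
      names(raw)[names(raw) == dialect[[std]]] <- std
    }
  }
  mandatory <- c("site_id", "study_id", "taxon_group", "realm", "latitude",
                 "longitude", "year", "sample_id", "species")
  miss <- setdiff(mandatory, names(raw))
  if (length(miss))
    stop("community table missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"abundance" %in% names(raw)) raw$abundance <- NA_real_
  raw <- raw[c(mandatory, "abundance")]
  validate_observations(raw)
}

# Shared validation + duplicate collapse for community observations.
validate_observations <- function(raw) {
  n_read <- nrow(raw)
  if (n_read == 0L) {
    out <- raw
    attr(out, "report") <- list(n_read = 0L, n_kept = 0L, n_collapsed = 0L,
                                rejections = data.frame(row = integer(),
                                                        reason = character()))
    return(out)
  }
  lat <- suppressWarnings(as.numeric(raw$latitude))
  lon <- suppressWarnings(as.numeric(raw$longitude))
  yr <- suppressWarnings(as.integer(raw$year))
  ab <- suppressWarnings(as.numeric(raw$abundance))
  reason <- rep(NA_character_, n_read)
  flag <- function(cond, why) reason[is.na(reason) & cond] <<- why
  flag(!is.finite(lat) | lat < -90 | lat > 90, "invalid_latitude")
  flag(!is.finite(lon) | lon < -180 | lon > 180, "invalid_longitude")
  flag(is.na(raw$species) | !nzchar(trimws(raw$species)), "empty_species")
  flag(is.na(yr), "invalid_year")
  flag(!is.na(ab) & ab < 0, "negative_abundance")
  keep <- is.na(reason)
  obs <- data.frame(
    site_id = as.character(raw$site_id[keep]),
    study_id = as.character(raw$study_id[keep]),
    taxon_group = as.character(raw$taxon_group[keep]),
    realm = as.character(raw$realm[keep]),
    latitude = lat[keep], longitude = lon[keep],
    year = yr[keep],
    sample_id = as.character(raw$sample_id[keep]),
    species = trimws(as.character(raw$species[keep])),
    abundance = ab[keep],
    stringsAsFactors = FALSE)
  key <- paste(obs$site_id, obs$year, obs$sample_id, obs$species, sep = "\r")
  n_collapsed <- 0L
  if (anyDuplicated(key)) {
    n_collapsed <- sum(duplicated(key))
    ab_sum <- tapply(obs$abundance, key, function(a)
      if (all(is.na(a))) NA_real_ else sum(a, na.rm = TRUE))
    obs <- obs[!duplicated(key), , drop = FALSE]
    obs$abundance <- as.numeric(ab_sum[paste(obs$site_id, obs$year,
                                             obs$sample_id, obs$species,
                                             sep = "\r")])
  }
  rownames(obs) <- NULL
  attr(obs, "report") <- list(
    n_read = n_read, n_kept = nrow(obs), n_collapsed = n_collapsed,
    rejections = data.frame(row = which(!keep), reason = reason[!keep]))
  obs
}

#' Read a species occurrence table
#'
#' CSV columns: `species`, `latitude`, `longitude`, optional `year`, optional
#' `basis` (record basis, e.g. `"PRESERVED_SPECIMEN"`). Coordinate validity is
#' *not* enforced here — raw downloads legitimately contain errors; run
#' [clean_occurrences()] next.
#'
#' @param path CSV file path.
#' @return Data.frame with columns `species`, `latitude`, `longitude`,
#'   `year`, `basis`.
#' @export
read_occurrence_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("species", "latitude", "longitude"), names(raw))
  if (length(miss))
    stop("occurrence table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  data.frame(
    species = as.character(raw$species),
    latitude = suppressWarnings(as.numeric(raw$latitude)),
    longitude = suppressWarnings(as.numeric(raw$longitude)),
    year = if ("year" %in% names(raw))
      suppressWarnings(as.integer(raw$year)) else NA_integer_,
    basis = if ("basis" %in% names(raw))
      as.character(raw$basis) else NA_character_,
    stringsAsFactors = FALSE)
}

#' Read a species trait table
#'
#' CSV columns: `species`, `body_size_m` (longest linear dimension, metres).
#'
#' @param path CSV file path.
#' @return Data.frame with columns `species`, `body_size_m`.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("species", "body_size_m"), names(raw))
  if (length(miss))
    stop("trait table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- data.frame(species = as.character(raw$species),
                    body_size_m = suppressWarnings(as.numeric(raw$body_size_m)),
                    stringsAsFactors = FALSE)
  if (any(out$body_size_m <= 0, na.rm = TRUE))
    stop("trait table contains non-positive body sizes", call. = FALSE)
  out
}

#' Write a community table (round-trip safe)
#' @param observations Data.frame as returned by [read_community_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_community_table <- function(observations, path) {
  out <- observations
  for (nm in names(out)) {
    if (is.double(out[[nm]])) {  # full precision so values round-trip exactly
      v <- sprintf("%.17g", out[[nm]])
      v[is.na(out[[nm]])] <- NA_character_
      out[[nm]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
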