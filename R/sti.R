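#' Clean species occurrence records
#'
#' Applies basic record hygiene before thermal-affinity estimation: removes
#' records with invalid coordinates (non-finite, out of the WGS84 bounds, or
#' the (0, 0) null-island point), optionally removes preserved-specimen
#' records, and removes exact duplicates on (species, latitude, longitude).
#'
#' @param records Data.frame as from [read_occurrence_table()].
#' @param drop_preserved Remove records whose `basis` matches
#'   `preserved_labels`?
#' @param preserved_labels Character vector of record-basis labels treated as
#'   preserved specimens (case-insensitive).
#' @return Cleaned data.frame with attribute `"report"`: a data.frame of
#'   removal counts by `reason` (`invalid_coordinate`, `zero_zero`,
#'   `preserved`, `duplicate`).
#' @examples
#' occ <- data.frame(species = "a", latitude = c(1, 1, 95),
#'                   longitude = c(2, 2, 10))
#' nrow(clean_occurrences(occ))  # 1: one duplicate + one bad coordinate
#' @export
clean_occurrences <- function(records, drop_preserved = FALSE,
                              preserved_labels = c("PRESERVED_SPECIMEN",
                                                   "FOSSIL_SPECIMEN")) {
  lat <- records$latitude
  lon <- records$longitude
  invalid <- !is.finite(lat) | !is.finite(lon) |
    lat < -90 | lat > 90 | lon < -180 | lon > 180
  zero <- !invalid & lat == 0 & lon == 0
  preserved <- rep(FALSE, nrow(records))
  if (drop_preserved && "basis" %in% names(records))
    preserved <- !invalid & !zero & !is.na(records$basis) &
      toupper(trimws(records$basis)) %in% toupper(preserved_labels)
  keep <- !(invalid | zero | preserved)
  out <- records[keep, , drop = FALSE]
  dup <- duplicated(out[c("species", "latitude", "longitude")])
  report <- data.frame(
    reason = c("invalid_coordinate", "zero_zero", "preserved", "duplicate"),
    n = c(sum(invalid), sum(zero), sum(preserved), sum(dup)),
    stringsAsFactors = FALSE)
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "report") <- report
  out
}

# Per-species mean of a grid layer over records; cells = TRUE averages over
# unique occupied cells, FALSE over raw records.
species_layer_mean <- function(records, grid, layer, cells = TRUE) {
  loc <- locate_cell(grid, records$latitude, records$longitude)
  val <- grid_values(grid, layer, loc$row, loc$col)
  ok <- !is.na(val)
  sp <- records$species[ok]
  if (cells) {
    cell_id <- (loc$col[ok] - 1L) * grid$n_rows + loc$row[ok]
    first <- !duplicated(paste(sp, cell_id))
    sp <- sp[first]
    val <- val[ok][first]
  } else val <- val[ok]
  tapply(val, sp, mean)
}

#' Estimate species temperature indices (STI) from occurrences
#'
#' The STI of a species is the mean annual-mean temperature (`bio01`) over its
#' occupied range: records are assigned to grid cells and, by default, the
#' mean is taken over the *unique occupied cells*, which blunts
#' sampling-density bias (a per-record mean is available via
#' `cells = FALSE`). Species with fewer than `min_records` retained in-extent
#' records get no profile and are listed in the attached report.
#'
#' @param records Cleaned occurrence records (see [clean_occurrences()]).
#' @param grid A [temperature_grid()] with a `bio01` layer.
#' @param min_records Minimum retained records for a species-level estimate
#'   (default 5).
#' @param cells Average over unique occupied cells (default) or raw records.
#' @return Data.frame (`species`, `sti`, `n_records`,
#'   `provenance = "species"`) with attribute `"excluded"`: a data.frame
#'   (`species`, `n_records`, `reason`) of species left unprofiled.
#' @export
estimate_sti <- function(records, grid, min_records = 5, cells = TRUE) {
  loc <- locate_cell(grid, records$latitude, records$longitude)
  val <- grid_values(grid, "bio01", loc$row, loc$col)
  ok <- !is.na(val)
  n_ok <- table(factor(records$species[ok],
                       levels = unique(records$species)))
  sti <- species_layer_mean(records, grid, "bio01", cells = cells)
  all_sp <- names(n_ok)
  enough <- all_sp[n_ok >= min_records & n_ok > 0]
  out <- data.frame(species = enough,
                    sti = as.numeric(sti[enough]),
                    n_records = as.integer(n_ok[enough]),
                    provenance = rep("species", length(enough)),
                    stringsAsFactors = FALSE)
  excluded <- all_sp[!all_sp %in% enough]
  attr(out, "excluded") <- data.frame(
    species = excluded, n_records = as.integer(n_ok[excluded]),
    reason = ifelse(n_ok[excluded] == 0L, "out_of_extent", "too_few_records"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Estimate thermal niche breadth from occurrences
#'
#' Breadth is the difference between the warmest-quarter and coldest-quarter
#' mean temperatures over a species' range: by default
#' `mean(bio10 over occupied cells) - mean(bio11 over occupied cells)`
#' (`mode = "range_mean_diff"`); `mode = "cell_diff_mean"` instead averages
#' the cell-wise `bio10 - bio11` differences. The two coincide whenever the
#' same cells carry both layers, as here.
#'
#' @inheritParams estimate_sti
#' @param mode `"range_mean_diff"` (default) or `"cell_diff_mean"`.
#' @return Data.frame (`species`, `niche_breadth`, `n_records`) with the same
#'   `"excluded"` attribute convention as [estimate_sti()].
#' @export
estimate_niche_breadth <- function(records, grid, min_records = 5,
                                   cells = TRUE,
                                   mode = c("range_mean_diff",
                                            "cell_diff_mean")) {
  mode <- match.arg(mode)
  for (ly in c("bio10", "bio11"))
    if (!ly %in% names(grid$layers))
      stop("grid lacks layer '", ly, "' required for niche breadth",
           call. = FALSE)
  m10 <- species_layer_mean(records, grid, "bio10", cells = cells)
  m11 <- species_layer_mean(records, grid, "bio11", cells = cells)
  if (mode == "cell_diff_mean") {
    diff_grid <- grid
    diff_grid$layers$bio_diff <- grid$layers$bio10 - grid$layers$bio11
    md <- species_layer_mean(records, diff_grid, "bio_diff", cells = cells)
  }
  base <- estimate_sti(records, grid, min_records = min_records,
                       cells = cells)
  breadth <- if (mode == "range_mean_diff")
    as.numeric(m10[base$species] - m11[base$species])
  else as.numeric(md[base$species])
  out <- data.frame(species = base$species, niche_breadth = breadth,
                    n_records = base$n_records, stringsAsFactors = FALSE)
  attr(out, "excluded") <- attr(base, "excluded")
  out
}

#' Build complete thermal profiles (STI + breadth) from occurrences
#'
#' @inheritParams estimate_niche_breadth
#' @return Data.frame (`species`, `sti`, `niche_breadth`, `n_records`,
#'   `provenance`) with the `"excluded"` attribute of [estimate_sti()].
#' @export
build_thermal_profiles <- function(records, grid, min_records = 5,
                                   cells = TRUE,
                                   mode = "range_mean_diff") {
  sti <- estimate_sti(records, grid, min_records = min_records, cells = cells)
  br <- estimate_niche_breadth(records, grid, min_records = min_records,
                               cells = cells, mode = mode)
  out <- merge(sti, br[c("species", "niche_breadth")], by = "species",
               sort = FALSE)
  out <- out[c("species", "sti", "niche_breadth", "n_records", "provenance")]
  attr(out, "excluded") <- attr(sti, "excluded")
  out
}

#' Aggregate STIs to genus-level and species-complex entries
#'
#' Taxa reported only at genus level, or as morphologically inseparable
#' species complexes, receive the unweighted mean STI (and niche breadth) of
#' their profiled members. Aggregate entries are appended to the profile
#' table under the genus / complex label with provenance `"genus_mean"` /
#' `"complex_mean"`; complexes with zero profiled members get no entry and
#' are reported in the `"skipped"` attribute.
#'
#' @param profiles Profile table from [build_thermal_profiles()] (or
#'   [estimate_sti()]; breadth column optional).
#' @param taxonomy Optional data.frame `species`, `genus`; defaults to the
#'   first word of the binomial.
#' @param complexes Optional data.frame `complex`, `species` listing member
#'   species of each complex label.
#' @return Profile table with appended aggregate rows; attribute `"skipped"`
#'   lists labels with no profiled members.
#' @export
aggregate_sti <- function(profiles, taxonomy = NULL, complexes = NULL) {
  has_breadth <- "niche_breadth" %in% names(profiles)
  agg_rows <- function(labels, members, provenance) {
    parts <- lapply(unique(labels), function(lb) {
      sp <- members[labels == lb]
      sub <- profiles[profiles$species %in% sp &
                        profiles$provenance == "species", , drop = FALSE]
      if (!nrow(sub)) return(NULL)
      data.frame(species = lb, sti = mean(sub$sti),
                 niche_breadth = if (has_breadth) mean(sub$niche_breadth)
                 else NA_real_,
                 n_records = sum(sub$n_records),
                 provenance = provenance, stringsAsFactors = FALSE)
    })
    list(rows = do.call(rbind, parts),
         skipped = unique(labels)[vapply(parts, is.null, TRUE)])
  }
  out <- profiles
  if (!has_breadth) out$niche_breadth <- NA_real_
  out <- out[c("species", "sti", "niche_breadth", "n_records", "provenance")]
  skipped <- character()
  if (is.null(taxonomy) || is.null(taxonomy$genus)) {
    sp_rows <- out$provenance == "species"
    taxonomy <- data.frame(species = out$species[sp_rows],
                           genus = vapply(strsplit(out$species[sp_rows], " "),
                                          `[`, "", 1L),
                           stringsAsFactors = FALSE)
  }
  g <- agg_rows(taxonomy$genus, taxonomy$species, "genus_mean")
  if (!is.null(g$rows)) out <- rbind(out, g$rows)
  skipped <- c(skipped, g$skipped)
  if (!is.null(complexes)) {
    cx <- agg_rows(complexes$complex, complexes$species, "complex_mean")
    if (!is.null(cx$rows)) out <- rbind(out, cx$rows)
    skipped <- c(skipped, cx$skipped)
  }
  rownames(out) <- NULL
  if (!has_breadth) out$niche_breadth <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Temporal stability of STI estimates
#'
#' Splits occurrence records into year bins (defaults: up to 1990, 1991-2000,
#' 2001-2010, after 2010), re-estimates STIs independently per bin, and
#' returns the pairwise Pearson correlations over the species profiled in
#' both bins — a check that range shifts over the record period are not
#' driving the STI estimates.
#'
#' @inheritParams estimate_sti
#' @param bin_edges Interior bin edges (years); records with year `<=` edge 1
#'   fall in bin 1, etc. Records without a year are dropped.
#' @return List: `correlation` (pairwise Pearson r matrix, `NA` when fewer
#'   than 3 shared species), `n_shared` (shared species counts), `sti_by_bin`
#'   (wide data.frame of per-bin STIs).
#' @export
sti_temporal_stability <- function(records, grid,
                                   bin_edges = c(1990, 2000, 2010),
                                   min_records = 5, cells = TRUE) {
  records <- records[!is.na(records$year), , drop = FALSE]
  edges <- c(-Inf, sort(bin_edges), Inf)
  labels <- character(length(edges) - 1L)
  for (b in seq_along(labels)) {
    labels[b] <- if (b == 1L) sprintf("<=%d", bin_edges[1L])
    else if (b == length(labels)) sprintf(">%d", bin_edges[length(bin_edges)])
    else sprintf("%d-%d", bin_edges[b - 1L] + 1L, bin_edges[b])
  }
  bin <- cut(records$year, edges, labels = labels)
  per_bin <- lapply(labels, function(lb) {
    sub <- records[!is.na(bin) & bin == lb, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    estimate_sti(sub, grid, min_records = min_records, cells = cells)
  })
  names(per_bin) <- labels
  all_sp <- sort(unique(unlist(lapply(per_bin, function(p) p$species))))
  wide <- data.frame(species = all_sp, stringsAsFactors = FALSE)
  for (lb in labels) {
    p <- per_bin[[lb]]
    wide[[lb]] <- if (is.null(p)) NA_real_
    else p$sti[match(all_sp, p$species)]
  }
  nb <- length(labels)
  r <- matrix(NA_real_, nb, nb, dimnames = list(labels, labels))
  n_sh <- matrix(0L, nb, nb, dimnames = list(labels, labels))
  for (a in seq_len(nb)) for (b in seq_len(nb)) {
    shared <- !is.na(wide[[labels[a]]]) & !is.na(wide[[labels[b]]])
    n_sh[a, b] <- sum(shared)
    if (a != b && sum(shared) >= 3L &&
        stats::sd(wide[[labels[a]]][shared]) > 0 &&
        stats::sd(wide[[labels[b]]][shared]) > 0)
      r[a, b] <- stats::cor(wide[[labels[a]]][shared],
                            wide[[labels[b]]][shared])
    if (a == b && sum(shared) > 0) r[a, b] <- 1
  }
  list(correlation = r, n_shared = n_sh, sti_by_bin = wide)
}
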