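#' Classify species fates across time transitions
#'
#' For each pair of consecutive *sampled* years (calendar gaps allowed), each
#' species is `persisted` (present in both years), `added` (present only in
#' the later year) or `lost` (extirpated; present only in the earlier year).
#' The three sets are pairwise disjoint; persisted + added is the later
#' year's community and persisted + lost the earlier year's. Transitions
#' from or to an empty species set are skipped.
#'
#' @param sets Named list of character vectors of species, as from
#'   [species_sets()]; names are years.
#' @return List of transitions; each has `year_from`, `year_to`, `persisted`,
#'   `added`, `lost`.
#' @examples
#' tr <- classify_fates(list(`2000` = c("A", "B", "C"),
#'                           `2001` = c("B", "C", "D")))
#' tr[[1]]$added  # "D"
#' @export
classify_fates <- function(sets) {
  yrs <- as.integer(names(sets))
  ord <- order(yrs)
  sets <- sets[ord]; yrs <- yrs[ord]
  out <- list()
  for (i in seq_len(length(sets) - 1L)) {
    a <- unique(sets[[i]]); b <- unique(sets[[i + 1L]])
    if (!length(a) || !length(b)) next
    out[[length(out) + 1L]] <- list(
      year_from = yrs[i], year_to = yrs[i + 1L],
      persisted = sort(intersect(a, b)),
      added = sort(setdiff(b, a)),
      lost = sort(setdiff(a, b)))
  }
  out
}

# mean STI of a species group, NA when no member has a profile
group_mean_sti <- function(species, sti_lookup) {
  if (!length(species)) return(NA_real_)
  v <- sti_lookup[species]
  if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
}

#' Mean-STI fate contrasts of one site
#'
#' Per transition, computes the three pairwise differences in group mean STI
#' — added - persisted, added - lost, lost - persisted — each defined only
#' when both groups are non-empty (and contain at least one profiled
#' species). The site-level value of each contrast is its mean over the
#' transitions where it is defined; a contrast never defined is `NA`.
#'
#' @param transitions Output of [classify_fates()].
#' @param profiles Thermal profile table (`species`, `sti`).
#' @return List: `per_transition` (data.frame with one row per transition),
#'   `site` (named numeric: `added_persisted`, `added_lost`,
#'   `lost_persisted`).
#' @export
fate_sti_contrasts <- function(transitions, profiles) {
  sti_lookup <- stats::setNames(profiles$sti, profiles$species)
  rows <- lapply(transitions, function(tr) {
    m_p <- group_mean_sti(tr$persisted, sti_lookup)
    m_a <- group_mean_sti(tr$added, sti_lookup)
    m_l <- group_mean_sti(tr$lost, sti_lookup)
    data.frame(year_from = tr$year_from, year_to = tr$year_to,
               added_persisted = m_a - m_p,
               added_lost = m_a - m_l,
               lost_persisted = m_l - m_p)
  })
  per <- do.call(rbind, rows)
  if (is.null(per))
    per <- data.frame(year_from = integer(), year_to = integer(),
                      added_persisted = numeric(), added_lost = numeric(),
                      lost_persisted = numeric())
  site <- vapply(c("added_persisted", "added_lost", "lost_persisted"),
                 function(nm) {
                   v <- per[[nm]]
                   if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
                 }, numeric(1L))
  list(per_transition = per, site = site)
}

#' Per-site fate contrasts for a whole dataset
#'
#' Runs [classify_fates()] and [fate_sti_contrasts()] on every site's pooled
#' per-year species sets.
#'
#' @param observations Community observations (long format).
#' @param profiles Thermal profile table.
#' @return Data.frame: `site_id`, `n_transitions`, `added_persisted`,
#'   `added_lost`, `lost_persisted`.
#' @export
fate_contrast_table <- function(observations, profiles) {
  parts <- lapply(split(observations, observations$site_id), function(o) {
    tr <- classify_fates(species_sets(o))
    if (!length(tr)) return(NULL)
    fc <- fate_sti_contrasts(tr, profiles)
    data.frame(site_id = o$site_id[1L], n_transitions = length(tr),
               added_persisted = fc$site[["added_persisted"]],
               added_lost = fc$site[["added_lost"]],
               lost_persisted = fc$site[["lost_persisted"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  if (is.null(out))
    out <- data.frame(site_id = character(), n_transitions = integer(),
                      added_persisted = numeric(), added_lost = numeric(),
                      lost_persisted = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' One-sided exact sign test at probability 0.5
#'
#' Tests whether values fall above (or below) zero more often than a fair
#' coin predicts. Zeros carry evidence for neither direction and are dropped;
#' with n nonzero values of which k match the direction, the p-value is the
#' exact binomial upper tail P(X >= k | n, 1/2). The exact tail (not a normal
#' approximation) matters because group sizes can be small.
#'
#' @param values Numeric vector (site-level contrasts); `NA` dropped.
#' @param direction `"above"` or `"below"` zero.
#' @return List: `k`, `n`, `p_value` (`NA` when n = 0), `direction`.
#' @examples
#' sign_binomial_test(c(rep(1, 8), rep(-1, 2)), "above")$p_value  # 0.0546875
#' @export
sign_binomial_test <- function(values, direction = c("above", "below")) {
  direction <- match.arg(direction)
  v <- values[is.finite(values) & values != 0]
  n <- length(v)
  k <- if (direction == "above") sum(v > 0) else sum(v < 0)
  p <- if (n == 0L) NA_real_
  else stats::pbinom(k - 1L, n, 0.5, lower.tail = FALSE)
  list(k = k, n = n, p_value = p, direction = direction)
}

#' Group-level summary of fate contrasts
#'
#' For each group (e.g. taxon group or realm) and each contrast, runs the
#' one-sided sign test in both directions and reports the smaller-p
#' direction — the style of summary behind per-panel significance marks.
#'
#' @param contrasts Output of [fate_contrast_table()] merged with a grouping
#'   column.
#' @param group Name of the grouping column.
#' @return Data.frame: group, `contrast`, `direction`, `k`, `n`, `p_value`.
#' @export
fate_summary <- function(contrasts, group = "taxon_group") {
  cn <- c("added_persisted", "added_lost", "lost_persisted")
  parts <- list()
  for (g in unique(contrasts[[group]])) {
    sub <- contrasts[contrasts[[group]] == g, , drop = FALSE]
    for (nm in cn) {
      up <- sign_binomial_test(sub[[nm]], "above")
      dn <- sign_binomial_test(sub[[nm]], "below")
      best <- if (!is.na(up$p_value) && (is.na(dn$p_value) ||
                                         up$p_value <= dn$p_value)) up else dn
      parts[[length(parts) + 1L]] <- data.frame(
        group = g, contrast = nm, direction = best$direction,
        k = best$k, n = best$n, p_value = best$p_value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, parts)
  names(out)[1L] <- group
  out
}
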