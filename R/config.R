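#' Analysis configuration
#'
#' Bundles the thresholds used throughout the pipeline: community inclusion
#' filters, rarefaction replication, the minimum occurrence-record count for a
#' species-level thermal profile, the residual-outlier cutoff for the driver
#' models and the predictor-collinearity warning level.
#'
#' @param min_species Minimum number of distinct species a community must
#'   contain over its whole series (default 4).
#' @param min_span_years Minimum series span in years, last year minus first
#'   year (default 5).
#' @param min_sti_coverage Minimum fraction of a community's species that must
#'   have a thermal profile (default 0.75).
#' @param min_year Observations before this calendar year are dropped
#'   (default 1980).
#' @param n_rarefaction_reps Number of resampling replicates for effort
#'   standardisation; must be odd so the median is an attained value
#'   (default 99).
#' @param min_sti_records Minimum retained occurrence records for a
#'   species-level STI (default 5).
#' @param outlier_sd Residual-outlier cutoff, in standard deviations, for the
#'   one-pass refit of the driver models (default 2).
#' @param correlation_warn Absolute pairwise predictor correlation above which
#'   a collinearity warning is raised (default 0.7).
#' @param rng_seed Integer seed used where a stage needs randomness and no
#'   explicit seed is given.
#'
#' @return A list of class `"analysis_config"`.
#' @examples
#' cfg <- analysis_config(min_species = 4, n_rarefaction_reps = 9)
#' cfg$min_sti_coverage
#' @export
analysis_config <- function(min_species = 4,
                            min_span_years = 5,
                            min_sti_coverage = 0.75,
                            min_year = 1980,
                            n_rarefaction_reps = 99,
                            min_sti_records = 5,
                            outlier_sd = 2,
                            correlation_warn = 0.7,
                            rng_seed = 1L) {
  cfg <- list(
    min_species = min_species,
    min_span_years = min_span_years,
    min_sti_coverage = min_sti_coverage,
    min_year = min_year,
    n_rarefaction_reps = as.integer(n_rarefaction_reps),
    min_sti_records = min_sti_records,
    outlier_sd = outlier_sd,
    correlation_warn = correlation_warn,
    rng_seed = as.integer(rng_seed)
  )
  num <- c("min_species", "min_span_years", "min_sti_coverage", "min_year",
           "n_rarefaction_reps", "min_sti_records", "outlier_sd",
           "correlation_warn")
  for (nm in num) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("analysis_config: '", nm, "' must be a single positive number",
           call. = FALSE)
  }
  if (cfg$n_rarefaction_reps %% 2L == 0L)
    stop("analysis_config: 'n_rarefaction_reps' must be odd so the median ",
         "across replicates is an attained value", call. = FALSE)
  if (cfg$min_sti_coverage > 1)
    stop("analysis_config: 'min_sti_coverage' is a fraction in (0, 1]",
         call. = FALSE)
  class(cfg) <- "analysis_config"
  cfg
}

#' Read / write a flat key-value configuration file
#'
#' The file holds one `key value` pair per line (whitespace separated, `#`
#' comments allowed); keys mirror the arguments of [analysis_config()].
#'
#' @param path File path.
#' @return `read_config()` returns an `analysis_config`; `write_config()`
#'   returns `path` invisibly.
#' @seealso [analysis_config()]
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "[[:space:]=]+")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  args <- as.list(as.numeric(vals))
  names(args) <- keys
  known <- names(formals(analysis_config))
  bad <- setdiff(keys, known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(analysis_config, args)
}

#' @rdname read_config
#' @param config An `analysis_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  lines <- sprintf("%s %s", names(config),
                   vapply(unclass(config), format, "", digits = 17))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration:\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}
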