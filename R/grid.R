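#' Regular latitude-longitude temperature grid
#'
#' A stack of equally shaped raster layers on a regular geographic grid,
#' indexed from the north-west origin. Climatological layers are keyed
#' `"bio01"` (annual mean), `"bio10"` (warmest-quarter mean) and `"bio11"`
#' (coldest-quarter mean); per-year annual-mean layers are keyed
#' `"annual_<year>"`. Cells are half-open in both axes: a point on a shared
#' edge belongs to the cell to the south/east. Missing cells are `NA`, never
#' a silent zero.
#'
#' @param origin_lat,origin_lon North-west corner of the grid, decimal degrees
#'   WGS84.
#' @param cell_size Cell edge length in degrees (> 0).
#' @param layers Named list of numeric matrices, all the same dimension, in
#'   degrees Celsius, rows running north to south.
#'
#' @return An object of class `"temperature_grid"`.
#' @examples
#' g <- temperature_grid(10, 0, 1, list(bio01 = matrix(1:4, 2, byrow = TRUE)))
#' locate_cell(g, 9.5, 0.5)
#' @export
temperature_grid <- function(origin_lat, origin_lon, cell_size, layers) {
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number", call. = FALSE)
  if (!is.list(layers) || length(layers) == 0L || is.null(names(layers)) ||
      any(!nzchar(names(layers))))
    stop("layers must be a non-empty named list of matrices", call. = FALSE)
  dims <- unique(lapply(layers, dim))
  if (length(dims) != 1L || any(!vapply(layers, is.matrix, TRUE)))
    stop("all layers must be matrices sharing one shape", call. = FALSE)
  g <- structure(
    list(origin_lat = origin_lat, origin_lon = origin_lon,
         cell_size = cell_size,
         n_rows = dims[[1L]][1L], n_cols = dims[[1L]][2L],
         layers = layers),
    class = "temperature_grid")
  g
}

#' @export
print.temperature_grid <- function(x, ...) {
  cat(sprintf("temperature_grid: %d x %d cells of %g deg, NW origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_lat, x$origin_lon))
  cat("layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

annual_layer_name <- function(year) sprintf("annual_%d", as.integer(year))

#' Years with an annual-mean layer
#' @param grid A [temperature_grid()].
#' @return Sorted integer vector of years.
#' @export
grid_years <- function(grid) {
  nm <- names(grid$layers)
  sort(as.integer(sub("^annual_", "", nm[startsWith(nm, "annual_")])))
}

#' Locate grid cells for points
#'
#' Maps WGS84 points onto 1-based (row, col) grid indices using the half-open
#' cell convention: a point exactly on a shared edge belongs to the cell to
#' the south (rows) / east (cols) of that edge. Points outside the grid extent
#' map to `NA` rather than raising an error.
#'
#' @param grid A [temperature_grid()].
#' @param latitude,longitude Numeric vectors, decimal degrees (recycled to a
#'   common length).
#' @return A data.frame with integer columns `row` and `col` (`NA` when out of
#'   extent).
#' @export
locate_cell <- function(grid, latitude, longitude) {
  n <- max(length(latitude), length(longitude))
  latitude <- rep_len(latitude, n)
  longitude <- rep_len(longitude, n)
  row <- floor((grid$origin_lat - latitude) / grid$cell_size) + 1
  col <- floor((longitude - grid$origin_lon) / grid$cell_size) + 1
  bad <- !is.finite(row) | !is.finite(col) |
    row < 1 | row > grid$n_rows | col < 1 | col > grid$n_cols
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Extract layer values at points or cells
#'
#' @param grid A [temperature_grid()].
#' @param layer Layer name, e.g. `"bio01"` or `annual_layer_name(year)`.
#' @param row,col 1-based cell indices as returned by [locate_cell()].
#' @return Numeric vector of cell values (`NA` for out-of-extent indices or
#'   no-data cells).
#' @export
grid_values <- function(grid, layer, row, col) {
  if (!layer %in% names(grid$layers))
    stop("grid has no layer '", layer, "'", call. = FALSE)
  m <- grid$layers[[layer]]
  out <- rep(NA_real_, length(row))
  ok <- !is.na(row) & !is.na(col)
  out[ok] <- m[cbind(row[ok], col[ok])]
  out
}

#' Per-year annual-mean temperature series at a point
#'
#' @param grid A [temperature_grid()] carrying `annual_<year>` layers.
#' @param latitude,longitude Point coordinates (single point).
#' @param years Years to extract; defaults to all years present.
#' @return Data.frame with columns `year` and `temperature`.
#' @export
annual_series <- function(grid, latitude, longitude, years = grid_years(grid)) {
  cell <- locate_cell(grid, latitude, longitude)
  temp <- vapply(years, function(y)
    grid_values(grid, annual_layer_name(y), cell$row, cell$col), numeric(1L))
  data.frame(year = as.integer(years), temperature = temp)
}

#' Read / write a temperature grid in the plain-text dialect
#'
#' The self-describing text format keeps fixtures diffable: a header of
#' `origin_lat`, `origin_lon`, `cell_size`, `n_rows`, `n_cols` lines, then one
#' `layer <name>` line per layer followed by `n_rows` lines of `n_cols`
#' whitespace-separated values (north to south, west to east), `NA` marking
#' no-data cells. Values round-trip at full double precision.
#'
#' @param path File path.
#' @return `read_temperature_grid()` returns a [temperature_grid()];
#'   `write_temperature_grid()` returns `path` invisibly.
#' @export
read_temperature_grid <- function(path) {
  if (!file.exists(path)) stop("grid file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && !startsWith(lines[i], "layer")) {
    kv <- strsplit(lines[i], "[[:space:]]+")[[1L]]
    hdr[[kv[1L]]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  need <- c("origin_lat", "origin_lon", "cell_size", "n_rows", "n_cols")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("grid header missing: ", paste(miss, collapse = ", "), call. = FALSE)
  nr <- as.integer(hdr$n_rows); nc <- as.integer(hdr$n_cols)
  layers <- list()
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "layer"))
      stop("expected 'layer <name>' at line ", i, call. = FALSE)
    nm <- strsplit(lines[i], "[[:space:]]+")[[1L]][2L]
    if (i + nr > length(lines))
      stop("layer '", nm, "': declared ", nr, " rows but file ends early",
           call. = FALSE)
    vals <- lapply(lines[(i + 1L):(i + nr)], function(l)
      suppressWarnings(as.numeric(strsplit(l, "[[:space:]]+")[[1L]])))
    if (any(lengths(vals) != nc))
      stop("layer '", nm, "': declared ", nc, " columns but a row differs",
           call. = FALSE)
    layers[[nm]] <- matrix(unlist(vals), nrow = nr, ncol = nc, byrow = TRUE)
    i <- i + nr + 1L
  }
  temperature_grid(hdr$origin_lat, hdr$origin_lon, hdr$cell_size, layers)
}

#' @rdname read_temperature_grid
#' @param grid A [temperature_grid()].
#' @export
write_temperature_grid <- function(grid, path) {
  stopifnot(inherits(grid, "temperature_grid"))
  fmt <- function(x) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- "NA"
    out
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("origin_lat %.17g", grid$origin_lat),
    sprintf("origin_lon %.17g", grid$origin_lon),
    sprintf("cell_size %.17g", grid$cell_size),
    sprintf("n_rows %d", grid$n_rows),
    sprintf("n_cols %d", grid$n_cols)), con)
  for (nm in names(grid$layers)) {
    writeLines(paste("layer", nm), con)
    m <- grid$layers[[nm]]
    writeLines(apply(m, 1L, function(r) paste(fmt(r), collapse = " ")), con)
  }
  invisible(path)
}
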