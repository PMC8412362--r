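#' Read and write single-layer grids as ESRI ASCII rasters
#'
#' Static attribute layers and per-cell result maps (trend slopes, zone
#' labels, change intensity) are exchanged as ESRI ASCII grids (`.asc`),
#' a plain-text raster format with a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows
#' of values from the northernmost row down. Row 1 of the grid table is
#' the northernmost row; the header is the single source of
#' georeferencing truth.
#'
#' @param x A tibble with columns `row`, `col` and the value column; every
#'   (row, col) of the grid must appear exactly once. `NA` is written as
#'   the nodata value.
#' @param path Output/input file path.
#' @param value Name of the value column (default `"value"`).
#' @param xll,yll,cellsize Georeferencing of the lower-left corner and the
#'   square cell size, in map units.
#' @param nodata Nodata sentinel written to file.
#' @return `read_ascii_grid()` returns a tibble with `cell`, `row`, `col`,
#'   `x`, `y` (cell centers) and `value`, with the header stored in the
#'   `grid` attribute; `write_ascii_grid()` returns `path` invisibly.
#' @examples
#' g <- tidyr::expand_grid(row = 1:2, col = 1:3)
#' g$value <- seq_len(6) / 7
#' f <- tempfile(fileext = ".asc")
#' write_ascii_grid(g, f, cellsize = 100)
#' read_ascii_grid(f)
#' @export
write_ascii_grid <- function(x, path, value = "value",
                             xll = 0, yll = 0, cellsize = 1,
                             nodata = -9999) {
  stopifnot(all(c("row", "col", value) %in% names(x)))
  nr <- max(x$row)
  nc <- max(x$col)
  if (nrow(x) != nr * nc || anyDuplicated(x[c("row", "col")])) {
    abort("Grid table must contain each (row, col) exactly once")
  }
  m <- matrix(NA_real_, nr, nc)
  m[cbind(x$row, x$col)] <- x[[value]]
  m[is.na(m)] <- nodata
  header <- c(
    paste("ncols", nc),
    paste("nrows", nr),
    paste("xllcorner", format(xll, digits = 17)),
    paste("yllcorner", format(yll, digits = 17)),
    paste("cellsize", format(cellsize, digits = 17)),
    paste("NODATA_value", format(nodata, digits = 17))
  )
  rows <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  header <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    header[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  for (key in c("ncols", "nrows")) {
    if (is.null(header[[key]])) abort(paste0("ASCII grid missing ", key))
  }
  nodata <- header[["nodata_value"]] %||% -9999
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  nr <- header$nrows
  nc <- header$ncols
  if (length(vals) != nr * nc) {
    abort(sprintf("Expected %d values, found %d", nr * nc, length(vals)))
  }
  m <- matrix(vals, nr, nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  xll <- header[["xllcorner"]] %||% 0
  yll <- header[["yllcorner"]] %||% 0
  cs <- header[["cellsize"]] %||% 1
  out <- tidyr::expand_grid(row = seq_len(nr), col = seq_len(nc))
  out$cell <- seq_len(nrow(out))
  out$x <- xll + (out$col - 0.5) * cs
  out$y <- yll + (nr - out$row + 0.5) * cs
  out$value <- m[cbind(out$row, out$col)]
  out <- out[c("cell", "row", "col", "x", "y", "value")]
  attr(out, "grid") <- list(nrows = nr, ncols = nc, xllcorner = xll,
                            yllcorner = yll, cellsize = cs)
  out
}

#' Matrix-backed daily forcing for grids
#'
#' For grid-scale runs the long forcing table becomes memory-hungry;
#' `wb_grid_forcing()` carries the same information as day-by-cell
#' matrices. Column `j` of each matrix is the series of the `j`-th row of
#' `cells`. [wb_run()] accepts either representation; results are
#' identical.
#'
#' @param dates Daily `Date` vector (rows of the matrices).
#' @param tmin,tmax,prcp Numeric matrices, `length(dates)` rows and one
#'   column per cell.
#' @param cells Integer or character vector of cell ids, one per column.
#' @param calendar `"gregorian"` or `"noleap"`; must match `dates`.
#' @return An object of class `wb_grid_forcing`.
#' @export
wb_grid_forcing <- function(dates, tmin, tmax, prcp, cells,
                            calendar = c("gregorian", "noleap")) {
  calendar <- match.arg(calendar)
  nd <- length(dates)
  ncell <- length(cells)
  for (nm in c("tmin", "tmax", "prcp")) {
    m <- get(nm)
    if (!is.matrix(m) || nrow(m) != nd || ncol(m) != ncell) {
      abort(sprintf("%s must be a %d x %d matrix", nm, nd, ncell))
    }
  }
  check_daily_index(dates, calendar)
  ok <- !is.na(tmax) & !is.na(tmin)
  if (any(tmax[ok] < tmin[ok])) abort("tmax < tmin in grid forcing")
  if (any(prcp < 0, na.rm = TRUE)) abort("Negative precipitation")
  structure(
    list(dates = dates, tmin = tmin, tmax = tmax, prcp = prcp,
         cells = cells, calendar = calendar),
    class = "wb_grid_forcing"
  )
}

#' @export
print.wb_grid_forcing <- function(x, ...) {
  cat(sprintf("<wb_grid_forcing> %d days x %d cells (%s calendar), %s .. %s\n",
              length(x$dates), length(x$cells), x$calendar,
              format(min(x$dates)), format(max(x$dates))))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @method as_tibble wb_grid_forcing
#' @export
as_tibble.wb_grid_forcing <- function(x, ...) {
  tibble::tibble(
    cell = rep(x$cells, each = length(x$dates)),
    date = rep(x$dates, times = length(x$cells)),
    tmin = as.vector(x$tmin),
    tmax = as.vector(x$tmax),
    prcp = as.vector(x$prcp)
  )
}

# Convert a long wb_forcing tibble to the matrix carrier, preserving
# cell order of first appearance.
as_grid_forcing <- function(forcing, calendar = NULL) {
  if (inherits(forcing, "wb_grid_forcing")) return(forcing)
  f <- wb_forcing(forcing, calendar = calendar %||% "auto")
  cal <- attr(f, "calendar")
  cells <- unique(f$cell)
  dates <- sort(unique(f$date))
  nd <- length(dates)
  if (nrow(f) != nd * length(cells)) {
    abort("All cells must share the same daily index")
  }
  shape <- function(v) matrix(v, nrow = nd)
  # arrange(cell, date) in wb_forcing guarantees column-major fill,
  # but unique() order of cells must match the sorted order used there
  ord <- order(match(f$cell, cells), f$date)
  wb_grid_forcing(dates,
                  tmin = shape(f$tmin[ord]),
                  tmax = shape(f$tmax[ord]),
                  prcp = shape(f$prcp[ord]),
                  cells = cells, calendar = cal)
}
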