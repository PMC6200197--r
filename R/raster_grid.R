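#' Create a raster grid
#'
#' The single aligned grid type used throughout the package: the DEM, its
#' derivatives (slope, aspect, TPI), kriged factor layers, probability and
#' class maps all share this representation. Coordinates are a local planar
#' system in metres; no geodetic transforms are performed. The origin is the
#' outer corner of the upper-left (north-west) cell, rows run north to south,
#' and a cell's value refers to its centre. `NA` marks nodata.
#'
#' @param values numeric matrix, `n_rows x n_cols`; `NA` is nodata.
#' @param x_origin,y_origin outer NW corner of the grid, metres.
#' @param cell_size cell edge length in metres (default 0.1).
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, x_origin = 0, y_origin = nrow(values) * cell_size,
                        cell_size = 0.1) {
  if (!is.matrix(values)) values <- as.matrix(values)
  stopifnot(is.numeric(cell_size), length(cell_size) == 1L)
  if (!is.finite(cell_size) || cell_size <= 0)
    stop("cell_size must be a positive number")
  storage.mode(values) <- "double"
  structure(
    list(values = values, x_origin = as.numeric(x_origin),
         y_origin = as.numeric(y_origin), cell_size = as.numeric(cell_size)),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<raster_grid> %d rows x %d cols, cell %g m\n", nrow(v), ncol(v),
              x$cell_size))
  cat(sprintf("  origin (NW corner): (%g, %g) m\n", x$x_origin, x$y_origin))
  ok <- is.finite(v)
  cat(sprintf("  valid cells: %d / %d", sum(ok), length(v)))
  if (any(ok))
    cat(sprintf("; range [%g, %g]", min(v[ok]), max(v[ok])))
  cat("\n")
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' Cell-centre coordinates of a raster grid
#'
#' @param grid a [raster_grid].
#' @return `cell_centers_x` gives the x coordinate of each column (west to
#'   east); `cell_centers_y` the y coordinate of each row (north to south).
#' @export
cell_centers_x <- function(grid) {
  grid$x_origin + (seq_len(ncol(grid$values)) - 0.5) * grid$cell_size
}

#' @rdname cell_centers_x
#' @export
cell_centers_y <- function(grid) {
  grid$y_origin - (seq_len(nrow(grid$values)) - 0.5) * grid$cell_size
}

#' Do two grids share origin, cell size and shape?
#'
#' @param a,b [raster_grid] objects.
#' @param tol numeric tolerance on origins and cell size, metres.
#' @export
grids_aligned <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$x_origin - b$x_origin) <= tol &&
    abs(a$y_origin - b$y_origin) <= tol &&
    abs(a$cell_size - b$cell_size) <= tol
}

stop_if_misaligned <- function(a, b, what = "grids") {
  if (!grids_aligned(a, b))
    stop(sprintf("%s are not aligned: they must share origin, cell size and shape",
                 what))
  invisible(TRUE)
}

## Build a grid of the same georeference with new values.
grid_like <- function(template, values) {
  raster_grid(values, template$x_origin, template$y_origin, template$cell_size)
}

#' Write a raster grid as an ESRI ASCII grid
#'
#' Plain-text `.asc` format: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#' values from the northernmost row down.
#'
#' @param grid a [raster_grid].
#' @param path output file path.
#' @param nodata value written for `NA` cells.
#' @param digits significant digits to print.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999, digits = 10) {
  v <- grid$values
  yll <- grid$y_origin - nrow(v) * grid$cell_size
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", grid$x_origin),
    sprintf("yllcorner %.10g", yll),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %g", nodata)
  )
  vv <- v
  vv[!is.finite(vv)] <- nodata
  body <- apply(vv, 1L, function(r) paste(formatC(r, digits = digits, format = "g"),
                                          collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path path to a `.asc` file.
#' @return a [raster_grid]; nodata cells become `NA`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 7L) stop("not an ESRI ASCII grid: file too short")
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(kv) != 2L) stop("malformed ESRI ASCII header line: ", lines[i])
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) stop("ESRI ASCII header missing: ", paste(miss, collapse = ", "))
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop(sprintf("ESRI ASCII body has %d values, header implies %d",
                 length(vals), nr * nc))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  raster_grid(m, hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize, hdr$cellsize)
}
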