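#' Grid scattered elevation points into a DEM
#'
#' Builds a fine-resolution digital elevation model from scattered (x, y, z)
#' survey points by linear interpolation on the Delaunay triangulation (a
#' TIN), sampled at cell centres. Cells outside the convex hull of the
#' points are nodata. The grid origin is the min-x / max-y corner of the
#' point bounding box.
#'
#' @param points data frame with numeric columns `x`, `y`, `z` (metres).
#' @param cell_size cell edge in metres; default 0.1.
#' @return a [raster_grid] DEM.
#' @export
grid_dem <- function(points, cell_size = 0.1) {
  need <- c("x", "y", "z")
  miss <- setdiff(need, names(points))
  if (length(miss)) stop("points table missing column(s): ", paste(miss, collapse = ", "))
  pts <- points[, need]
  if (!all(vapply(pts, is.numeric, TRUE)) || !all(is.finite(as.matrix(pts))))
    stop("point coordinates must be finite numerics")
  if (nrow(pts) < 3L) stop("need at least 3 points to triangulate")
  ## collinearity: every point on one line => zero max triangle cross product
  dx <- pts$x - pts$x[1L]; dy <- pts$y - pts$y[1L]
  cross <- abs(dx[2L] * dy - dy[2L] * dx)
  if (max(cross) <= 1e-12 * max(1, max(abs(dx)), max(abs(dy))))
    stop("points are collinear; cannot triangulate")

  x0 <- min(pts$x); y1 <- max(pts$y)
  ncols <- max(1L, ceiling((max(pts$x) - x0) / cell_size))
  nrows <- max(1L, ceiling((y1 - min(pts$y)) / cell_size))
  xo <- x0 + (seq_len(ncols) - 0.5) * cell_size
  yo <- y1 - (seq_len(nrows) - 0.5) * cell_size
  res <- interp::interp(pts$x, pts$y, pts$z, xo = xo, yo = sort(yo),
                        method = "linear", duplicate = "mean",
                        output = "grid")
  ## interp returns z[i, j] at (xo[i], sorted yo[j]); transpose to row-major
  ## from the north and flip so row 1 is the northernmost row
  m <- t(res$z)[rev(seq_len(nrows)), , drop = FALSE]
  raster_grid(m, x0, y1, cell_size)
}

## value[i, j] <- m[i + di, j + dj], NA-padded at the edges
shift_mat <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  ri <- seq_len(nr) + di; cj <- seq_len(nc) + dj
  keep_r <- ri >= 1L & ri <= nr
  keep_c <- cj >= 1L & cj <= nc
  out[keep_r, keep_c] <- m[ri[keep_r], cj[keep_c]]
  out
}

## Horn 3x3 gradient; returns east (gx) and north (gy) slope components.
## Cells on the border or adjacent to nodata are NA.
horn_gradient <- function(dem) {
  v <- dem$values
  if (nrow(v) < 3L || ncol(v) < 3L)
    stop("DEM too small: Horn gradient needs at least a 3x3 grid")
  cs <- dem$cell_size
  nb <- list(
    a = shift_mat(v, -1L, -1L), b = shift_mat(v, -1L, 0L), c = shift_mat(v, -1L, 1L),
    d = shift_mat(v,  0L, -1L),                            f = shift_mat(v,  0L, 1L),
    g = shift_mat(v,  1L, -1L), h = shift_mat(v,  1L, 0L), i = shift_mat(v,  1L, 1L)
  )
  gx <- ((nb$c + 2 * nb$f + nb$i) - (nb$a + 2 * nb$d + nb$g)) / (8 * cs)
  gy <- ((nb$a + 2 * nb$b + nb$c) - (nb$g + 2 * nb$h + nb$i)) / (8 * cs)
  bad <- !is.finite(v)
  for (m in nb) bad <- bad | !is.finite(m)
  gx[bad] <- NA_real_; gy[bad] <- NA_real_
  list(gx = gx, gy = gy)
}

#' Slope of a DEM (degrees)
#'
#' Horn 3x3 finite-difference gradient; slope is
#' `atan(sqrt((dz/dx)^2 + (dz/dy)^2))` in degrees. Border cells and cells
#' adjacent to nodata are nodata.
#'
#' @param dem a [raster_grid] DEM.
#' @return a [raster_grid] of slope in degrees.
#' @export
compute_slope <- function(dem) {
  g <- horn_gradient(dem)
  grid_like(dem, atan(sqrt(g$gx^2 + g$gy^2)) * 180 / pi)
}

#' Aspect of a DEM (degrees clockwise from north)
#'
#' Downslope azimuth from the Horn gradient, in `[0, 360)` degrees measured
#' clockwise from north. Cells with zero gradient carry the flat flag `-1`.
#'
#' @param dem a [raster_grid] DEM.
#' @return a [raster_grid]; flat cells are `-1`, nodata is `NA`.
#' @export
compute_aspect <- function(dem) {
  g <- horn_gradient(dem)
  az <- (atan2(-g$gx, -g$gy) * 180 / pi) %% 360
  flat <- is.finite(g$gx) & g$gx == 0 & g$gy == 0
  az[flat] <- -1
  grid_like(dem, az)
}

#' Reclassify aspect into four insolation codes
#'
#' Sunny slope (135-225 degrees) = 4, half-sunny (45-135) = 3, half-shady
#' (225-315) = 2, shady (0-45 and 315-360) = 1. Boundary values belong to
#' the higher-numbered band (135 is sunny, 45 half-sunny, 225 half-shady,
#' 315 half-shady). Flat-flagged cells get the shady code 1.
#'
#' @param aspect a [raster_grid] from [compute_aspect()].
#' @return a [raster_grid] of codes 1-4.
#' @export
reclassify_aspect <- function(aspect) {
  a <- aspect$values
  ok <- is.finite(a)
  if (any(ok & (a < -1 - 1e-12 | a > 360)))
    stop("aspect values must lie in [0, 360] or be the flat flag -1")
  out <- matrix(NA_real_, nrow(a), ncol(a))
  flat <- ok & a == -1
  shady <- ok & !flat & ((a >= 0 & a < 45) | (a > 315 & a <= 360))
  halfsunny <- ok & !flat & a >= 45 & a < 135
  sunny <- ok & !flat & a >= 135 & a <= 225
  halfshady <- ok & !flat & a > 225 & a <= 315
  out[flat | shady] <- 1
  out[halfshady] <- 2
  out[halfsunny] <- 3
  out[sunny] <- 4
  grid_like(aspect, out)
}

#' Topographic position index
#'
#' For each cell, the raw TPI is the cell elevation minus the mean elevation
#' of all valid cells whose centres lie within `radius` of it (the focal cell
#' itself excluded by default). The standardized TPI divides the raw TPI by
#' the standard deviation of those neighbourhood elevations, so the
#' landform-classification thresholds are expressed in SD units. Cells whose
#' neighbourhood SD is zero get standardized TPI 0; cells with fewer than 3
#' valid neighbours are nodata.
#'
#' @param dem a [raster_grid] DEM.
#' @param radius neighbourhood radius in metres; must be at least
#'   `2 * cell_size`. Default 1 m.
#' @param exclude_focal drop the focal cell from the neighbourhood mean/SD
#'   (default `TRUE`).
#' @param standardize `"neighborhood"` (default) divides by the local
#'   neighbourhood SD; `"global"` divides by the SD of all valid DEM cells.
#' @return a [raster_grid] of standardized TPI with the raw TPI attached as
#'   attribute `"raw"`.
#' @export
compute_tpi <- function(dem, radius = 1.0, exclude_focal = TRUE,
                        standardize = c("neighborhood", "global")) {
  standardize <- match.arg(standardize)
  cs <- dem$cell_size
  if (radius < 2 * cs)
    stop("TPI radius must be at least twice the cell size")
  v <- dem$values
  mu0 <- mean(v[is.finite(v)])
  vc <- v - mu0                       # centre for numerical stability
  valid <- is.finite(vc)
  vz <- vc; vz[!valid] <- 0

  k <- floor(radius / cs)
  offs <- expand.grid(di = -k:k, dj = -k:k)
  offs <- offs[(offs$di^2 + offs$dj^2) * cs^2 <= radius^2 + 1e-12, ]
  if (exclude_focal) offs <- offs[!(offs$di == 0 & offs$dj == 0), ]

  n <- s <- ss <- matrix(0, nrow(v), ncol(v))
  for (r in seq_len(nrow(offs))) {
    sv <- shift_mat(vz, offs$di[r], offs$dj[r])
    sm <- shift_mat(valid + 0, offs$di[r], offs$dj[r])
    sm[is.na(sm)] <- 0
    sv[sm == 0] <- 0
    n <- n + sm
    s <- s + sv
    ss <- ss + sv^2
  }
  mean_nb <- s / n
  raw <- vc - mean_nb
  var_nb <- (ss - s^2 / n) / (n - 1)
  var_nb[var_nb < 0] <- 0
  sd_nb <- sqrt(var_nb)

  if (standardize == "global") sd_use <- stats::sd(vc[valid]) else sd_use <- sd_nb
  std <- raw / sd_use
  std[sd_use == 0] <- 0
  bad <- !valid | n < 3
  std[bad] <- NA_real_
  raw[bad] <- NA_real_
  out <- grid_like(dem, std)
  attr(out, "raw") <- grid_like(dem, raw)
  out
}

#' Microtopography class legend
#'
#' @return data frame of class codes 1-6 and names, valley through ridge.
#' @export
microtopo_classes <- function() {
  data.frame(code = 1:6,
             name = c("valley", "lower_slope", "flat_slope", "middle_slope",
                      "upper_slope", "ridge"))
}

#' Classify microtopography from standardized TPI and slope
#'
#' Six-class landform scheme on the (TPI, slope) plane, TPI in SD units:
#' valley `tpi <= -0.3`; lower slope `-0.3 < tpi <= -0.05`; flat slope
#' `-0.05 < tpi <= 0.15` and slope `<= 7` degrees; middle slope
#' `-0.05 < tpi <= 0.15` and slope `> 7`; upper slope `0.15 < tpi <= 0.4`;
#' ridge `tpi > 0.4`. The bands are exhaustive and mutually exclusive, with
#' "<=" on every upper bound.
#'
#' @param tpi_std standardized TPI [raster_grid] from [compute_tpi()].
#' @param slope slope [raster_grid] in degrees from [compute_slope()].
#' @param breaks numeric vector of the four TPI cuts (valley, lower, upper,
#'   ridge), default `c(-0.3, -0.05, 0.15, 0.4)`.
#' @param slope_cut slope threshold in degrees separating flat from middle
#'   slope; default 7.
#' @return a [raster_grid] of class codes 1-6 with the legend attached as
#'   attribute `"legend"`; class `microtopo_map`.
#' @export
classify_microtopography <- function(tpi_std, slope,
                                     breaks = c(-0.3, -0.05, 0.15, 0.4),
                                     slope_cut = 7) {
  stop_if_misaligned(tpi_std, slope, "TPI and slope grids")
  stopifnot(length(breaks) == 4L, !is.unsorted(breaks))
  t <- tpi_std$values; s <- slope$values
  out <- matrix(NA_real_, nrow(t), ncol(t))
  okt <- is.finite(t)
  out[okt & t <= breaks[1L]] <- 1
  out[okt & t > breaks[1L] & t <= breaks[2L]] <- 2
  mid <- okt & t > breaks[2L] & t <= breaks[3L]
  oks <- is.finite(s)
  out[mid & oks & s <= slope_cut] <- 3
  out[mid & oks & s > slope_cut] <- 4
  out[mid & !oks] <- NA_real_
  out[okt & t > breaks[3L] & t <= breaks[4L]] <- 5
  out[okt & t > breaks[4L]] <- 6
  g <- grid_like(tpi_std, out)
  attr(g, "legend") <- microtopo_classes()
  class(g) <- c("microtopo_map", class(g))
  g
}

#' Rasterize polygons onto a template grid
#'
#' Centre-point rule: a cell is 1 iff its centre lies inside any polygon
#' (exterior minus holes, even-odd rule), else 0. Nodata cells of the
#' template stay nodata. An empty polygon set gives an all-zero grid.
#'
#' @param polys a [patch_polygons] object.
#' @param template a [raster_grid] supplying the georeference and mask.
#' @return a binary [raster_grid].
#' @export
rasterize_polygons <- function(polys, template) {
  nr <- nrow(template$values); nc <- ncol(template$values)
  out <- matrix(0, nr, nc)
  cx <- cell_centers_x(template); cy <- cell_centers_y(template)
  for (p in polys$polygons) {
    allx <- c(p$exterior[, 1L], unlist(lapply(p$holes, function(h) h[, 1L])))
    ally <- c(p$exterior[, 2L], unlist(lapply(p$holes, function(h) h[, 2L])))
    jj <- which(cx >= min(allx) & cx <= max(allx))
    ii <- which(cy >= min(ally) & cy <= max(ally))
    if (!length(ii) || !length(jj)) next
    px <- rep(cx[jj], each = length(ii))
    py <- rep(cy[ii], times = length(jj))
    hit <- points_in_polygon(px, py, p)
    sub <- matrix(hit, nrow = length(ii), ncol = length(jj))
    out[ii, jj] <- pmax(out[ii, jj], sub + 0)
  }
  out[!is.finite(template$values)] <- NA_real_
  grid_like(template, out)
}

## Shared area accounting: counts of cells per class -> areas + percentages.
area_table <- function(counts, cell_size, labels) {
  area <- counts * cell_size^2
  total <- sum(area)
  pct <- if (total > 0) 100 * area / total else rep(NA_real_, length(area))
  data.frame(class = labels, n_cells = as.integer(counts), area_m2 = area,
             percentage = pct, row.names = NULL)
}

#' Areas and percentages of microtopography classes under a mask
#'
#' Counts cells of each landform class whose mask value is 1 (for example a
#' rasterized species-patch layer), converts counts to areas via the cell
#' size, and reports each class's percentage of the total masked area.
#' Percentages sum to 100 when the mask is non-empty; with an empty mask the
#' areas are zero and percentages are `NA` (flagged via the
#' `"empty_mask"` attribute).
#'
#' @param classes a microtopography class [raster_grid].
#' @param mask optional binary [raster_grid]; `NULL` uses every valid cell.
#' @return data frame with columns `class`, `name`, `n_cells`, `area_m2`,
#'   `percentage`.
#' @export
overlay_class_areas <- function(classes, mask = NULL) {
  v <- classes$values
  if (!is.null(mask)) {
    stop_if_misaligned(classes, mask, "class and mask grids")
    keep <- is.finite(mask$values) & mask$values == 1
  } else {
    keep <- is.finite(v)
  }
  leg <- attr(classes, "legend")
  if (is.null(leg)) leg <- microtopo_classes()
  counts <- vapply(leg$code, function(k) sum(v[keep] == k, na.rm = TRUE), 0)
  out <- area_table(counts, classes$cell_size, leg$code)
  out <- cbind(class = out$class, name = leg$name, out[, -1L])
  attr(out, "empty_mask") <- sum(counts) == 0
  out
}
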