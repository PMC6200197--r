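#' Patch polygons
#'
#' A light container for simple planar polygons (species patch borders,
#' level-trench footprints): a list of polygons, each with an exterior ring
#' and optional holes. Rings are two-column matrices of (x, y) vertices in
#' metres; the closing vertex is implicit.
#'
#' @param polys list of polygons; each either a two-column matrix (exterior
#'   only) or a list with elements `exterior` (matrix) and `holes` (list of
#'   matrices).
#' @return an object of class `patch_polygons`.
#' @export
patch_polygons <- function(polys = list()) {
  norm_ring <- function(r) {
    r <- as.matrix(r)
    if (ncol(r) != 2L) stop("polygon rings must be two-column (x, y) matrices")
    storage.mode(r) <- "double"
    n <- nrow(r)
    if (n >= 2L && all(r[1L, ] == r[n, ])) r <- r[-n, , drop = FALSE]
    if (nrow(r) < 3L) stop("polygon rings need at least 3 distinct vertices")
    if (!all(is.finite(r))) stop("polygon rings must have finite coordinates")
    r
  }
  polys <- lapply(polys, function(p) {
    if (is.matrix(p) || is.data.frame(p)) p <- list(exterior = p, holes = list())
    if (is.null(p$holes)) p$holes <- list()
    p$exterior <- norm_ring(p$exterior)
    p$holes <- lapply(p$holes, norm_ring)
    if (ring_area(p$exterior) <= 0 && abs(shoelace(p$exterior)) <= 0)
      stop("polygon has zero area")
    p
  })
  structure(list(polygons = polys), class = "patch_polygons")
}

#' @export
length.patch_polygons <- function(x) length(x$polygons)

#' @export
print.patch_polygons <- function(x, ...) {
  cat(sprintf("<patch_polygons> %d polygon(s), total area %.4f m^2\n",
              length(x), polygon_area(x)))
  invisible(x)
}

## Signed shoelace area of an open ring.
shoelace <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  sum(x * ys - xs * y) / 2
}

ring_area <- function(ring) abs(shoelace(ring))

#' Total area of patch polygons
#'
#' Shoelace area of each exterior ring minus its holes, summed.
#' @param polys a [patch_polygons] object.
#' @return area in m^2.
#' @export
polygon_area <- function(polys) {
  if (length(polys) == 0L) return(0)
  sum(vapply(polys$polygons, function(p) {
    ring_area(p$exterior) - sum(vapply(p$holes, ring_area, 0))
  }, 0))
}

## Even-odd ray-casting point-in-ring test, vectorized over points.
points_in_ring <- function(px, py, ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  n <- nrow(ring)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((y[i] > py) != (y[j] > py))
    if (any(crosses)) {
      xint <- x[i] + (py[crosses] - y[i]) * (x[j] - x[i]) / (y[j] - y[i])
      hit <- which(crosses)[px[crosses] < xint]
      inside[hit] <- !inside[hit]
    }
    j <- i
  }
  inside
}

## Points inside polygon p = exterior minus holes (even-odd rule).
points_in_polygon <- function(px, py, p) {
  inside <- points_in_ring(px, py, p$exterior)
  for (h in p$holes) inside <- inside & !points_in_ring(px, py, h)
  inside
}

#' Write patch polygons as GeoJSON
#'
#' Polygons are written as a `FeatureCollection` of `Polygon` features in the
#' local planar coordinate system (metres).
#'
#' @param polys a [patch_polygons] object.
#' @param path output file path.
#' @export
write_geojson <- function(polys, path) {
  close_ring <- function(r) rbind(r, r[1L, , drop = FALSE])
  feats <- lapply(polys$polygons, function(p) {
    rings <- c(list(close_ring(p$exterior)), lapply(p$holes, close_ring))
    list(
      type = "Feature",
      properties = stats::setNames(list(), character(0)),
      geometry = list(
        type = "Polygon",
        coordinates = lapply(rings, function(r) {
          lapply(seq_len(nrow(r)), function(i) c(r[i, 1L], r[i, 2L]))
        })
      )
    )
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read patch polygons from GeoJSON
#'
#' Accepts `Polygon` and `MultiPolygon` features; the first ring of each
#' polygon is the exterior, further rings are holes.
#'
#' @param path path to a GeoJSON file.
#' @return a [patch_polygons] object.
#' @export
read_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  geoms <- switch(
    g$type %||% "",
    FeatureCollection = lapply(g$features, function(f) f$geometry),
    Feature = list(g$geometry),
    Polygon = ,
    MultiPolygon = list(g),
    stop("unsupported GeoJSON type: ", g$type %||% "<missing>")
  )
  ring_mat <- function(r)
    do.call(rbind, lapply(r, function(pt) c(pt[[1L]], pt[[2L]])))
  polys <- list()
  for (geom in geoms) {
    coords <- switch(geom$type,
                     Polygon = list(geom$coordinates),
                     MultiPolygon = geom$coordinates,
                     stop("unsupported geometry type: ", geom$type))
    for (poly in coords) {
      rings <- lapply(poly, ring_mat)
      polys[[length(polys) + 1L]] <-
        list(exterior = rings[[1L]], holes = rings[-1L])
    }
  }
  patch_polygons(polys)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
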