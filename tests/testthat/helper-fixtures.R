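## Shared in-code fixtures; everything is generated, nothing read from disk.

## Random survey points on the plane z = a*x + b*y + c over [0,ext]^2.
plane_points <- function(n = 60, a = 2, b = 3, c = 1, ext = 5, seed = 1) {
  set.seed(seed)
  x <- c(0, ext, 0, ext, runif(n - 4, 0, ext))
  y <- c(0, 0, ext, ext, runif(n - 4, 0, ext))
  data.frame(x = x, y = y, z = a * x + b * y + c)
}

## A small synthetic site shared across test files, built once on demand.
.site_cache <- new.env(parent = emptyenv())
small_site <- function() {
  if (!is.null(.site_cache$site)) return(.site_cache$site)
  ts <- terrain_spec(extent_x = 10, extent_y = 10, n_gullies = 2,
                     n_points = 900, seed = 42)
  pts <- generate_terrain(ts)
  dem <- grid_dem(pts, 0.1)
  slope <- compute_slope(dem)
  aspect <- compute_aspect(dem)
  tpi <- compute_tpi(dem, 1.0)
  microtopo <- classify_microtopography(tpi, slope)
  fields <- generate_factor_fields(dem, tpi, seed = 43)
  resp <- response_spec(seed = 44)
  presence <- generate_presence(fields, resp)
  stack <- factor_stack(c(list(altitude = dem, slope = slope,
                               aspect_class = reclassify_aspect(aspect)),
                          fields$layers))
  train <- build_training(presence, stack)
  .site_cache$site <- list(spec = ts, points = pts, dem = dem, slope = slope,
                           aspect = aspect, tpi = tpi, microtopo = microtopo,
                           fields = fields, resp = resp, presence = presence,
                           stack = stack, train = train)
  .site_cache$site
}

## Independent even-odd point-in-polygon oracle (scalar, naive loop).
pip_oracle <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- FALSE
  for (i in seq_len(n)) {
    j <- if (i == 1) n else i - 1
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if ((yi > py) != (yj > py)) {
      xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
      if (px < xint) inside <- !inside
    }
  }
  inside
}
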