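## All generators draw their randomness through one explicit seed argument;
## the caller's RNG state is saved and restored.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Synthetic terrain specification
#'
#' Parameters of the synthetic gullied hillslope used to exercise the whole
#' pipeline without field data: a planar hillslope with sinusoidal
#' cross-slope ridges and valleys (gullies running downslope), surveyed by
#' quasi-uniform scattered points with GPS-like elevation noise. The
#' defaults emulate a ~576 m^2 site surveyed with 3,358 points, three
#' gullies, and 0.05 m elevation noise (half the nominal +-0.1 m accuracy
#' of a survey-grade GPS).
#'
#' @param extent_x,extent_y site extent in metres (> 0).
#' @param n_gullies number of full ridge/valley cycles across `extent_x`
#'   (>= 1).
#' @param ridge_amplitude half-height of the ridges above the valleys,
#'   metres.
#' @param base_slope dimensionless gradient of the underlying hillslope
#'   (rise northward per metre).
#' @param noise_sd SD of Gaussian elevation noise, metres (>= 0).
#' @param n_points number of survey points (>= 10).
#' @param min_spacing minimum distance between survey points, metres.
#' @param seed RNG seed.
#' @return an object of class `terrain_spec`.
#' @export
terrain_spec <- function(extent_x = 24, extent_y = 24, n_gullies = 3,
                         ridge_amplitude = 1.2, base_slope = 0.25,
                         noise_sd = 0.05, n_points = 3358,
                         min_spacing = 0.05, seed = 1) {
  if (!is.finite(extent_x) || !is.finite(extent_y) || extent_x <= 0 || extent_y <= 0)
    stop("invalid terrain spec: extents must be positive")
  if (n_gullies < 1) stop("invalid terrain spec: n_gullies must be >= 1")
  if (noise_sd < 0) stop("invalid terrain spec: noise_sd must be >= 0")
  if (n_points < 10) stop("invalid terrain spec: need at least 10 survey points")
  structure(list(extent_x = extent_x, extent_y = extent_y,
                 n_gullies = n_gullies, ridge_amplitude = ridge_amplitude,
                 base_slope = base_slope, noise_sd = noise_sd,
                 n_points = n_points, min_spacing = min_spacing, seed = seed),
            class = "terrain_spec")
}

## Surface without noise: hillslope + cosine ridges (ridges at x = 0 and
## x = extent_x when n_gullies = 1, valley in between).
terrain_surface <- function(spec, x, y) {
  spec$base_slope * y +
    spec$ridge_amplitude * cos(2 * pi * spec$n_gullies * x / spec$extent_x)
}

#' Generate scattered elevation survey points
#'
#' Scatters `n_points` quasi-uniformly over the extent (uniform proposals
#' thinned by a minimum-spacing rejection rule so the later triangulation is
#' well conditioned) and evaluates the synthetic surface plus Gaussian
#' noise. Deterministic given the spec's seed.
#'
#' @param spec a [terrain_spec].
#' @return data frame with columns `x`, `y`, `z` (metres).
#' @export
generate_terrain <- function(spec) {
  stopifnot(inherits(spec, "terrain_spec"))
  with_seed(spec$seed, {
    s <- max(spec$min_spacing, 1e-6)
    kept_x <- numeric(0); kept_y <- numeric(0)
    cells <- new.env(parent = emptyenv())
    tries <- 0L
    while (length(kept_x) < spec$n_points && tries < 50L) {
      tries <- tries + 1L
      m <- 2L * (spec$n_points - length(kept_x))
      cx <- stats::runif(m, 0, spec$extent_x)
      cy <- stats::runif(m, 0, spec$extent_y)
      for (i in seq_len(m)) {
        ix <- floor(cx[i] / s); iy <- floor(cy[i] / s)
        ok <- TRUE
        for (dx in -1:1) for (dy in -1:1) {
          key <- paste(ix + dx, iy + dy)
          idx <- cells[[key]]
          if (!is.null(idx) &&
              any((kept_x[idx] - cx[i])^2 + (kept_y[idx] - cy[i])^2 < s^2)) {
            ok <- FALSE
            break
          }
        }
        if (ok) {
          kept_x <- c(kept_x, cx[i]); kept_y <- c(kept_y, cy[i])
          key <- paste(ix, iy)
          cells[[key]] <- c(cells[[key]], length(kept_x))
          if (length(kept_x) >= spec$n_points) break
        }
      }
    }
    if (length(kept_x) < spec$n_points)
      stop("could not place ", spec$n_points, " points at min spacing ",
           s, " m; reduce n_points or min_spacing")
    z <- terrain_surface(spec, kept_x, kept_y)
    if (spec$noise_sd > 0) z <- z + stats::rnorm(length(z), 0, spec$noise_sd)
    data.frame(x = kept_x, y = kept_y, z = z)
  })
}

#' Default synthetic factor-field configuration
#'
#' One row per environmental factor (8 soil + 18 microclimate): the field
#' mean, the half-range `amplitude` of its gradient across the terrain, the
#' `direction` of that gradient with respect to the topographic position
#' index (+1 increases valley to ridge, -1 decreases), and the SD of the
#' cell-level noise around the gradient. Means, amplitudes and directions
#' follow the magnitudes and valley-to-ridge trends typical of gullied
#' red-soil sites (cooler, moister, more fertile valleys); the noise SD
#' defaults to 0.8 x amplitude so that factors sharing the topographic
#' gradient remain statistically distinguishable.
#'
#' @return data frame with columns `name`, `mean`, `amplitude`,
#'   `direction`, `noise_sd`.
#' @export
default_factor_config <- function() {
  cfg <- rbind(
    data.frame(name = "organic_matter", valley = 9.04,  ridge = 1.89),
    data.frame(name = "total_n",        valley = 0.58,  ridge = 0.21),
    data.frame(name = "available_n",    valley = 55.47, ridge = 24.21),
    data.frame(name = "total_p",        valley = 0.09,  ridge = 0.13),
    data.frame(name = "available_p",    valley = 0.09,  ridge = 0.04),
    data.frame(name = "total_k",        valley = 1.98,  ridge = 2.15),
    data.frame(name = "available_k",    valley = 18.11, ridge = 5.28),
    data.frame(name = "ph",             valley = 4.41,  ridge = 4.61),
    data.frame(name = "ut_max_spring",  valley = 26.98, ridge = 32.05),
    data.frame(name = "ut_min_spring",  valley = 16.38, ridge = 15.88),
    data.frame(name = "ut_avg_spring",  valley = 20.42, ridge = 21.97),
    data.frame(name = "ut_max_summer_autumn", valley = 34.20, ridge = 40.26),
    data.frame(name = "ut_min_summer_autumn", valley = 23.31, ridge = 23.02),
    data.frame(name = "ut_avg_summer_autumn", valley = 26.99, ridge = 28.87),
    data.frame(name = "ut_max_winter",  valley = 23.21, ridge = 27.61),
    data.frame(name = "ut_min_winter",  valley = 8.37,  ridge = 8.59),
    data.frame(name = "ut_avg_winter",  valley = 13.47, ridge = 14.26),
    data.frame(name = "um_max_spring",  valley = 30.09, ridge = 21.41),
    data.frame(name = "um_min_spring",  valley = 12.93, ridge = 8.30),
    data.frame(name = "um_avg_spring",  valley = 15.67, ridge = 10.89),
    data.frame(name = "um_max_summer_autumn", valley = 23.86, ridge = 19.93),
    data.frame(name = "um_min_summer_autumn", valley = 16.08, ridge = 8.62),
    data.frame(name = "um_avg_summer_autumn", valley = 18.96, ridge = 12.10),
    data.frame(name = "um_max_winter",  valley = 8.61,  ridge = 13.23),
    data.frame(name = "um_min_winter",  valley = 6.03,  ridge = 10.28),
    data.frame(name = "um_avg_winter",  valley = 7.33,  ridge = 11.50)
  )
  data.frame(
    name = cfg$name,
    mean = (cfg$valley + cfg$ridge) / 2,
    amplitude = abs(cfg$ridge - cfg$valley) / 2,
    direction = ifelse(cfg$ridge >= cfg$valley, 1, -1),
    noise_sd = 0.8 * abs(cfg$ridge - cfg$valley) / 2
  )
}

#' Generate environmental factor fields from the terrain
#'
#' Each factor layer is an affine function of the z-scored standardized TPI
#' with the sign given by its direction, plus independent Gaussian cell
#' noise: `factor = mean + direction * amplitude * tpi_z + noise`. With zero
#' noise a layer is therefore an exact monotone (affine) function of TPI,
#' and its Spearman correlation with TPI equals its direction.
#'
#' @param dem,tpi aligned [raster_grid]s (the DEM and its standardized TPI).
#' @param config factor table as from [default_factor_config()]; columns
#'   `name`, `mean`, `amplitude`, `direction` (+1/-1), `noise_sd`.
#' @param seed RNG seed.
#' @return a [factor_stack] of the configured factors.
#' @export
generate_factor_fields <- function(dem, tpi, config = default_factor_config(),
                                   seed = 1) {
  stop_if_misaligned(dem, tpi, "DEM and TPI grids")
  stopifnot(all(c("name", "mean", "amplitude", "direction", "noise_sd") %in%
                  names(config)))
  if (!all(config$direction %in% c(-1, 1)))
    stop("every factor needs a direction of +1 or -1")
  t <- tpi$values
  ok <- is.finite(t)
  tz <- t
  tz[ok] <- (t[ok] - mean(t[ok])) / stats::sd(t[ok])
  with_seed(seed, {
    layers <- list()
    for (i in seq_len(nrow(config))) {
      v <- config$mean[i] + config$direction[i] * config$amplitude[i] * tz
      if (config$noise_sd[i] > 0) {
        eps <- matrix(stats::rnorm(length(v), 0, config$noise_sd[i]),
                      nrow(v), ncol(v))
        v <- v + eps
      }
      v[!ok] <- NA_real_
      layers[[config$name[i]]] <- grid_like(dem, v)
    }
    factor_stack(layers)
  })
}

#' Ground-truth response specification
#'
#' The known logistic response used to generate synthetic presence data:
#' cellwise presence probability is
#' `plogis(intercept + sum(coef * zscore(factor)))`. Coefficients act on
#' z-scored factor layers, so they are comparable to the standardized
#' coefficients reported by [fit_sdm()] and support parameter-recovery
#' tests. The default response prefers valley conditions (cool growing
#' season soil temperatures, moist springs, nitrogen-rich soil) and its
#' intercept is set for a realistic site-level prevalence of roughly a
#' quarter of the cells.
#'
#' @param coefficients named numeric vector (logit scale, per z-scored
#'   factor); at least one must be nonzero.
#' @param intercept logit-scale intercept.
#' @param seed RNG seed for the Bernoulli draws.
#' @return an object of class `response_spec`.
#' @export
response_spec <- function(coefficients = c(ut_avg_summer_autumn = -2.5,
                                           um_avg_spring = 1.5,
                                           ut_min_spring = 1.2,
                                           ut_max_spring = -1.2,
                                           total_n = 1.0),
                          intercept = -5, seed = 1) {
  if (is.null(names(coefficients)) || any(names(coefficients) == ""))
    stop("response coefficients must be named by factor")
  if (all(coefficients == 0))
    stop("at least one response coefficient must be nonzero")
  structure(list(coefficients = coefficients, intercept = intercept,
                 seed = seed), class = "response_spec")
}

#' Generate a synthetic presence raster
#'
#' Draws cellwise Bernoulli presence from the logistic response of
#' [response_spec()] evaluated on z-scored factor layers. Reproducible
#' under the spec's seed.
#'
#' @param factors a [factor_stack].
#' @param resp a [response_spec]; every coefficient name must be a factor in
#'   the stack.
#' @return binary [raster_grid] with the probability layer attached as
#'   attribute `"probability"`.
#' @export
generate_presence <- function(factors, resp) {
  stopifnot(inherits(resp, "response_spec"))
  miss <- setdiff(names(resp$coefficients), names(factors))
  if (length(miss))
    stop("response names factor(s) absent from the stack: ",
         paste(miss, collapse = ", "))
  tmpl <- factors$layers[[1L]]
  eta <- matrix(resp$intercept, nrow(tmpl$values), ncol(tmpl$values))
  for (f in names(resp$coefficients)) {
    v <- factors$layers[[f]]$values
    ok <- is.finite(v)
    z <- v
    z[ok] <- (v[ok] - mean(v[ok])) / stats::sd(v[ok])
    eta <- eta + resp$coefficients[[f]] * z
  }
  p <- 1 / (1 + exp(-eta))
  with_seed(resp$seed, {
    draw <- matrix(NA_real_, nrow(p), ncol(p))
    ok <- is.finite(p)
    draw[ok] <- stats::rbinom(sum(ok), 1L, p[ok])
    out <- grid_like(tmpl, draw)
    attr(out, "probability") <- grid_like(tmpl, p)
    out
  })
}

#' Stratified field-sampling design
#'
#' Places sampling points stratified by merged microtopography class
#' (valley = valley; slope = lower/flat/middle/upper slope; ridge = ridge)
#' and by gully type. Gully types split the site across its x extent
#' (western half `"with"`, eastern half `"without"` the species), emulating
#' paired gullies with and without established patches. The default design
#' is 9 points x 3 classes x 2 gully types = 54 points.
#'
#' @param microtopo microtopography class [raster_grid].
#' @param n_per_class points per class-by-type stratum; default 9.
#' @param classes merged classes to sample; default
#'   `c("valley", "slope", "ridge")`.
#' @param gully_types stratum labels across the x extent; default
#'   `c("with", "without")`.
#' @param seed RNG seed.
#' @return data frame `x`, `y`, `microtopo`, `gully_type`.
#' @export
generate_sampling_design <- function(microtopo, n_per_class = 9,
                                     classes = c("valley", "slope", "ridge"),
                                     gully_types = c("with", "without"),
                                     seed = 1) {
  class_codes <- list(valley = 1, lower_slope = 2, flat_slope = 3,
                      middle_slope = 4, upper_slope = 5, ridge = 6,
                      slope = 2:5)
  bad <- setdiff(classes, names(class_codes))
  if (length(bad)) stop("unknown microtopography class(es): ",
                        paste(bad, collapse = ", "))
  v <- microtopo$values
  cx <- cell_centers_x(microtopo); cy <- cell_centers_y(microtopo)
  nr <- nrow(v)
  xmid <- microtopo$x_origin + ncol(v) * microtopo$cell_size / 2
  with_seed(seed, {
    rows <- list()
    for (gt in seq_along(gully_types)) {
      for (cl in classes) {
        idx <- which(is.finite(v) & matrix(v %in% class_codes[[cl]], nr))
        px <- cx[(idx - 1L) %/% nr + 1L]
        if (length(gully_types) == 2L)
          idx <- idx[if (gt == 1L) px < xmid else px >= xmid]
        if (length(idx) < n_per_class)
          stop(sprintf(
            "sampling design error: class '%s' (%s) has %d cells, need %d",
            cl, gully_types[gt], length(idx), n_per_class))
        pick <- sample(idx, n_per_class)
        rows[[length(rows) + 1L]] <- data.frame(
          x = cx[(pick - 1L) %/% nr + 1L],
          y = cy[(pick - 1L) %% nr + 1L],
          microtopo = cl, gully_type = gully_types[gt])
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Default synthetic physiology configuration
#'
#' Class-conditional means and SDs of the four plant-performance factors
#' (plant height and above/under/total biomass per unit area), strongly
#' decreasing valley to ridge as observed for fern stands on gullied
#' slopes.
#'
#' @return data frame `name`, `valley`, `slope`, `ridge`, `sd_frac`.
#' @export
default_physiology_config <- function() {
  data.frame(
    name = c("ph_cm", "abpua", "ubpua", "tbpua"),
    valley = c(43.38, 1054.63, 355.24, 1409.86),
    slope = c(25.44, 434.35, 250.38, 684.72),
    ridge = c(11.64, 110.28, 88.80, 199.08),
    sd_frac = 0.25
  )
}

#' Sample a factor table at design points
#'
#' Extracts every stack layer at the sampling-design locations and
#' optionally appends synthetic plant-physiology measurements drawn from
#' class-conditional normals (truncated at a small positive floor).
#'
#' @param design data frame from [generate_sampling_design()].
#' @param stack a [factor_stack].
#' @param physiology optional config from [default_physiology_config()].
#' @param seed RNG seed for the physiology draws.
#' @return data frame: design columns, one column per factor, physiology
#'   columns if requested.
#' @export
sample_factor_table <- function(design, stack, physiology = NULL, seed = 1) {
  tmpl <- stack$layers[[1L]]
  j <- pmin(pmax(ceiling((design$x - tmpl$x_origin) / tmpl$cell_size), 1L),
            ncol(tmpl$values))
  i <- pmin(pmax(ceiling((tmpl$y_origin - design$y) / tmpl$cell_size), 1L),
            nrow(tmpl$values))
  out <- design
  for (f in names(stack))
    out[[f]] <- stack$layers[[f]]$values[cbind(i, j)]
  if (!is.null(physiology)) {
    merged <- ifelse(design$microtopo %in%
                       c("lower_slope", "flat_slope", "middle_slope",
                         "upper_slope", "slope"),
                     "slope", design$microtopo)
    out2 <- with_seed(seed, {
      for (r in seq_len(nrow(physiology))) {
        mu <- unlist(physiology[r, c("valley", "slope", "ridge")])[merged]
        val <- stats::rnorm(nrow(out), mu, physiology$sd_frac[r] * mu)
        out[[physiology$name[r]]] <- pmax(val, 0.01 * mu)
      }
      out
    })
    out <- out2
  }
  out
}

#' Generate level-trench footprints
#'
#' Places `n` rectangular trenches (default 4.0 m x 0.5 m, the standard
#' level-trench footprint) centred on random valid DEM cells and oriented
#' along the local elevation contour (perpendicular to the aspect). Trenches
#' must fall inside the grid extent and must not overlap; placement retries
#' are bounded. The default count scales the customary density of 600
#' trenches per hectare to the grid area, rounded to the nearest integer.
#'
#' @param dem a [raster_grid] DEM.
#' @param n number of trenches; `NULL` uses the density default; 0 gives an
#'   empty set.
#' @param length_m,width_m trench footprint, metres.
#' @param density_per_ha trench density used when `n` is `NULL`.
#' @param seed RNG seed.
#' @param max_tries placement attempts per trench before giving up.
#' @return a [patch_polygons] of trench rectangles.
#' @export
generate_trenches <- function(dem, n = NULL, length_m = 4.0, width_m = 0.5,
                              density_per_ha = 600, seed = 1,
                              max_tries = 200) {
  v <- dem$values
  area_m2 <- length(v) * dem$cell_size^2
  if (is.null(n)) n <- round(density_per_ha * area_m2 / 1e4)
  if (n == 0) return(patch_polygons())
  ext_x <- ncol(v) * dem$cell_size
  ext_y <- nrow(v) * dem$cell_size
  if (length_m > sqrt(ext_x^2 + ext_y^2) || width_m > min(ext_x, ext_y))
    stop("trench footprint does not fit the grid extent")
  asp <- compute_aspect(dem)$values
  cand <- which(is.finite(asp))
  if (!length(cand)) stop("no valid cells to place trenches on")
  nr <- nrow(v)
  cx <- cell_centers_x(dem); cy <- cell_centers_y(dem)
  occupied <- matrix(0, nr, ncol(v))
  occ_grid <- grid_like(dem, occupied)
  with_seed(seed, {
    polys <- list()
    for (k in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        idx <- sample(cand, 1L)
        x0 <- cx[(idx - 1L) %/% nr + 1L]
        y0 <- cy[(idx - 1L) %% nr + 1L]
        a <- asp[idx]
        th <- if (a < 0) stats::runif(1, 0, 360) else (a + 90) %% 360
        th <- th * pi / 180
        u <- c(sin(th), cos(th))          # along-contour unit vector
        w <- c(cos(th), -sin(th))         # across-contour unit vector
        h <- outer(c(-1, 1, 1, -1) * length_m / 2, u) +
          outer(c(-1, -1, 1, 1) * width_m / 2, w)
        corners <- sweep(h, 2L, c(x0, y0), "+")
        if (any(corners[, 1L] < dem$x_origin) ||
            any(corners[, 1L] > dem$x_origin + ext_x) ||
            any(corners[, 2L] > dem$y_origin) ||
            any(corners[, 2L] < dem$y_origin - ext_y)) next
        fp <- rasterize_polygons(patch_polygons(list(corners)), occ_grid)
        hit <- is.finite(fp$values) & fp$values == 1
        if (any(occ_grid$values[hit] == 1, na.rm = TRUE)) next
        occ_grid$values[hit] <- 1
        polys[[k]] <- corners
        placed <- TRUE
        break
      }
      if (!placed)
        stop(sprintf(
          "trench placement error: could not place trench %d of %d without overlap after %d tries",
          k, n, max_tries))
    }
    patch_polygons(polys)
  })
}

#' Convert a presence raster to patch polygons
#'
#' Decomposes the presence cells into maximal horizontal runs per row and
#' emits one axis-aligned rectangle per run. The result rasterizes back to
#' exactly the input presence layer under the centre-point rule, giving a
#' lossless polygon representation of synthetic patches.
#'
#' @param presence binary [raster_grid].
#' @return a [patch_polygons] object.
#' @export
presence_to_patches <- function(presence) {
  v <- presence$values
  cs <- presence$cell_size
  polys <- list()
  for (i in seq_len(nrow(v))) {
    row <- is.finite(v[i, ]) & v[i, ] == 1
    if (!any(row)) next
    r <- rle(row)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      x0 <- presence$x_origin + (starts[k] - 1L) * cs
      x1 <- presence$x_origin + ends[k] * cs
      y1 <- presence$y_origin - (i - 1L) * cs
      y0 <- y1 - cs
      polys[[length(polys) + 1L]] <-
        cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
    }
  }
  patch_polygons(polys)
}
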