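test_that("terrain generation is deterministic and validates its spec", {
  ts <- terrain_spec(extent_x = 6, extent_y = 6, n_points = 300, seed = 5)
  p1 <- generate_terrain(ts)
  p2 <- generate_terrain(ts)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 300)
  expect_true(all(p1$x >= 0 & p1$x <= 6 & p1$y >= 0 & p1$y <= 6))
  ## min-spacing rejection rule
  d <- as.matrix(dist(cbind(p1$x, p1$y)))
  diag(d) <- Inf
  expect_gte(min(d), ts$min_spacing)

  expect_error(terrain_spec(extent_x = -1), "positive")
  expect_error(terrain_spec(n_points = 5), "10")
  expect_error(terrain_spec(noise_sd = -0.1), "noise_sd")
  expect_error(terrain_spec(n_gullies = 0), "n_gullies")
})

test_that("a noiseless single-gully surface classifies into one valley and two ridge bands", {
  ts <- terrain_spec(extent_x = 8, extent_y = 8, n_gullies = 1,
                     ridge_amplitude = 1, base_slope = 0.2, noise_sd = 0,
                     n_points = 700, seed = 6)
  pts <- generate_terrain(ts)
  dem <- grid_dem(pts, 0.1)
  tpi <- compute_tpi(dem, 1)
  mt <- classify_microtopography(tpi, compute_slope(dem))
  cx <- cell_centers_x(dem)
  enough <- colSums(is.finite(mt$values)) > 0.3 * nrow(mt$values)
  col_class <- apply(mt$values[, enough, drop = FALSE], 2,
                     function(col) {
                       tab <- table(col)
                       as.numeric(names(tab)[which.max(tab)])
                     })
  cx <- cx[enough]
  r <- rle(col_class)
  ## exactly one contiguous valley band, centred at the cosine trough x = 4
  expect_equal(sum(r$values == 1), 1L)
  expect_true(all(abs(cx[col_class == 1] - 4) < 2))
  ## exactly two ridge bands, one at each x edge (the cosine peaks)
  expect_equal(sum(r$values == 6), 2L)
  expect_equal(r$values[1], 6)
  expect_equal(r$values[length(r$values)], 6)
})

test_that("a flat spec yields only the flat-slope class", {
  ts <- terrain_spec(extent_x = 6, extent_y = 6, ridge_amplitude = 0,
                     base_slope = 0, noise_sd = 0, n_points = 400, seed = 7)
  dem <- grid_dem(generate_terrain(ts), 0.1)
  mt <- classify_microtopography(compute_tpi(dem, 1), compute_slope(dem))
  got <- unique(mt$values[is.finite(mt$values)])
  expect_equal(got, 3)                   # TPI 0 and slope 0 force flat slope
})

test_that("factor fields are affine in TPI with the configured direction", {
  site <- small_site()
  cfg <- data.frame(name = c("up", "down"), mean = c(10, 20),
                    amplitude = c(2, 5), direction = c(1, -1),
                    noise_sd = c(0, 0))
  fs <- generate_factor_fields(site$dem, site$tpi, cfg, seed = 9)
  t <- site$tpi$values
  ok <- is.finite(t)
  tz <- (t[ok] - mean(t[ok])) / sd(t[ok])
  ## zero noise: exact affine functions of standardized TPI
  expect_equal(max(abs(fs$layers$up$values[ok] - (10 + 2 * tz))), 0,
               tolerance = 1e-12)
  expect_equal(max(abs(fs$layers$down$values[ok] - (20 - 5 * tz))), 0,
               tolerance = 1e-12)
  ## Spearman correlation with TPI equals the direction
  expect_equal(cor(fs$layers$up$values[ok], t[ok], method = "spearman"), 1)
  expect_equal(cor(fs$layers$down$values[ok], t[ok], method = "spearman"), -1)
  ## a decreasing factor has valley mean above ridge mean
  valley <- which(site$microtopo$values == 1)
  ridge <- which(site$microtopo$values == 6)
  expect_gt(mean(fs$layers$down$values[valley], na.rm = TRUE),
            mean(fs$layers$down$values[ridge], na.rm = TRUE))
  ## determinism and error contracts
  fs2 <- generate_factor_fields(site$dem, site$tpi, cfg, seed = 9)
  expect_identical(fs$layers$up$values, fs2$layers$up$values)
  expect_error(generate_factor_fields(site$dem, raster_grid(matrix(0, 2, 2)),
                                      cfg), "aligned")
  cfg$direction <- c(1, 0)
  expect_error(generate_factor_fields(site$dem, site$tpi, cfg), "direction")
})

test_that("presence generation follows the logistic response", {
  site <- small_site()
  ## saturated intercept: every valid cell is presence
  sat <- generate_presence(site$fields,
                           response_spec(c(total_n = 1e-9), intercept = 10,
                                         seed = 11))
  ok <- is.finite(sat$values)
  expect_true(all(sat$values[ok] == 1))

  ## null response: empirical prevalence ~ 0.5 (binomial bound at >= 10k cells)
  null <- generate_presence(site$fields,
                            response_spec(c(total_n = 1e-9), intercept = 0,
                                          seed = 12))
  expect_gt(sum(is.finite(null$values)), 9000)
  expect_equal(mean(null$values[is.finite(null$values)]), 0.5,
               tolerance = 0.02)

  ## strong coefficient on a TPI-decreasing factor: valleys hold more presence
  strong <- generate_presence(site$fields,
                              response_spec(c(um_avg_spring = 3),
                                            intercept = -1, seed = 13))
  valley <- which(site$microtopo$values == 1)
  ridge <- which(site$microtopo$values == 6)
  expect_gt(mean(strong$values[valley], na.rm = TRUE),
            mean(strong$values[ridge], na.rm = TRUE))

  ## determinism and error contract
  again <- generate_presence(site$fields,
                             response_spec(c(um_avg_spring = 3),
                                           intercept = -1, seed = 13))
  expect_identical(strong$values, again$values)
  expect_error(generate_presence(site$fields,
                                 response_spec(c(nope = 1))), "absent")
  expect_error(response_spec(c(a = 0)), "nonzero")
})

test_that("sampling designs stratify by class and gully type", {
  site <- small_site()
  d <- generate_sampling_design(site$microtopo, seed = 14)
  expect_equal(nrow(d), 54)                       # 9 x 3 classes x 2 types
  expect_equal(as.vector(table(d$microtopo)), rep(18L, 3))
  expect_equal(as.vector(table(d$gully_type)), rep(27L, 2))
  expect_identical(d, generate_sampling_design(site$microtopo, seed = 14))

  d1 <- generate_sampling_design(site$microtopo, n_per_class = 1, seed = 15)
  expect_equal(nrow(d1), 6)
  expect_error(generate_sampling_design(site$microtopo,
                                        classes = c("valley", "nonsense")),
               "unknown")
  ## a class with no cells raises a design error naming the class
  flat_only <- site$microtopo
  flat_only$values[] <- ifelse(is.finite(site$microtopo$values), 3, NA)
  expect_error(generate_sampling_design(flat_only), "valley")
})

test_that("factor tables sample the stack at the design points", {
  site <- small_site()
  d <- generate_sampling_design(site$microtopo, seed = 16)
  tab <- sample_factor_table(d, site$fields,
                             physiology = default_physiology_config(),
                             seed = 17)
  expect_equal(nrow(tab), 54)
  expect_true(all(default_factor_config()$name %in% names(tab)))
  expect_true(all(c("ph_cm", "abpua", "ubpua", "tbpua") %in% names(tab)))
  ## extracted values equal the layer value at the point's cell
  g <- site$fields$layers$total_n
  i <- ceiling((g$y_origin - tab$y[1]) / g$cell_size)
  j <- ceiling((tab$x[1] - g$x_origin) / g$cell_size)
  expect_equal(tab$total_n[1], g$values[i, j])
  ## physiology decreases valley -> ridge on average
  m <- tapply(tab$ph_cm, tab$microtopo, mean)
  expect_gt(m[["valley"]], m[["ridge"]])
})

test_that("trenches are contour-aligned rectangles of the right area", {
  site <- small_site()
  tr <- generate_trenches(site$dem, n = 1, seed = 18)
  expect_equal(length(tr), 1L)
  expect_equal(polygon_area(tr), 2.0, tolerance = 1e-9)   # 4.0 x 0.5 m

  expect_equal(length(generate_trenches(site$dem, n = 0)), 0L)

  ## several trenches: non-overlapping footprints
  tr6 <- generate_trenches(site$dem, n = 6, seed = 19)
  r <- rasterize_polygons(tr6, site$dem)
  per_poly <- vapply(tr6$polygons, function(p)
    sum(rasterize_polygons(patch_polygons(list(p$exterior)),
                           site$dem)$values, na.rm = TRUE), 0)
  expect_equal(sum(r$values, na.rm = TRUE), sum(per_poly))
  expect_identical(generate_trenches(site$dem, n = 6, seed = 19)$polygons,
                   tr6$polygons)
  expect_error(generate_trenches(site$dem, n = 2, length_m = 100),
               "does not fit")
})

test_that("the density default scales 600 per hectare to the grid area", {
  dem <- raster_grid(matrix(0, 100, 60), cell_size = 0.1)   # 60 m^2
  dem$values[] <- rep((1:60) * 0.05, each = 100)            # gentle ramp
  tr <- generate_trenches(dem, length_m = 1, width_m = 0.2, seed = 20)
  expect_equal(length(tr), round(600 * 60 / 1e4))           # 4 trenches
})

test_that("presence patches rasterize back to the presence layer exactly", {
  site <- small_site()
  patches <- presence_to_patches(site$presence)
  back <- rasterize_polygons(patches, site$presence)
  ok <- is.finite(site$presence$values)
  expect_identical(back$values[ok], site$presence$values[ok])
  expect_equal(polygon_area(patches),
               sum(site$presence$values[ok]) * site$presence$cell_size^2,
               tolerance = 1e-9)
})
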