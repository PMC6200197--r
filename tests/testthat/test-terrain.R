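test_that("grid_dem reproduces affine surfaces at interior cells", {
  pts <- plane_points(80, a = 2, b = 3, c = 1, ext = 5, seed = 1)
  dem <- grid_dem(pts, 0.5)
  cx <- cell_centers_x(dem); cy <- cell_centers_y(dem)
  expected <- outer(cy * 3, cx * 2, "+") + 1
  ok <- is.finite(dem$values)
  expect_gt(sum(ok), 50)
  expect_equal(dem$values[ok], expected[ok], tolerance = 1e-10)

  ## three points only: the unique plane through them
  tri <- data.frame(x = c(0, 4, 0), y = c(0, 0, 4), z = c(1, 9, 13))
  dem3 <- grid_dem(tri, 0.5)            # z = 1 + 2x + 3y
  ok3 <- is.finite(dem3$values)
  exp3 <- outer(cell_centers_y(dem3) * 3, cell_centers_x(dem3) * 2, "+") + 1
  expect_gt(sum(ok3), 5)
  expect_equal(dem3$values[ok3], exp3[ok3], tolerance = 1e-10)
})

test_that("grid_dem agrees with a barycentric Delaunay oracle on random points", {
  set.seed(7)
  pts <- data.frame(x = runif(40, 0, 8), y = runif(40, 0, 8),
                    z = rnorm(40))
  dem <- grid_dem(pts, 0.4)
  ## digits = 14 stops deldir rounding the input coordinates
  tr <- deldir::triang.list(deldir::deldir(pts$x, pts$y, digits = 14))
  cx <- cell_centers_x(dem); cy <- cell_centers_y(dem)
  ok <- which(is.finite(dem$values), arr.ind = TRUE)
  set.seed(8)
  probe <- ok[sample(nrow(ok), 20), , drop = FALSE]
  for (k in seq_len(nrow(probe))) {
    px <- cx[probe[k, 2]]; py <- cy[probe[k, 1]]
    val <- NA_real_
    for (t in tr) {
      x <- t$x; y <- t$y
      d <- (y[2] - y[3]) * (x[1] - x[3]) + (x[3] - x[2]) * (y[1] - y[3])
      l1 <- ((y[2] - y[3]) * (px - x[3]) + (x[3] - x[2]) * (py - y[3])) / d
      l2 <- ((y[3] - y[1]) * (px - x[3]) + (x[1] - x[3]) * (py - y[3])) / d
      l3 <- 1 - l1 - l2
      if (min(l1, l2, l3) >= -1e-9) {
        zs <- pts$z[t$ptNum]
        val <- l1 * zs[1] + l2 * zs[2] + l3 * zs[3]
        break
      }
    }
    expect_equal(dem$values[probe[k, 1], probe[k, 2]], val, tolerance = 1e-8)
  }
})

test_that("grid_dem rejects bad input", {
  expect_error(grid_dem(data.frame(x = 1:5, y = 1:5, z = rnorm(5))),
               "collinear")
  expect_error(grid_dem(data.frame(x = 1:2, y = c(0, 1), z = 1:2)),
               "at least 3")
  expect_error(grid_dem(data.frame(x = 1:3, y = c(0, 1, 2))), "missing column")
})

test_that("slope is 0 on a flat DEM and 45 degrees on a unit-gradient plane", {
  flat <- raster_grid(matrix(5, 6, 6), cell_size = 0.5)
  s <- compute_slope(flat)
  expect_true(all(s$values[2:5, 2:5] == 0))
  expect_true(all(is.na(s$values[1, ])))   # border is nodata

  cx <- (1:8 - 0.5) * 0.5
  ramp <- raster_grid(matrix(rep(cx, each = 8), 8, byrow = FALSE),
                      cell_size = 0.5)   # dz/dx = 1
  s2 <- compute_slope(ramp)
  expect_equal(unname(s2$values[4, 4]), 45, tolerance = 1e-10)
  expect_error(compute_slope(raster_grid(matrix(0, 2, 2))), "3x3")
})

test_that("slope matches a brute-force Horn stencil on a random DEM", {
  set.seed(11)
  dem <- raster_grid(matrix(rnorm(100), 10), cell_size = 0.2)
  s <- compute_slope(dem)
  v <- dem$values
  set.seed(12)
  for (k in 1:10) {
    i <- sample(2:9, 1); j <- sample(2:9, 1)
    gx <- ((v[i - 1, j + 1] + 2 * v[i, j + 1] + v[i + 1, j + 1]) -
             (v[i - 1, j - 1] + 2 * v[i, j - 1] + v[i + 1, j - 1])) / (8 * 0.2)
    gy <- ((v[i - 1, j - 1] + 2 * v[i - 1, j] + v[i - 1, j + 1]) -
             (v[i + 1, j - 1] + 2 * v[i + 1, j] + v[i + 1, j + 1])) / (8 * 0.2)
    expect_equal(s$values[i, j], atan(sqrt(gx^2 + gy^2)) * 180 / pi,
                 tolerance = 1e-12)
  }
})

test_that("aspect gives the downslope azimuth and flags flat cells", {
  cy <- (6:1 - 0.5) * 1            # y decreases with row
  south <- raster_grid(matrix(rep(cy, 6), 6), cell_size = 1)  # descends south
  a <- compute_aspect(south)
  expect_equal(unname(a$values[3, 3]), 180)
  east <- raster_grid(matrix(rep((1:6 - 0.5), each = 6) * -1, 6,
                             byrow = FALSE), cell_size = 1)
  expect_equal(unname(compute_aspect(east)$values[3, 3]), 90)
  flat <- compute_aspect(raster_grid(matrix(2, 5, 5)))
  expect_true(all(flat$values[2:4, 2:4] == -1))
})

test_that("aspect reclassification follows the four insolation bands", {
  mk <- function(vals) raster_grid(matrix(vals, 1))
  got <- function(vals) as.vector(reclassify_aspect(mk(vals))$values)
  expect_equal(got(c(180, 10, 90)), c(4, 1, 3))
  ## boundaries go to the higher-numbered band
  expect_equal(got(c(0, 45, 135, 225, 315, 360)), c(1, 3, 4, 4, 2, 1))
  expect_equal(got(-1), 1)              # flat -> shady code
  expect_error(reclassify_aspect(mk(400)), "0, 360")
})

test_that("TPI is 0 on constant DEMs and on interior cells of a ramp", {
  const <- raster_grid(matrix(7, 15, 15), cell_size = 0.2)
  t1 <- compute_tpi(const, 0.6)
  expect_true(all(t1$values[4:12, 4:12] == 0))

  cx <- (1:21 - 0.5) * 0.2
  ramp <- raster_grid(matrix(rep(cx, each = 21), 21, byrow = FALSE),
                      cell_size = 0.2)
  t2 <- compute_tpi(ramp, 0.6)
  raw <- attr(t2, "raw")
  expect_equal(max(abs(raw$values[5:17, 5:17])), 0, tolerance = 1e-12)
  expect_error(compute_tpi(const, 0.1), "radius")
})

test_that("TPI equals the brute-force disc computation on a random DEM", {
  set.seed(21)
  dem <- raster_grid(matrix(rnorm(1600, 100, 2), 40), cell_size = 0.1)
  tpi <- compute_tpi(dem, 0.5)
  raw <- attr(tpi, "raw")
  v <- dem$values
  set.seed(22)
  for (k in 1:10) {
    i <- sample(40, 1); j <- sample(40, 1)
    nb <- numeric(0)
    for (ii in 1:40) for (jj in 1:40) {
      if (ii == i && jj == j) next
      if (((ii - i)^2 + (jj - j)^2) * 0.01 <= 0.25 + 1e-12)
        nb <- c(nb, v[ii, jj])
    }
    expect_equal(raw$values[i, j], v[i, j] - mean(nb), tolerance = 1e-10)
    expect_equal(tpi$values[i, j], (v[i, j] - mean(nb)) / sd(nb),
                 tolerance = 1e-10)
  }
})

test_that("global standardization divides the raw TPI by the DEM-wide SD", {
  set.seed(23)
  dem <- raster_grid(matrix(rnorm(400), 20), cell_size = 0.1)
  tg <- compute_tpi(dem, 0.4, standardize = "global")
  raw <- attr(tg, "raw")
  ok <- is.finite(tg$values)
  expect_equal(tg$values[ok], raw$values[ok] / sd(dem$values), tolerance = 1e-12)
})

test_that("microtopography classification matches the six-class criteria", {
  mk <- function(t, s) {
    classify_microtopography(raster_grid(matrix(t, 1)),
                             raster_grid(matrix(s, 1)))$values[1, ]
  }
  expect_equal(unname(mk(0.5, 5)), 6)          # ridge
  expect_equal(unname(mk(0.0, 10)), 4)         # middle slope
  expect_equal(unname(mk(0.0, 3)), 3)          # flat slope
  expect_equal(unname(mk(-0.5, 20)), 1)        # valley, any slope
  ## boundary convention: "<=" on the upper bound
  expect_equal(unname(mk(c(-0.3, -0.05, 0.15, 0.4), c(9, 9, 9, 9))),
               c(1, 2, 4, 5))
  expect_equal(unname(mk(0.15, 7)), 3)         # slope <= 7 is flat
})

test_that("classification is exhaustive and mutually exclusive", {
  ## grid straddling every threshold, crossed with slopes around the cut
  tvals <- c(-1, -0.31, -0.3, -0.29, -0.06, -0.05, -0.04, 0, 0.14, 0.15,
             0.16, 0.39, 0.4, 0.41, 1)
  svals <- c(0, 6.99, 7, 7.01, 30)
  g <- expand.grid(t = tvals, s = svals)
  cls <- classify_microtopography(raster_grid(matrix(g$t, 1)),
                                  raster_grid(matrix(g$s, 1)))
  expect_true(all(cls$values %in% 1:6))        # no gaps
  ## deterministic: same inputs, same single class
  cls2 <- classify_microtopography(raster_grid(matrix(g$t, 1)),
                                   raster_grid(matrix(g$s, 1)))
  expect_identical(cls$values, cls2$values)
  expect_error(
    classify_microtopography(raster_grid(matrix(0, 2, 2)),
                             raster_grid(matrix(0, 3, 3))),
    "aligned")
})

test_that("rasterization uses the centre-point rule", {
  tmpl <- raster_grid(matrix(0, 20, 20), x_origin = 0, y_origin = 2,
                      cell_size = 0.1)
  sq <- patch_polygons(list(cbind(c(0.5, 1.5, 1.5, 0.5), c(0.5, 0.5, 1.5, 1.5))))
  r <- rasterize_polygons(sq, tmpl)
  expect_equal(sum(r$values), 100)             # 1 m^2 at 0.1 m cells
  outside <- patch_polygons(list(cbind(c(5, 6, 6, 5), c(5, 5, 6, 6))))
  expect_equal(sum(rasterize_polygons(outside, tmpl)$values), 0)
  expect_equal(sum(rasterize_polygons(patch_polygons(), tmpl)$values), 0)
})

test_that("rasterization agrees with a naive ray-casting oracle", {
  set.seed(31)
  ring <- cbind(runif(7, 0, 2), runif(7, 0, 2))
  poly <- patch_polygons(list(ring))
  tmpl <- raster_grid(matrix(0, 20, 20), x_origin = 0, y_origin = 2,
                      cell_size = 0.1)
  r <- rasterize_polygons(poly, tmpl)
  cx <- cell_centers_x(tmpl); cy <- cell_centers_y(tmpl)
  for (k in 1:20) {
    i <- sample(20, 1); j <- sample(20, 1)
    expect_equal(r$values[i, j], as.numeric(pip_oracle(cx[j], cy[i], ring)),
                 info = sprintf("cell (%d,%d)", i, j))
  }
})

test_that("class-area overlay accounts areas and percentages exactly", {
  cls <- raster_grid(matrix(c(rep(1, 50), rep(6, 30), rep(4, 20)), 10),
                     cell_size = 0.1)
  attr(cls, "legend") <- microtopo_classes()
  mask <- raster_grid(matrix(c(rep(1, 50), rep(0, 50)), 10), cell_size = 0.1)
  tab <- overlay_class_areas(cls, mask)
  expect_equal(tab$area_m2[tab$name == "valley"], 0.5)   # 50 cells x 0.01
  expect_equal(sum(tab$percentage), 100, tolerance = 1e-9)

  ## single-class map -> 100%
  tab1 <- overlay_class_areas(cls, raster_grid(matrix(c(rep(1, 50), rep(0, 50)), 10),
                                               cell_size = 0.1))
  expect_equal(tab1$percentage[tab1$name == "valley"], 100)

  ## area conservation without a mask
  tab_all <- overlay_class_areas(cls)
  expect_equal(sum(tab_all$area_m2), sum(is.finite(cls$values)) * 0.01)

  ## empty mask: zero areas, flagged undefined percentages
  tab0 <- overlay_class_areas(cls, raster_grid(matrix(0, 10, 10), cell_size = 0.1))
  expect_true(attr(tab0, "empty_mask"))
  expect_equal(sum(tab0$area_m2), 0)
  expect_true(all(is.na(tab0$percentage)))
})
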