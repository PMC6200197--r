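#' Empirical semivariogram
#'
#' Bins all point pairs by separation distance and returns, per bin, the
#' classical semivariance estimate `mean(0.5 * (z_i - z_j)^2)` over the pairs
#' in that bin. Bins with no pairs are omitted.
#'
#' @param x,y point coordinates, metres.
#' @param z factor values at the points.
#' @param n_lags number of distance bins; default 12.
#' @param max_lag largest separation considered, metres; default half the
#'   maximum pairwise distance.
#' @return data frame with columns `lag` (mean pair distance in the bin),
#'   `gamma` (semivariance) and `np` (pair count). A constant field gives
#'   all-zero semivariances, flagged via attribute `"constant"`.
#' @export
empirical_semivariogram <- function(x, y, z, n_lags = 12, max_lag = NULL) {
  stopifnot(length(x) == length(y), length(x) == length(z))
  if (length(x) < 2L) stop("need at least 2 points")
  d <- as.vector(stats::dist(cbind(x, y)))
  g <- as.vector(stats::dist(z))^2 / 2
  if (is.null(max_lag)) max_lag <- max(d) / 2
  if (!is.finite(max_lag) || max_lag <= 0) stop("max_lag must be positive")
  keep <- d <= max_lag & d > 0
  d <- d[keep]; g <- g[keep]
  if (!length(d)) stop("no point pairs within max_lag")
  bin <- cut(d, breaks = seq(0, max_lag, length.out = n_lags + 1L),
             include.lowest = TRUE)
  out <- data.frame(
    lag = as.vector(tapply(d, bin, mean)),
    gamma = as.vector(tapply(g, bin, mean)),
    np = as.vector(tapply(g, bin, length))
  )
  out <- out[stats::complete.cases(out), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "constant") <- all(out$gamma == 0)
  out
}

#' Variogram model
#'
#' Isotropic semivariogram model with nugget, partial sill and range.
#' Families: `spherical` (range = true range), `exponential` and `gaussian`
#' (range = practical range, i.e. the distance at which the model reaches
#' 95% of the sill).
#'
#' @param family one of `"spherical"`, `"exponential"`, `"gaussian"`.
#' @param nugget,psill,range model parameters; `nugget`, `psill >= 0`,
#'   `range > 0`.
#' @export
variogram_model <- function(family = c("spherical", "exponential", "gaussian"),
                            nugget, psill, range) {
  family <- match.arg(family)
  if (nugget < 0 || psill < 0 || range <= 0)
    stop("variogram parameters out of bounds: need nugget, psill >= 0 and range > 0")
  structure(list(family = family, nugget = nugget, psill = psill,
                 range = range), class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("<variogram_model> %s: nugget %.4g, partial sill %.4g, range %.4g m\n",
              x$family, x$nugget, x$psill, x$range))
  invisible(x)
}

#' Model semivariance at distance h
#'
#' @param vg a [variogram_model].
#' @param h non-negative distances, metres.
#' @return semivariances; exactly 0 at `h = 0`.
#' @export
semivariance <- function(vg, h) {
  a <- vg$range
  s <- switch(vg$family,
    spherical = ifelse(h >= a, 1, 1.5 * h / a - 0.5 * (h / a)^3),
    exponential = 1 - exp(-3 * h / a),
    gaussian = 1 - exp(-3 * (h / a)^2)
  )
  out <- vg$nugget + vg$psill * s
  out[h == 0] <- 0
  out
}

#' Fit a variogram model to an empirical semivariogram
#'
#' Weighted least squares with the pair counts as weights, over a grid of
#' starting values refined by box-constrained quasi-Newton steps.
#'
#' @param emp data frame from [empirical_semivariogram()].
#' @param family model family; default `"spherical"`.
#' @return a [variogram_model] with the weighted SSE attached as attribute
#'   `"wsse"`; an all-zero semivariogram yields the degenerate model
#'   (nugget 0, partial sill 0) flagged via attribute `"degenerate"`.
#' @export
fit_variogram <- function(emp, family = c("spherical", "exponential", "gaussian")) {
  family <- match.arg(family)
  if (nrow(emp) < 3L) stop("need at least 3 non-empty lag bins to fit a variogram")
  if (all(emp$gamma == 0)) {
    vg <- variogram_model(family, 0, 0, max(emp$lag))
    attr(vg, "degenerate") <- TRUE
    attr(vg, "wsse") <- 0
    return(vg)
  }
  wsse <- function(p) {
    vg <- list(family = family, nugget = p[1L], psill = p[2L], range = p[3L])
    class(vg) <- "variogram_model"
    sum(emp$np * (emp$gamma - semivariance(vg, emp$lag))^2)
  }
  gmax <- max(emp$gamma); hmax <- max(emp$lag)
  starts <- expand.grid(nugget = c(0, min(emp$gamma)),
                        psill = gmax * c(0.5, 1),
                        range = hmax * c(0.3, 0.6, 1))
  best <- NULL
  for (r in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(as.numeric(starts[r, ]), wsse, method = "L-BFGS-B",
                   lower = c(0, 0, hmax * 1e-4),
                   upper = c(gmax * 2 + 1e-12, gmax * 3 + 1e-12, hmax * 10)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    stop("variogram fit failed to converge from every starting value")
  vg <- variogram_model(family, best$par[1L], best$par[2L], best$par[3L])
  attr(vg, "degenerate") <- FALSE
  attr(vg, "wsse") <- best$value
  vg
}

## Solve the ordinary kriging system for prediction locations (px, py).
## Returns weights (n x m), predictions, and kriging variances.
## Duplicate sample locations are averaged before solving; a tiny diagonal
## ridge is added only if the plain system is singular.
ok_solve <- function(x, y, z, vg, px, py) {
  key <- paste(signif(x, 12), signif(y, 12))
  if (anyDuplicated(key)) {
    agg <- stats::aggregate(cbind(x, y, z), by = list(key = key), FUN = mean)
    x <- agg$x; y <- agg$y; z <- agg$z
    message("kriging: duplicate sample locations averaged")
  }
  n <- length(x)
  if (n < 2L) stop("kriging needs at least 2 distinct sample points")
  D <- as.matrix(stats::dist(cbind(x, y)))
  A <- rbind(cbind(semivariance(vg, D), 1), c(rep(1, n), 0))
  dx <- outer(x, px, "-"); dy <- outer(y, py, "-")
  B <- rbind(semivariance(vg, sqrt(dx^2 + dy^2)), 1)
  W <- tryCatch(solve(A, B), error = function(e) {
    message("kriging: singular system, adding 1e-10 ridge to the diagonal")
    A2 <- A
    diag(A2)[seq_len(n)] <- diag(A2)[seq_len(n)] + 1e-10
    solve(A2, B)
  })
  w <- W[seq_len(n), , drop = FALSE]
  mu <- W[n + 1L, ]
  pred <- as.vector(crossprod(w, z))
  var <- colSums(w * B[seq_len(n), , drop = FALSE]) + mu
  var[var < 0] <- 0
  list(weights = w, pred = pred, var = var, z = z)
}

#' Ordinary kriging onto a raster grid
#'
#' Best linear unbiased prediction: for each target cell the weights solve
#' the ordinary kriging system (semivariance form with a Lagrange multiplier
#' enforcing that weights sum to 1); the prediction is the weighted sum of
#' the sample values and the kriging variance is returned per cell. With a
#' zero nugget the predictor interpolates the samples exactly. Cells whose
#' weights include negative values are permitted; their count is reported
#' via attribute `"n_negative_weight_cells"`.
#'
#' @param x,y,z sample locations and values (at least 4 points).
#' @param vg a [variogram_model].
#' @param template [raster_grid] defining the prediction grid and mask.
#' @return a [raster_grid] of predictions with the kriging-variance grid
#'   attached as attribute `"variance"`.
#' @export
krige <- function(x, y, z, vg, template) {
  if (length(x) < 4L) stop("kriging needs at least 4 sample points")
  v <- template$values
  ok <- is.finite(v)
  cx <- cell_centers_x(template); cy <- cell_centers_y(template)
  px <- rep(cx, each = nrow(v))[ok]   # column-major over the value matrix
  py <- rep(cy, times = ncol(v))[ok]
  sol <- ok_solve(x, y, z, vg, px, py)
  pred <- matrix(NA_real_, nrow(v), ncol(v)); pred[ok] <- sol$pred
  kvar <- matrix(NA_real_, nrow(v), ncol(v)); kvar[ok] <- sol$var
  out <- grid_like(template, pred)
  attr(out, "variance") <- grid_like(template, kvar)
  attr(out, "n_negative_weight_cells") <- sum(apply(sol$weights < -1e-10, 2L, any))
  out
}

#' Leave-one-out cross-validation of a kriging model
#'
#' Each point is predicted from all the others with the given variogram.
#' Reports the mean prediction error `MPE = mean(pred - obs)` and the
#' root-mean-square standardized prediction error
#' `RMSSE = sqrt(mean(((pred - obs) / sqrt(kriging variance))^2))`; for a
#' well-specified model the RMSSE is close to 1. Points with zero kriging
#' variance are excluded from the RMSSE and flagged.
#'
#' @param x,y,z sample locations and values (at least 5 points).
#' @param vg a [variogram_model].
#' @return list with `mpe`, `rmsse`, per-point `residuals` data frame, and
#'   `n_excluded`.
#' @export
cross_validate <- function(x, y, z, vg) {
  n <- length(x)
  if (n < 5L) stop("leave-one-out validation needs at least 5 points")
  pred <- var <- numeric(n)
  for (i in seq_len(n)) {
    sol <- ok_solve(x[-i], y[-i], z[-i], vg, x[i], y[i])
    pred[i] <- sol$pred; var[i] <- sol$var
  }
  res <- pred - z
  usable <- var > 0
  std <- res[usable] / sqrt(var[usable])
  list(
    mpe = mean(res),
    rmsse = if (any(usable)) sqrt(mean(std^2)) else NA_real_,
    residuals = data.frame(x = x, y = y, observed = z, predicted = pred,
                           kriging_variance = var, residual = res),
    n_excluded = sum(!usable)
  )
}
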