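#' Factor stack
#'
#' A named collection of aligned raster layers: the environmental predictors
#' of the species distribution model (topographic layers plus kriged soil
#' and microclimate factors).
#'
#' @param layers named list of [raster_grid] objects, all aligned.
#' @return an object of class `factor_stack`.
#' @export
factor_stack <- function(layers) {
  nm <- names(layers)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("factor stack layers must have unique non-empty names")
  if (!length(layers)) stop("factor stack must hold at least one layer")
  for (i in seq_along(layers)) {
    if (!inherits(layers[[i]], "raster_grid"))
      stop("layer '", nm[i], "' is not a raster_grid")
    stop_if_misaligned(layers[[1L]], layers[[i]],
                       sprintf("layers '%s' and '%s'", nm[1L], nm[i]))
  }
  structure(list(layers = layers), class = "factor_stack")
}

#' @export
print.factor_stack <- function(x, ...) {
  d <- dim(x$layers[[1L]]$values)
  cat(sprintf("<factor_stack> %d layer(s) on a %d x %d grid\n",
              length(x$layers), d[1L], d[2L]))
  cat(" ", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' @export
names.factor_stack <- function(x) names(x$layers)

#' Assemble a per-cell training table
#'
#' One row per cell that is valid in the presence layer and in every factor
#' layer; the binary label comes from the presence raster. Cells with any
#' nodata factor are dropped and counted (attribute `"n_dropped"`); the cell
#' index (column-major) is kept so predictions can be mapped back.
#'
#' @param presence binary [raster_grid] (1 = presence, 0 = absence).
#' @param stack a [factor_stack].
#' @return data frame with columns `cell`, `label`, and one column per
#'   factor.
#' @export
build_training <- function(presence, stack) {
  for (nm in names(stack))
    stop_if_misaligned(presence, stack$layers[[nm]],
                       sprintf("presence and factor '%s'", nm))
  lab <- as.vector(presence$values)
  X <- vapply(stack$layers, function(g) as.vector(g$values),
              numeric(length(lab)))
  ok <- is.finite(lab)
  keep <- ok & apply(is.finite(X), 1L, all)
  n_dropped <- sum(ok) - sum(keep)
  out <- data.frame(cell = which(keep), label = as.integer(lab[keep]),
                    X[keep, , drop = FALSE])
  names(out) <- c("cell", "label", names(stack))
  if (!any(out$label == 1) || !any(out$label == 0))
    stop("degenerate training data: need both presence and absence cells")
  attr(out, "n_dropped") <- n_dropped
  out
}

## Ridge-penalized logistic regression by iteratively reweighted least
## squares; the intercept is not penalized. X excludes the intercept column.
irls_ridge <- function(X, ylab, l2, max_iter = 100, tol = 1e-9) {
  Xd <- cbind(1, X)
  p <- ncol(Xd)
  beta <- numeric(p)
  pen <- diag(c(0, rep(l2, p - 1L)), p)
  for (it in seq_len(max_iter)) {
    eta <- as.vector(Xd %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-12)
    grad <- crossprod(Xd, ylab - mu) - pen %*% beta
    H <- crossprod(Xd, Xd * w) + pen
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol)
      return(list(beta = as.vector(beta), converged = TRUE, iterations = it))
  }
  list(beta = as.vector(beta), converged = FALSE, iterations = max_iter)
}

#' Fit a presence-absence species distribution model
#'
#' Calibrates a binomial generalized linear model with logit link on
#' z-score standardized factors, by iteratively reweighted least squares
#' (optionally with an L2 ridge penalty to handle separation). Factors that
#' are constant in training are dropped with a warning. Coefficients are
#' reported on both the standardized and the original factor scale, and the
#' training AUC is computed from the fitted probabilities.
#'
#' @param train training table from [build_training()] (columns `label` and
#'   one per factor; a `cell` column is ignored for fitting).
#' @param l2 ridge penalty on the standardized coefficients; default 0
#'   (plain maximum likelihood).
#' @param max_iter IRLS iteration cap.
#' @return an object of class `sdm` with `print`, `summary`, `coef`,
#'   `predict`, `residuals` and `plot` methods.
#' @export
fit_sdm <- function(train, l2 = 0, max_iter = 100) {
  stopifnot(l2 >= 0)
  fac <- setdiff(names(train), c("cell", "label"))
  if (!length(fac)) stop("no factor columns in the training table")
  y <- train$label
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1")
  if (!any(y == 1) || !any(y == 0))
    stop("degenerate training data: need both classes")
  X <- as.matrix(train[, fac, drop = FALSE])
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  dropped <- fac[scl == 0]
  if (length(dropped)) {
    warning("dropping constant factor(s): ", paste(dropped, collapse = ", "))
    fac <- setdiff(fac, dropped)
    if (!length(fac)) stop("all factors constant; nothing to fit")
    X <- X[, fac, drop = FALSE]
    ctr <- ctr[fac]; scl <- scl[fac]
  }
  Z <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")

  if (l2 == 0) {
    df <- data.frame(.y = y, Z)
    fit <- stats::glm(.y ~ ., data = df, family = stats::binomial(),
                      control = stats::glm.control(maxit = max_iter))
    beta <- unname(stats::coef(fit))
    if (any(!is.finite(beta)) || max(abs(beta[-1L])) > 15)
      stop("(quasi-)perfect separation detected; refit with l2 > 0")
    if (!fit$converged)
      stop("GLM did not converge within ", max_iter, " iterations")
    converged <- TRUE
    loglik <- as.numeric(stats::logLik(fit))
  } else {
    res <- irls_ridge(Z, y, l2, max_iter = max_iter)
    if (!res$converged)
      stop("penalized IRLS did not converge within ", max_iter, " iterations")
    beta <- res$beta
    eta <- beta[1L] + as.vector(Z %*% beta[-1L])
    loglik <- sum(y * eta - log1p(exp(eta)))
    converged <- TRUE
  }
  names(beta) <- c("(Intercept)", fac)

  ## back-transform to the original factor scale
  b_raw <- beta[-1L] / scl
  a_raw <- beta[1L] - sum(beta[-1L] * ctr / scl)
  coef_raw <- c("(Intercept)" = unname(a_raw), b_raw)

  eta <- beta[1L] + as.vector(Z %*% beta[-1L])
  prob <- 1 / (1 + exp(-eta))
  obj <- structure(list(
    kind = "glm",
    coefficients = beta,
    coefficients_raw = coef_raw,
    center = ctr, scale = scl,
    dropped_factors = dropped,
    l2 = l2,
    converged = converged,
    loglik = loglik,
    n = length(y),
    prevalence = mean(y),
    fitted = prob,
    labels = y,
    auc = auc(y, prob)
  ), class = "sdm")
  obj
}

#' @export
print.sdm <- function(x, ...) {
  cat(sprintf("<sdm> presence-absence %s, %d cells (prevalence %.3f)\n",
              toupper(x$kind), x$n, x$prevalence))
  cat(sprintf("  training AUC %.3f (%s)%s\n", x$auc, accuracy_band(x$auc),
              if (x$l2 > 0) sprintf(", ridge l2 = %g", x$l2) else ""))
  invisible(x)
}

#' @export
summary.sdm <- function(object, ...) {
  cat(sprintf("Presence-absence %s species distribution model\n",
              toupper(object$kind)))
  cat(sprintf("  n = %d cells, prevalence = %.4f, log-likelihood = %.2f\n",
              object$n, object$prevalence, object$loglik))
  cat(sprintf("  training AUC = %.3f (%s)\n", object$auc,
              accuracy_band(object$auc)))
  if (length(object$dropped_factors))
    cat("  dropped constant factors:",
        paste(object$dropped_factors, collapse = ", "), "\n")
  cat("\nCoefficients (standardized factors):\n")
  print(round(object$coefficients, 4))
  invisible(object)
}

#' @export
coef.sdm <- function(object, standardized = TRUE, ...) {
  if (standardized) object$coefficients else object$coefficients_raw
}

#' Predict habitat probability
#'
#' @param object an [fit_sdm()] model.
#' @param newdata a [factor_stack] (returns a probability [raster_grid]) or
#'   a data frame with the model's factor columns (returns a vector).
#' @param type `"response"` (probability) or `"link"` (linear predictor).
#' @param ... unused.
#' @export
predict.sdm <- function(object, newdata,
                        type = c("response", "link"), ...) {
  type <- match.arg(type)
  fac <- names(object$coefficients)[-1L]
  if (inherits(newdata, "factor_stack")) {
    miss <- setdiff(fac, names(newdata))
    if (length(miss))
      stop("factor stack is missing model factor(s): ",
           paste(miss, collapse = ", "))
    tmpl <- newdata$layers[[1L]]
    X <- vapply(newdata$layers[fac], function(g) as.vector(g$values),
                numeric(length(tmpl$values)))
    eta <- object$coefficients[1L] +
      as.vector(scale(X, object$center[fac], object$scale[fac]) %*%
                  object$coefficients[-1L])
    out <- if (type == "link") eta else 1 / (1 + exp(-eta))
    return(grid_like(tmpl, matrix(out, nrow(tmpl$values), ncol(tmpl$values))))
  }
  miss <- setdiff(fac, names(newdata))
  if (length(miss))
    stop("newdata is missing model factor(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(newdata[, fac, drop = FALSE])
  eta <- object$coefficients[1L] +
    as.vector(scale(X, object$center[fac], object$scale[fac]) %*%
                object$coefficients[-1L])
  if (type == "link") eta else 1 / (1 + exp(-eta))
}

#' @export
residuals.sdm <- function(object, type = c("deviance", "response"), ...) {
  type <- match.arg(type)
  y <- object$labels; mu <- object$fitted
  if (type == "response") return(y - mu)
  d <- -2 * (y * log(mu) + (1 - y) * log1p(-mu))
  sign(y - mu) * sqrt(pmax(d, 0))
}

#' ROC curve of a fitted model
#'
#' @param x an `sdm` object.
#' @param ... passed to [graphics::plot].
#' @export
plot.sdm <- function(x, ...) {
  ord <- order(x$fitted, decreasing = TRUE)
  y <- x$labels[ord]
  tpr <- c(0, cumsum(y) / sum(y))
  fpr <- c(0, cumsum(1 - y) / sum(1 - y))
  graphics::plot(fpr, tpr, type = "l", xlab = "False positive rate",
                 ylab = "True positive rate",
                 main = sprintf("ROC, AUC = %.3f", x$auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank-sum (Mann-Whitney) formulation: the fraction of
#' presence-absence score pairs that are concordant, counting ties as one
#' half. Threshold-independent; invariant under strictly monotone
#' transforms of the scores.
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores, higher = more presence-like.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC is undefined with a single class")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Accuracy band of an AUC value
#'
#' Conventional bands: excellent (AUC > 0.9), good (0.8-0.9), fair
#' (0.7-0.8), poor (0.6-0.7), fail (below 0.6). Boundary values go to the
#' higher band.
#'
#' @param auc_value AUC in `[0, 1]`.
#' @return one of `"excellent"`, `"good"`, `"fair"`, `"poor"`, `"fail"`.
#' @export
accuracy_band <- function(auc_value) {
  stopifnot(is.finite(auc_value), auc_value >= 0, auc_value <= 1)
  if (auc_value >= 0.9) "excellent"
  else if (auc_value >= 0.8) "good"
  else if (auc_value >= 0.7) "fair"
  else if (auc_value >= 0.6) "poor"
  else "fail"
}

#' Select the best model above an AUC gate
#'
#' Returns the highest-AUC candidate whose AUC exceeds the threshold; ties
#' resolve to the earliest candidate in the input order (reported via a
#' message). If no candidate clears the gate, an error lists every AUC.
#'
#' @param candidates list of `sdm` objects.
#' @param threshold AUC gate; default 0.9.
#' @return the selected `sdm`, with attribute `"all_auc"`.
#' @export
select_model <- function(candidates, threshold = 0.9) {
  if (!length(candidates)) stop("no candidate models")
  aucs <- vapply(candidates, function(m) m$auc, 0)
  ok <- aucs > threshold
  if (!any(ok))
    stop(sprintf("no model exceeds the AUC gate %.2f; candidate AUCs: %s",
                 threshold, paste(sprintf("%.3f", aucs), collapse = ", ")))
  best <- which(ok & aucs == max(aucs[ok]))
  if (length(best) > 1L)
    message(sprintf("AUC tie at %.3f; keeping candidate %d (input order)",
                    max(aucs[ok]), best[1L]))
  out <- candidates[[best[1L]]]
  attr(out, "all_auc") <- aucs
  out
}

#' Permutation importance of model factors
#'
#' For each factor, its training-table column is permuted `k` times and the
#' model is rescored; the importance is the mean drop in AUC relative to the
#' unpermuted table. Deterministic given `seed`.
#'
#' @param model an `sdm` object.
#' @param train training table used to fit the model.
#' @param k permutations per factor (default 5); must be at least 1.
#' @param seed RNG seed.
#' @return data frame `factor`, `auc_drop`, sorted descending.
#' @export
factor_importance <- function(model, train, k = 5, seed = 1) {
  if (k < 1) stop("k must be at least 1")
  fac <- names(model$coefficients)[-1L]
  base <- auc(train$label, predict(model, train))
  set.seed(seed)
  drop <- vapply(fac, function(f) {
    mean(vapply(seq_len(k), function(i) {
      tr <- train
      tr[[f]] <- sample(tr[[f]])
      base - auc(tr$label, predict(model, tr))
    }, 0))
  }, 0)
  out <- data.frame(factor = fac, auc_drop = unname(drop))
  out[order(-out$auc_drop), , drop = FALSE]
}
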