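#' Read an elevation point table
#'
#' CSV with a header and numeric columns `x`, `y`, `z` (metres). Rows with
#' missing or non-numeric coordinates are dropped and reported with their
#' line numbers.
#'
#' @param path CSV file path.
#' @return data frame `x`, `y`, `z`.
#' @export
read_points_csv <- function(path) {
  df <- utils::read.csv(path)
  if (nrow(df) == 0L) stop("empty point file: ", path)
  miss <- setdiff(c("x", "y", "z"), names(df))
  if (length(miss))
    stop("point table missing column(s): ", paste(miss, collapse = ", "))
  for (cl in c("x", "y", "z")) df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))
  bad <- !stats::complete.cases(df[, c("x", "y", "z")])
  if (any(bad)) {
    warning(sprintf("dropping %d malformed point row(s) at line(s): %s",
                    sum(bad),
                    paste(utils::head(which(bad) + 1L, 10L), collapse = ", ")))
    df <- df[!bad, , drop = FALSE]
  }
  df[, c("x", "y", "z")]
}

#' Write an elevation point table
#'
#' @param points data frame with `x`, `y`, `z`.
#' @param path output CSV path.
#' @export
write_points_csv <- function(points, path) {
  utils::write.csv(points[, c("x", "y", "z")], path, row.names = FALSE)
  invisible(path)
}

#' Read a factor-sample table
#'
#' CSV with a header: point coordinates `x`, `y`, the group labels
#' `gully_type` and `microtopo`, and one numeric column per factor.
#'
#' @param path CSV file path.
#' @param factors optional character vector of required factor columns.
#' @return data frame.
#' @export
read_factor_samples_csv <- function(path, factors = NULL) {
  df <- utils::read.csv(path)
  if (nrow(df) == 0L) stop("empty sample file: ", path)
  need <- c("x", "y", "gully_type", "microtopo", factors)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample table missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Serialize a fitted SDM to JSON
#'
#' Stores the model kind, coefficients on both scales, the standardization
#' constants, and the training AUC, so a model can be archived next to the
#' rasters it produced and reloaded later.
#'
#' @param model an `sdm` object.
#' @param path output JSON path.
#' @export
write_sdm_json <- function(model, path) {
  jsonlite::write_json(list(
    kind = model$kind,
    coefficients = as.list(model$coefficients),
    coefficients_raw = as.list(model$coefficients_raw),
    center = as.list(model$center),
    scale = as.list(model$scale),
    dropped_factors = model$dropped_factors,
    l2 = model$l2,
    auc = model$auc,
    n = model$n,
    prevalence = model$prevalence
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Reload a fitted SDM from JSON
#'
#' Restores the pieces needed for prediction (coefficients and
#' standardization constants); training-time vectors (fitted values,
#' labels) are not stored.
#'
#' @param path JSON path from [write_sdm_json()].
#' @return an `sdm` object usable with [predict.sdm()].
#' @export
read_sdm_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    kind = j$kind,
    coefficients = unlist(j$coefficients),
    coefficients_raw = unlist(j$coefficients_raw),
    center = unlist(j$center),
    scale = unlist(j$scale),
    dropped_factors = j$dropped_factors,
    l2 = j$l2, converged = TRUE, loglik = NA_real_,
    n = j$n, prevalence = j$prevalence,
    fitted = NULL, labels = NULL, auc = j$auc
  ), class = "sdm")
}
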