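#' Restoration scenario specification
#'
#' The counterfactual used to evaluate a level-trench restoration measure:
#' inside the trench footprints each listed soil/microclimate factor is set
#' to a reference replacement value (typically the mean of that factor
#' measured in established trenches of a reference stand); topographic
#' layers are left unchanged by default.
#'
#' @param trenches level-trench footprints as a [patch_polygons] object.
#' @param replacements named numeric vector, factor name -> replacement
#'   value.
#' @param factors_replaced names of the factors to replace; defaults to
#'   `names(replacements)`.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(trenches, replacements,
                          factors_replaced = names(replacements)) {
  if (!inherits(trenches, "patch_polygons"))
    stop("trenches must be a patch_polygons object")
  if (length(factors_replaced)) {
    if (is.null(names(replacements)) || any(names(replacements) == ""))
      stop("replacements must be a named numeric vector")
    miss <- setdiff(factors_replaced, names(replacements))
    if (length(miss))
      stop("no replacement value for factor(s): ", paste(miss, collapse = ", "))
  }
  structure(list(trenches = trenches,
                 replacements = replacements,
                 factors_replaced = factors_replaced),
            class = "scenario_spec")
}

#' Apply a restoration scenario to a factor stack
#'
#' Rasterizes the trench footprints onto the stack grid (centre-point rule)
#' and sets each replaced factor to its replacement value inside the
#' footprints; every cell outside the footprints, and every non-replaced
#' layer, is returned bit-identical. With no trenches or an empty
#' replacement set this is the identity.
#'
#' @param stack a [factor_stack].
#' @param spec a [scenario_spec].
#' @return a [factor_stack] with the trench mask attached as attribute
#'   `"trench_mask"`.
#' @export
apply_scenario <- function(stack, spec) {
  miss <- setdiff(spec$factors_replaced, names(stack))
  if (length(miss))
    stop("scenario replaces factor(s) absent from the stack: ",
         paste(miss, collapse = ", "))
  tmpl <- stack$layers[[1L]]
  mask <- rasterize_polygons(spec$trenches, tmpl)
  inside <- is.finite(mask$values) & mask$values == 1
  layers <- stack$layers
  for (f in spec$factors_replaced) {
    v <- layers[[f]]$values
    v[inside & is.finite(v)] <- spec$replacements[[f]]
    layers[[f]] <- grid_like(layers[[f]], v)
  }
  out <- factor_stack(layers)
  attr(out, "trench_mask") <- mask
  out
}

#' Reclassify a probability layer into suitability classes
#'
#' Three-class reclassification of a habitat-probability raster:
#' `p < t_low` unsuitable (0), `t_low <= p < t_high` sub-suitable (1),
#' `p >= t_high` suitable (2). The thresholds are design parameters, not
#' field-measured quantities, and are always echoed in the output so the
#' reported areas stay interpretable.
#'
#' @param prob probability [raster_grid] with values in `[0, 1]`.
#' @param t_low,t_high thresholds with `0 <= t_low < t_high <= 1`;
#'   defaults 0.5 and 0.75.
#' @return an object of class `suitability_map`: the class [raster_grid]
#'   plus an area/percentage table and the thresholds used.
#' @export
reclassify_suitability <- function(prob, t_low = 0.5, t_high = 0.75) {
  if (!(t_low >= 0 && t_low < t_high && t_high <= 1))
    stop("thresholds must satisfy 0 <= t_low < t_high <= 1")
  p <- prob$values
  cls <- matrix(NA_real_, nrow(p), ncol(p))
  ok <- is.finite(p)
  cls[ok] <- 0
  cls[ok & p >= t_low] <- 1
  cls[ok & p >= t_high] <- 2
  counts <- vapply(0:2, function(k) sum(cls[ok] == k), 0)
  tab <- area_table(counts, prob$cell_size,
                    c("unsuitable", "sub-suitable", "suitable"))
  structure(list(grid = grid_like(prob, cls), areas = tab,
                 t_low = t_low, t_high = t_high),
            class = "suitability_map")
}

#' @export
print.suitability_map <- function(x, ...) {
  cat(sprintf("<suitability_map> thresholds %.2f / %.2f\n", x$t_low, x$t_high))
  print(x$areas, row.names = FALSE)
  invisible(x)
}

#' Cross-tabulate suitability against landscape strata
#'
#' Splits the valid area into three strata: inside the trench footprints,
#' valley cells outside the trenches, and all other cells, then reports the
#' area of each suitability class in each stratum together with the
#' percentage of the stratum it occupies.
#'
#' @param map a [suitability_map].
#' @param microtopo microtopography class [raster_grid].
#' @param trenches trench [patch_polygons].
#' @return data frame with one row per stratum x suitability class:
#'   `stratum`, `class`, `area_m2`, `pct_of_stratum`.
#' @export
suitability_report <- function(map, microtopo, trenches) {
  g <- map$grid
  stop_if_misaligned(g, microtopo, "suitability and microtopography grids")
  mask <- rasterize_polygons(trenches, g)
  cls <- g$values
  ok <- is.finite(cls)
  in_trench <- ok & is.finite(mask$values) & mask$values == 1
  valley <- ok & !in_trench & is.finite(microtopo$values) & microtopo$values == 1
  other <- ok & !in_trench & !valley
  strata <- list(trench = in_trench, valley = valley, other = other)
  labels <- c("unsuitable", "sub-suitable", "suitable")
  rows <- list()
  for (s in names(strata)) {
    sel <- strata[[s]]
    tot <- sum(sel)
    for (k in 0:2) {
      n <- sum(cls[sel] == k)
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, class = labels[k + 1L],
        area_m2 = n * g$cell_size^2,
        pct_of_stratum = if (tot > 0) 100 * n / tot else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
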