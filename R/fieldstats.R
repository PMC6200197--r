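#' Kolmogorov-Smirnov normality check (Lilliefors variant)
#'
#' One-sample KS statistic of the data against a normal distribution with
#' mean and SD estimated from the same data; the p-value uses the Lilliefors
#' approximation (which corrects the KS null distribution for the estimated
#' parameters). Constant data cannot be tested and are returned flagged as
#' degenerate.
#'
#' @param values numeric vector, `n >= 3`.
#' @return list with `statistic` (the KS D), `p_value` (Lilliefors
#'   approximation, `NA` when `n < 5`), `method`, and `degenerate`.
#' @export
ks_normality <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L) stop("normality check needs at least 3 values")
  if (stats::sd(values) == 0)
    return(list(statistic = NA_real_, p_value = NA_real_,
                method = "Lilliefors (KS, estimated parameters)",
                degenerate = TRUE))
  z <- sort((values - mean(values)) / stats::sd(values))
  cdf <- stats::pnorm(z)
  i <- seq_len(n)
  d <- max(i / n - cdf, cdf - (i - 1) / n)
  p <- if (n >= 5L) unname(nortest::lillie.test(values)$p.value) else NA_real_
  list(statistic = d, p_value = p,
       method = "Lilliefors (KS, estimated parameters)", degenerate = FALSE)
}

#' Levene's test for homogeneity of variances
#'
#' Mean-centred variant: a one-way ANOVA on the absolute deviations of each
#' value from its group mean.
#'
#' @param values numeric vector.
#' @param group group labels, same length.
#' @return list with `statistic` (F), `df`, `p_value`.
#' @export
levene_test <- function(values, group) {
  group <- as.factor(group)
  stopifnot(length(values) == length(group))
  cnt <- table(group)
  if (length(cnt) < 2L) stop("Levene's test needs at least 2 groups")
  if (any(cnt < 2L))
    stop("every group needs at least 2 values; too few in: ",
         paste(names(cnt)[cnt < 2L], collapse = ", "))
  lt <- car::leveneTest(values ~ group, center = mean)
  list(statistic = lt[1L, "F value"],
       df = c(lt[1L, "Df"], lt[2L, "Df"]),
       p_value = lt[1L, "Pr(>F)"])
}

## Insert-and-absorb compact letter display. `sig` is a symmetric logical
## matrix (TRUE = pair significantly different); groups are assumed ordered
## (letters are assigned 'a' first to the first group's columns).
cld_letters <- function(sig) {
  k <- nrow(sig)
  cols <- list(rep(TRUE, k))
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      if (!sig[i, j]) next
      for (ci in seq_along(cols)) {
        col <- cols[[ci]]
        if (col[i] && col[j]) {
          c1 <- col; c1[j] <- FALSE
          c2 <- col; c2[i] <- FALSE
          cols[[ci]] <- c1
          cols[[length(cols) + 1L]] <- c2
        }
      }
      ## absorb columns that are subsets of another column
      keep <- rep(TRUE, length(cols))
      for (a in seq_along(cols)) for (b in seq_along(cols)) {
        if (a != b && keep[a] && keep[b] &&
            all(cols[[a]] <= cols[[b]]) && any(cols[[b]] & !cols[[a]]))
          keep[a] <- FALSE
        if (a != b && keep[a] && keep[b] &&
            identical(cols[[a]], cols[[b]]) && a > b)
          keep[a] <- FALSE
      }
      cols <- cols[keep]
    }
  }
  ## order columns by their first member so 'a' goes to the top group
  ord <- order(vapply(cols, function(cc) which(cc)[1L], 0L))
  cols <- cols[ord]
  vapply(seq_len(k), function(g) {
    paste(letters[which(vapply(cols, function(cc) cc[g], TRUE))], collapse = "")
  }, "")
}

#' One-way ANOVA with LSD pairwise comparisons and letter groups
#'
#' Classic field-table analysis: one-way ANOVA followed by unadjusted
#' pairwise least-significant-difference t-tests using the pooled
#' within-group mean square, and a compact letter display (insert-and-absorb
#' algorithm). Groups are ordered by descending mean and 'a' is assigned to
#' the largest mean, the convention of field tables where the most
#' favourable microtopography carries 'a'. Two groups sharing a letter do
#' not differ at `alpha`; groups sharing no letter do.
#'
#' @param values numeric measurements.
#' @param group group labels, same length as `values`.
#' @param alpha significance level; default 0.05.
#' @param log_transform natural-log transform the values first (all values
#'   must be positive); used when raw data fail normality/homogeneity.
#' @return object of class `anova_lsd`: `f_statistic`, `df`, `p_value`,
#'   `groups` (per-group n, mean, SE on the analysis scale, letters),
#'   `lsd_p` (pairwise p matrix), `alpha`, `log_transform`.
#' @export
anova_lsd <- function(values, group, alpha = 0.05, log_transform = FALSE) {
  group <- as.factor(group)
  stopifnot(length(values) == length(group))
  cnt <- table(group)
  if (length(cnt) < 2L) stop("ANOVA needs at least 2 groups")
  if (any(cnt < 2L))
    stop("every group needs at least 2 values; too few in: ",
         paste(names(cnt)[cnt < 2L], collapse = ", "))
  if (log_transform) {
    if (any(values <= 0))
      stop("log transform requires all values > 0")
    values <- log(values)
  }
  fit <- stats::aov(values ~ group)
  sm <- summary(fit)[[1L]]
  f_stat <- sm[1L, "F value"]
  p_val <- sm[1L, "Pr(>F)"]
  df1 <- sm[1L, "Df"]; df2 <- sm[2L, "Df"]
  mse <- sm[2L, "Mean Sq"]

  means <- tapply(values, group, mean)
  ses <- tapply(values, group, stats::sd) / sqrt(as.vector(cnt))
  ord <- order(-means)
  g_ord <- levels(group)[ord]
  k <- length(g_ord)

  lsd_p <- matrix(NA_real_, k, k, dimnames = list(g_ord, g_ord))
  for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
    gi <- g_ord[i]; gj <- g_ord[j]
    se_d <- sqrt(mse * (1 / cnt[[gi]] + 1 / cnt[[gj]]))
    t <- (means[[gi]] - means[[gj]]) / se_d
    lsd_p[i, j] <- lsd_p[j, i] <- 2 * stats::pt(-abs(t), df2)
  }
  sig <- !is.na(lsd_p) & lsd_p < alpha
  letters <- cld_letters(sig)

  structure(list(
    f_statistic = f_stat, df = c(df1, df2), p_value = p_val, mse = mse,
    groups = data.frame(group = g_ord, n = as.integer(cnt[g_ord]),
                        mean = as.vector(means[g_ord]),
                        se = as.vector(ses[g_ord]), letters = letters,
                        row.names = NULL),
    lsd_p = lsd_p, alpha = alpha, log_transform = log_transform
  ), class = "anova_lsd")
}

#' @export
print.anova_lsd <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g%s\n",
              x$df[1L], x$df[2L], x$f_statistic, x$p_value,
              if (x$log_transform) " (ln-transformed)" else ""))
  g <- x$groups
  cat(sprintf("LSD letters at alpha = %g:\n", x$alpha))
  for (i in seq_len(nrow(g)))
    cat(sprintf("  %-12s %.2f ± %.2f%s\n", g$group[i], g$mean[i],
                g$se[i], g$letters[i]))
  invisible(x)
}
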