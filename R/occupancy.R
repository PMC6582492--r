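#' Collapse per-day removal records to per-season device usage
#'
#' A device is "used" in a season if its seed was removed on at least one of
#' the two days it was offered.
#'
#' @param removal data frame with columns `device_id`, `season`, `day`,
#'   `removed` (exactly one record per device x season x day).
#' @return data frame with columns `device_id`, `season`, `used` (and
#'   `grid_id` when present in `removal`).
#' @export
make_usage <- function(removal) {
  key <- interaction(removal$device_id, removal$season, drop = TRUE)
  days <- tapply(removal$day, key, function(d) length(unique(d)))
  if (any(days < 2)) stop("missing day records for some device x season")
  agg <- stats::aggregate(removed ~ device_id + season, data = removal,
                          FUN = any)
  names(agg)[names(agg) == "removed"] <- "used"
  if ("grid_id" %in% names(removal)) {
    gmap <- unique(removal[, c("device_id", "grid_id")])
    agg <- merge(agg, gmap, by = "device_id", sort = FALSE)
  }
  agg[order(agg$season, agg$device_id), , drop = FALSE]
}

#' Fisher exact test of day-to-day dependence of seed removal
#'
#' Cross-tabulates day-1 by day-2 removal over devices within one season and
#' tests independence with Fisher's exact test, flagging whether "double
#' removal" and "never removed" exceed their independence expectations (the
#' signature of devices being re-visited).
#'
#' @param removal per-day records of one season (columns `device_id`, `day`,
#'   `removed`).
#' @return list with `table` (2x2), `P`, `odds_ratio` (sample cross-product),
#'   `excess_double`, `excess_never`.
#' @export
day_dependence_test <- function(removal) {
  d1 <- removal$removed[removal$day == 1][order(removal$device_id[removal$day == 1])]
  d2 <- removal$removed[removal$day == 2][order(removal$device_id[removal$day == 2])]
  if (length(d1) != length(d2) || !length(d1)) stop("need both days for every device")
  tab <- table(factor(d1, c(TRUE, FALSE)), factor(d2, c(TRUE, FALSE)),
               dnn = c("day1", "day2"))
  if (sum(tab > 0) <= 1L) {
    warning("degenerate 2x2 table; P set to 1")
    p <- 1
  } else {
    p <- stats::fisher.test(tab)$p.value
  }
  n <- sum(tab)
  exp_double <- sum(tab[1, ]) * sum(tab[, 1]) / n
  exp_never <- sum(tab[2, ]) * sum(tab[, 2]) / n
  list(table = tab, P = p,
       odds_ratio = (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]),
       excess_double = tab[1, 1] - exp_double,
       excess_never = tab[2, 2] - exp_never)
}

#' Binomial GLM of per-cell usage proportions
#'
#' Fits the proportion of used devices per season x grid cell with a binomial
#' GLM (logit link) by maximum likelihood.
#'
#' @param used_counts data frame with columns `season`, `grid_id`, `used`
#'   (successes) and `total` (trials) per cell.
#' @param design model formula right-hand side as a string: one of
#'   `"season * grid"`, `"season + grid"`, `"season"`, `"grid"`, `"1"`.
#' @return object of class `usage_glm`: list with the fitted `glm` object,
#'   `design`, `deviance`, `df_residual`, `coefficients`.
#' @export
fit_binomial_glm <- function(used_counts, design = "season + grid") {
  if (any(used_counts$total <= 0)) stop("trials must be positive in every cell")
  dat <- data.frame(season = factor(used_counts$season,
                                    levels = intersect(c("W", "Sp", "Su", "A"),
                                                       unique(used_counts$season))),
                    grid = factor(used_counts$grid_id),
                    used = used_counts$used,
                    total = used_counts$total)
  rhs <- gsub("grid_id", "grid", design)
  fml <- stats::as.formula(paste("cbind(used, total - used) ~", rhs))
  fit <- stats::glm(fml, family = stats::binomial(), data = dat)
  if (!fit$converged) stop("IRLS did not converge")
  if (any(abs(stats::coef(fit)) > 15, na.rm = TRUE))
    warning("very large coefficient: possible separation")
  structure(list(fit = fit, design = design,
                 deviance = stats::deviance(fit),
                 df_residual = stats::df.residual(fit),
                 coefficients = stats::coef(fit)),
            class = "usage_glm")
}

#' @export
print.usage_glm <- function(x, ...) {
  cat(sprintf("Binomial GLM (~ %s): residual deviance %.3f on %d df\n",
              x$design, x$deviance, x$df_residual))
  invisible(x)
}

#' Analysis-of-deviance table for nested usage GLMs
#'
#' Compares each model against a reference model (by default the first,
#' richest one) through the change in deviance, asymptotically chi-square
#' with the difference in residual df. With the standard backwards-elimination
#' path the comparisons are full vs main effects, then each single-factor and
#' the null model vs the main-effects model.
#'
#' @param fits named list of `usage_glm` objects ordered from richest to
#'   simplest.
#' @param vs integer vector: for each model (from the second on), the index of
#'   the nested reference model it is compared against. Default compares
#'   model 2 vs 1 and all later models vs 2.
#' @return data frame with `model`, `df_residual`, `deviance`, `vs`,
#'   `delta_deviance`, `delta_df`, `P`.
#' @export
deviance_table <- function(fits, vs = NULL) {
  m <- length(fits)
  if (m < 2L) stop("need at least two models")
  if (is.null(vs)) vs <- c(1L, rep(2L, m - 2L))
  dev <- vapply(fits, function(f) f$deviance, 0)
  dfr <- vapply(fits, function(f) f$df_residual, 0)
  dd <- ddf <- pv <- rep(NA_real_, m)
  for (i in seq(2L, m)) {
    r <- vs[i - 1L]
    dd[i] <- dev[i] - dev[r]
    ddf[i] <- dfr[i] - dfr[r]
    if (ddf[i] < 0 || dd[i] < -1e-8)
      stop("models not nested in the stated order (model ", i, " vs ", r, ")")
    dd[i] <- max(dd[i], 0)
    pv[i] <- stats::pchisq(dd[i], df = max(ddf[i], 1), lower.tail = FALSE)
    if (ddf[i] == 0) pv[i] <- if (dd[i] == 0) 1 else pv[i]
  }
  nm <- names(fits)
  if (is.null(nm)) nm <- vapply(fits, function(f) f$design, "")
  data.frame(model = nm, df_residual = dfr, deviance = dev,
             vs = c(NA, nm[vs]), delta_deviance = dd, delta_df = ddf, P = pv,
             row.names = NULL)
}

#' Backwards-elimination deviance analysis of seasonal and grid effects
#'
#' Convenience wrapper fitting the full interaction model, the main-effects
#' model, each single-factor model and the null model, and tabulating the
#' standard backwards-elimination comparisons.
#'
#' @param used_counts as in [fit_binomial_glm()].
#' @return list with `fits` and the deviance `table`.
#' @export
removal_deviance_analysis <- function(used_counts) {
  designs <- c(full = "season * grid", main = "season + grid",
               season = "season", grid = "grid", null = "1")
  fits <- lapply(designs, fit_binomial_glm, used_counts = used_counts)
  list(fits = fits, table = deviance_table(fits))
}

#' Deviance / residual-df overdispersion ratio
#'
#' @param fit a `usage_glm`.
#' @return the ratio; values well above 1 suggest extra-binomial variation,
#'   in which case F-tests of the deviance changes are the robust variant.
#' @export
overdispersion_ratio <- function(fit) {
  if (fit$df_residual == 0) stop("residual df is zero")
  fit$deviance / fit$df_residual
}

#' Poisson-binomial probability mass function
#'
#' Distribution of the number of successes in independent Bernoulli trials
#' with unequal probabilities, computed by exact convolution.
#'
#' @param p vector of success probabilities.
#' @return numeric vector of length `length(p) + 1` over counts 0..length(p).
#' @export
poisson_binomial_pmf <- function(p) {
  if (any(p < 0 | p > 1)) stop("probabilities must be in [0, 1]")
  pmf <- 1
  for (pi in p) pmf <- c(pmf * (1 - pi), 0) + c(0, pmf * pi)
  pmf
}

#' Chi-square test of among-season independence of device use
#'
#' For one grid, compares the observed distribution of the number of seasons
#' (0-4) in which each device was used against the product-Bernoulli
#' expectation with per-season success probabilities estimated as the
#' proportion of used devices in that grid, i.e. a Poisson-binomial pmf
#' scaled by the number of devices. Fit is evaluated with a chi-square
#' statistic; P values are reported for both df = number of categories - 1
#' and that minus the number of estimated proportions.
#'
#' @param seasons_used integer vector: per-device count of seasons used.
#' @param p_seasons per-season use proportions for the grid (length 4 in the
#'   field design).
#' @return list with `observed`, `expected`, `chisq`, `df`, `P`, `df_est`,
#'   `P_est`, `infinite` (TRUE when a zero-expectation category is occupied).
#' @export
season_independence_test <- function(seasons_used, p_seasons) {
  k <- length(p_seasons)
  if (any(seasons_used < 0 | seasons_used > k))
    stop("counts must be in 0..length(p_seasons)")
  n <- length(seasons_used)
  obs <- tabulate(seasons_used + 1L, nbins = k + 1L)
  expd <- n * poisson_binomial_pmf(p_seasons)
  if (any(expd < 1))
    warning("expected count below 1 in some category; chi-square approximation is weak")
  infinite <- any(obs > 0 & expd == 0)
  keep <- expd > 0
  chisq <- if (infinite) Inf else sum((obs[keep] - expd[keep])^2 / expd[keep])
  df <- length(obs) - 1L   # categories - 1
  df_est <- df - 1L        # charging one further df for the estimated proportions
  list(observed = obs, expected = expd, chisq = chisq,
       df = df, P = stats::pchisq(chisq, df, lower.tail = FALSE),
       df_est = df_est, P_est = stats::pchisq(chisq, df_est, lower.tail = FALSE),
       infinite = infinite)
}
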