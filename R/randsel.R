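#' Two-tailed Monte-Carlo pseudo-P value
#'
#' P = 2 * (number of null values at least as extreme as the observed, with
#' the observed counted once) / (number of samples including the observed),
#' capped at 1. "At least as extreme" is operationalised as the smaller of the
#' two tail counts (values >= observed vs values <= observed), so the test is
#' two-tailed for any statistic.
#'
#' @param observed observed statistic.
#' @param null numeric vector of null statistic values (or a
#'   `null_distribution`).
#' @return pseudo-P in (0, 1].
#' @examples
#' pseudo_p(10, runif(1999))  # 2/2000 = 0.001
#' @export
pseudo_p <- function(observed, null) {
  if (inherits(null, "null_distribution")) null <- null$sample
  if (!length(null)) stop("empty null distribution")
  tail_count <- min(sum(null >= observed), sum(null <= observed))
  min(1, 2 * (tail_count + 1) / (length(null) + 1))
}

new_null_distribution <- function(sample, observed, statistic, model, seed) {
  structure(list(sample = sample, observed = observed,
                 statistic = statistic, model = model,
                 n_samples = length(sample), seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Randomization null for the %s (%s model, %d samples)\n",
              x$statistic, x$model, x$n_samples))
  cat(sprintf("  observed %.4f | null mean %.4f, 95%% band [%.4f, %.4f]\n",
              x$observed, mean(x$sample),
              stats::quantile(x$sample, 0.025), stats::quantile(x$sample, 0.975)))
  cat(sprintf("  pseudo-P = %.4g\n", pseudo_p(x$observed, x$sample)))
  invisible(x)
}

stat_fun <- function(statistic) {
  switch(statistic,
         mean = mean,
         variance = stats::var,
         median = stats::median,
         stop("unknown statistic: ", statistic))
}

#' Pooled randomization null for a used-versus-available statistic
#'
#' Draws `n_used` values without replacement from all available values in each
#' iteration and records the statistic, giving the null distribution under no
#' selection at any scale.
#'
#' @param values numeric vector over all available devices.
#' @param n_used number of used devices.
#' @param statistic `"mean"`, `"variance"` or `"median"`.
#' @param n_samples iterations (convention: 4999 for the mean, 1999 for the
#'   variance).
#' @param seed integer seed.
#' @param observed optional observed statistic to store alongside.
#' @return a `null_distribution`.
#' @export
pooled_null <- function(values, n_used, statistic = "mean",
                        n_samples = 4999L, seed = NULL, observed = NA_real_) {
  n <- length(values)
  if (n_used < 1 || n_used > n) stop("n_used must be in 1..length(values)")
  if (!is.null(seed)) set.seed(seed)
  f <- stat_fun(statistic)
  sam <- vapply(seq_len(n_samples),
                function(i) f(values[sample.int(n, n_used)]), 0)
  new_null_distribution(sam, observed, statistic, "pooled", seed)
}

#' Grid-stratified randomization null
#'
#' Draws, in each iteration, the observed number of used devices from each
#' grid separately (without replacement within grid), pools the draws and
#' records the statistic. This controls for selective use of space at the grid
#' scale: the null expectation of the mean is the average of the grid means
#' weighted by the number of used devices in each grid.
#'
#' @param values_by_grid named list of numeric vectors, one per grid.
#' @param used_by_grid named integer vector of used counts per grid.
#' @param statistic,n_samples,seed,observed as in [pooled_null()].
#' @return a `null_distribution`.
#' @export
stratified_null <- function(values_by_grid, used_by_grid, statistic = "mean",
                            n_samples = 4999L, seed = NULL, observed = NA_real_) {
  grids <- names(values_by_grid)
  if (is.null(grids)) grids <- as.character(seq_along(values_by_grid))
  if (!is.null(names(used_by_grid))) used_by_grid <- used_by_grid[grids]
  if (length(used_by_grid) != length(values_by_grid))
    stop("used_by_grid does not match values_by_grid")
  sizes <- lengths(values_by_grid)
  if (anyNA(used_by_grid) || any(used_by_grid < 0))
    stop("invalid used count")
  if (any(used_by_grid > sizes))
    stop("stratum oversampled: ",
         paste(grids[used_by_grid > sizes], collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  f <- stat_fun(statistic)
  idx <- seq_along(values_by_grid)
  sam <- vapply(seq_len(n_samples), function(i) {
    f(unlist(lapply(idx, function(g) {
      v <- values_by_grid[[g]]
      v[sample.int(length(v), used_by_grid[[g]])]
    }), use.names = FALSE))
  }, 0)
  new_null_distribution(sam, observed, statistic, "stratified", seed)
}

#' Randomization test of microhabitat selection on one score axis
#'
#' Compares the observed statistic (mean or variance) of the scores of used
#' devices against a pooled or grid-stratified resampling null, reporting the
#' null expectation, the 95% band (2.5 and 97.5 percentiles) and the
#' two-tailed pseudo-P.
#'
#' @param scores numeric vector of component scores over all devices.
#' @param used_mask logical vector, TRUE for used devices.
#' @param grid_ids grid identifier per device (required for the stratified
#'   model).
#' @param statistic `"mean"` or `"variance"`.
#' @param model `"pooled"` or `"stratified"`.
#' @param n_samples iterations; default 4999 for the mean, 1999 otherwise.
#' @param seed integer seed.
#' @return object of class `selection_test`: list with `observed`,
#'   `expectation`, `lo`, `hi`, `pseudo_P`, `statistic`, `model`, `n_used`,
#'   and the `null` distribution.
#' @export
selection_test <- function(scores, used_mask, grid_ids = NULL,
                           statistic = "mean",
                           model = c("pooled", "stratified"),
                           n_samples = if (statistic == "mean") 4999L else 1999L,
                           seed = NULL) {
  model <- match.arg(model)
  used_mask <- as.logical(used_mask)
  if (length(used_mask) != length(scores)) stop("used_mask does not match scores")
  obs <- stat_fun(statistic)(scores[used_mask])
  null <- if (model == "pooled") {
    pooled_null(scores, sum(used_mask), statistic, n_samples, seed, obs)
  } else {
    if (is.null(grid_ids)) stop("grid_ids required for the stratified model")
    vb <- split(scores, grid_ids)
    ub <- vapply(split(used_mask, grid_ids), sum, 0L)
    stratified_null(vb, ub, statistic, n_samples, seed, obs)
  }
  structure(list(observed = obs,
                 expectation = mean(null$sample),
                 lo = unname(stats::quantile(null$sample, 0.025, type = 1)),
                 hi = unname(stats::quantile(null$sample, 0.975, type = 1)),
                 pseudo_P = pseudo_p(obs, null),
                 statistic = statistic, model = model,
                 n_used = sum(used_mask), null = null),
            class = "selection_test")
}

#' @export
print.selection_test <- function(x, ...) {
  cat(sprintf("Selection test (%s of scores, %s null, %d used)\n",
              x$statistic, x$model, x$n_used))
  cat(sprintf("  observed %.4f vs expected %.4f [%.4f, %.4f], pseudo-P = %.4g\n",
              x$observed, x$expectation, x$lo, x$hi, x$pseudo_P))
  invisible(x)
}
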