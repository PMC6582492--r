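#' Percentage of used-used joins in a distance class
#'
#' Joins are unordered device pairs linked by the binary weight matrix of one
#' distance class; the statistic is 100 times the fraction of those joins
#' whose two endpoints were both used.
#'
#' @param used logical or 0/1 vector over the devices of one grid.
#' @param W binary symmetric weight matrix (one distance class).
#' @return percentage in [0, 100].
#' @export
join_count_pct <- function(used, W) {
  u <- as.logical(used)
  jl <- weight_joins(W)
  if (jl$n_joins == 0L) stop("weight matrix has no joins")
  100 * sum(u[jl$i] & u[jl$j]) / jl$n_joins
}

join_pct_from_joins <- function(u, jl) {
  100 * sum(u[jl$i] & u[jl$j]) / jl$n_joins
}

make_envelope <- function(observed, sims, null_model, n_sim, seed, class_index) {
  structure(list(class_index = class_index,
                 observed = observed,
                 median = stats::median(sims),
                 mean = mean(sims),
                 lo = unname(stats::quantile(sims, 0.025, type = 1)),
                 hi = unname(stats::quantile(sims, 0.975, type = 1)),
                 pseudo_P = pseudo_p(observed, sims),
                 null_model = null_model, n_sim = n_sim, seed = seed,
                 sims = sims),
            class = "join_envelope")
}

#' @export
print.join_envelope <- function(x, ...) {
  cat(sprintf("Join-count envelope (%s null, %d simulations)\n",
              x$null_model, x$n_sim))
  cat(sprintf("  observed %.2f%% | null median %.2f%% [%.2f, %.2f], pseudo-P = %.4g\n",
              x$observed, x$median, x$lo, x$hi, x$pseudo_P))
  invisible(x)
}

#' Monte-Carlo join-count envelope under Complete Spatial Randomness
#'
#' Conditions on the observed number of used devices: each simulation selects
#' `n_used` of the `n` devices uniformly without replacement and recomputes
#' the percentage of used-used joins. The envelope is the 2.5/97.5 percentile
#' band, the expected value the null median, and the pseudo-P the two-tailed
#' Monte-Carlo probability with denominator `n_sim + 1`.
#'
#' @param used observed binary usage vector (its sum sets `n_used`), or NULL
#'   if `n_used` is given directly.
#' @param W binary weight matrix for the distance class.
#' @param n_used number of used devices (defaults to `sum(used)`).
#' @param n_sim simulations (default 1999, so the pseudo-P denominator is
#'   2000).
#' @param seed integer seed.
#' @return a `join_envelope`.
#' @export
csr_envelope <- function(used = NULL, W, n_used = sum(used), n_sim = 1999L,
                         seed = NULL) {
  n <- nrow(W)
  if (n_used < 0 || n_used > n) stop("n_used must be in 0..n")
  if (!is.null(seed)) set.seed(seed)
  jl <- weight_joins(W)
  if (jl$n_joins == 0L) stop("weight matrix has no joins")
  obs <- if (is.null(used)) NA_real_ else join_pct_from_joins(as.logical(used), jl)
  u <- logical(n)
  sims <- vapply(seq_len(n_sim), function(s) {
    u[] <- FALSE
    u[sample.int(n, n_used)] <- TRUE
    join_pct_from_joins(u, jl)
  }, 0)
  make_envelope(obs, sims, "CSR", n_sim, seed, attr(W, "class_index"))
}

#' Weighted random sampling without replacement
#'
#' Sequential scheme: at each step one index is selected with probability
#' proportional to the weights of the indices still available, then removed,
#' until `k` distinct indices are drawn (successive sampling). This is the
#' sampling mechanism of the heterogeneous distance-to-tree null model.
#'
#' @param weights non-negative weights.
#' @param k number of indices to draw; at most the number of positive
#'   weights.
#' @param seed integer seed.
#' @return integer vector of `k` distinct indices.
#' @export
weighted_sample_without_replacement <- function(weights, k, seed = NULL) {
  if (any(weights < 0)) stop("weights must be non-negative")
  npos <- sum(weights > 0)
  if (k > npos) stop("k exceeds the number of positive weights")
  if (!is.null(seed)) set.seed(seed)
  # base R's sample() with prob and replace = FALSE implements exactly the
  # sequential proportional-to-remaining-weights scheme
  sample.int(length(weights), k, replace = FALSE, prob = weights)
}

#' Monte-Carlo join-count envelope under the Distance-To-Tree null
#'
#' Heterogeneous-Poisson null: each simulation draws `n_used` devices by
#' weighted sampling without replacement with probabilities proportional to
#' the DTT relative-use weights (0.6/0.3/0.1/0 by distance band to tall
#' trees), inducing first-order aggregation of use around trees. Envelope and
#' pseudo-P as in [csr_envelope()].
#'
#' @param weights per-device relative use weights (see [dtt_weights()]).
#' @param used observed binary usage vector, or NULL.
#' @param W binary weight matrix for the distance class.
#' @param n_used number of used devices (defaults to `sum(used)`).
#' @param n_sim,seed as in [csr_envelope()].
#' @return a `join_envelope`.
#' @export
dtt_envelope <- function(weights, used = NULL, W, n_used = sum(used),
                         n_sim = 1999L, seed = NULL) {
  n <- nrow(W)
  if (length(weights) != n) stop("weights do not match W")
  if (sum(weights > 0) < n_used)
    stop("fewer positive-weight devices than n_used")
  if (!is.null(seed)) set.seed(seed)
  jl <- weight_joins(W)
  if (jl$n_joins == 0L) stop("weight matrix has no joins")
  obs <- if (is.null(used)) NA_real_ else join_pct_from_joins(as.logical(used), jl)
  u <- logical(n)
  sims <- vapply(seq_len(n_sim), function(s) {
    u[] <- FALSE
    u[sample.int(n, n_used, prob = weights)] <- TRUE
    join_pct_from_joins(u, jl)
  }, 0)
  make_envelope(obs, sims, "DTT", n_sim, seed, attr(W, "class_index"))
}

#' Moran's I of a continuous variable for one binary weight matrix
#'
#' I = (n/S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2,
#' with S0 the sum of all weights. Under the permutation null its expectation
#' is -1/(n-1).
#'
#' @param x numeric vector over devices (non-constant).
#' @param W binary symmetric weight matrix.
#' @return Moran's I.
#' @export
morans_i <- function(x, W) {
  n <- length(x)
  if (n != nrow(W)) stop("x does not match W")
  z <- x - mean(x)
  denom <- sum(z^2)
  if (denom == 0) stop("x is constant")
  jl <- weight_joins(W)
  s0 <- 2 * jl$n_joins
  if (s0 == 0) stop("weight matrix has no joins")
  (n / s0) * (2 * sum(z[jl$i] * z[jl$j])) / denom
}

#' Permutation envelope for Moran's I across distance classes
#'
#' Permutes the variable over devices `n_sim` times, recomputing Moran's I in
#' every distance class from the same permutation, and reports point-wise
#' 2.5/97.5 percentile intervals, flagging observed values outside them
#' (P < 0.05, two-tailed pseudo-P with denominator `n_sim + 1`).
#'
#' @param x numeric vector over devices.
#' @param W_list list of binary weight matrices (one per distance class).
#' @param n_sim permutations.
#' @param seed integer seed.
#' @return data frame of class `moran_correlogram`: one row per class with
#'   `class_index`, `observed`, `expectation` (-1/(n-1)), `lo`, `hi`,
#'   `pseudo_P`, `outside`.
#' @export
morans_envelope <- function(x, W_list, n_sim = 1999L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  z <- x - mean(x)
  denom <- sum(z^2)
  if (denom == 0) stop("x is constant")
  jls <- lapply(W_list, weight_joins)
  i_of <- function(zz, jl) (n / (2 * jl$n_joins)) * (2 * sum(zz[jl$i] * zz[jl$j])) / denom
  obs <- vapply(jls, function(jl) i_of(z, jl), 0)
  sims <- matrix(0, n_sim, length(jls))
  for (s in seq_len(n_sim)) {
    zp <- z[sample.int(n)]
    sims[s, ] <- vapply(jls, function(jl) i_of(zp, jl), 0)
  }
  res <- data.frame(
    class_index = vapply(W_list, function(w) {
      ci <- attr(w, "class_index"); if (is.null(ci)) NA_integer_ else ci
    }, 0L),
    observed = obs,
    expectation = -1 / (n - 1),
    lo = apply(sims, 2L, stats::quantile, 0.025, type = 1),
    hi = apply(sims, 2L, stats::quantile, 0.975, type = 1),
    pseudo_P = vapply(seq_along(jls), function(k) pseudo_p(obs[k], sims[, k]), 0))
  res$outside <- res$observed < res$lo | res$observed > res$hi
  class(res) <- c("moran_correlogram", class(res))
  res
}
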