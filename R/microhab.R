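#' Names of the ten microhabitat cover variables
#' @export
cover_variables <- function() {
  c("grasses", "dry_standing_grasses", "low_shrubs", "tall_shrubs_lt1m",
    "tall_shrubs_gt1m", "trees_lt1m", "trees_gt1m", "no_vegetation",
    "bare_ground", "dense_litter")
}

#' Transform and standardise cover proportions
#'
#' Applies a per-variable symmetrising transformation to cover proportions and
#' standardises each column to zero mean and unit variance, the usual
#' preparation for a correlation-matrix PCA. Supported transformations:
#' `"arcsin"` (arcsine of the square root, the default for proportions),
#' `"sqrt"`, `"log"` (with a half-resolution offset of 0.025 so zero covers
#' stay finite), and `"identity"`.
#'
#' @param covers data frame containing the ten cover columns (see
#'   [cover_variables()]), plus any identifier columns (ignored).
#' @param transform_map named character vector mapping variable names to
#'   transformation names; variables not named get `default`.
#' @param default transformation for unmapped variables.
#' @return numeric matrix of standardised transformed values with attribute
#'   `transform_map`; row order follows `covers`.
#' @export
transform_covers <- function(covers, transform_map = NULL, default = "arcsin") {
  vars <- cover_variables()
  missing <- setdiff(vars, names(covers))
  if (length(missing))
    stop("missing cover columns: ", paste(missing, collapse = ", "))
  map <- stats::setNames(rep(default, length(vars)), vars)
  if (!is.null(transform_map)) map[names(transform_map)] <- transform_map
  funs <- list(arcsin = function(p) asin(sqrt(p)),
               sqrt = sqrt,
               log = function(p) log(p + 0.025),
               identity = identity)
  bad <- setdiff(unique(map), names(funs))
  if (length(bad)) stop("unknown transformation: ", paste(bad, collapse = ", "))
  x <- sapply(vars, function(v) funs[[map[[v]]]](covers[[v]]))
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance variable(s): ", paste(vars[sds == 0], collapse = ", "))
  z <- scale(x)
  dimnames(z) <- list(NULL, vars)
  attr(z, "transform_map") <- map
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  z
}

#' Broken-stick expected eigenvalue proportions
#'
#' Expected ordered proportions of variance when a unit stick is broken at
#' random into `p` pieces: b_k = (1/p) * sum_{i=k..p} 1/i. A component is
#' retained under the broken-stick rule while its observed proportion of
#' variance exceeds b_k.
#'
#' @param p number of variables.
#' @return numeric vector of length `p` summing to 1.
#' @examples
#' broken_stick(10)[1]  # 0.29290
#' @export
broken_stick <- function(p) {
  if (p < 1) stop("p must be >= 1")
  rev(cumsum(1 / rev(seq_len(p)))) / p
}

#' PCA of the correlation matrix with varimax rotation of retained axes
#'
#' Eigen-decomposes the correlation matrix of a standardised data matrix,
#' retains components by the requested rule, and applies a varimax rotation
#' (with Kaiser row normalisation) to the retained loadings only. Component
#' signs are oriented so that, when the canonical cover variables are present,
#' `dense_litter` loads positively on axis 1 (a cover-vs-open axis),
#' `trees_gt1m` positively on axis 2 (a tree axis) and `dry_standing_grasses`
#' positively on axis 3 (a grass-vs-low-shrub axis).
#'
#' @param x standardised matrix from [transform_covers()] (rows = devices).
#' @param retention `"kaiser"` (eigenvalue > 1), `"broken_stick"`, or
#'   `"scree"` (eigenvalues above a straight line fitted to the tail half of
#'   the scree plot).
#' @param rotation `"varimax"` or `"none"`.
#' @return object of class `pca_model`: list with `loadings` (p x k rotated
#'   loadings), `eigenvalues` (all p), `retained`, `rotmat`, `pct_variance`,
#'   `cum_pct_variance`, `rotation`, `transform_map`.
#' @export
pca_varimax <- function(x, retention = c("kaiser", "broken_stick", "scree"),
                        rotation = c("varimax", "none")) {
  retention <- match.arg(retention)
  rotation <- match.arg(rotation)
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("non-finite values in input")
  if (nrow(x) <= ncol(x)) stop("need more rows than variables")
  p <- ncol(x)
  eg <- eigen(stats::cor(x), symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  k <- switch(retention,
    kaiser = sum(ev > 1),
    broken_stick = {
      ok <- (ev / p) > broken_stick(p)
      if (!ok[1]) 0L else max(which(cumsum(!ok) == 0))
    },
    scree = {
      tail_idx <- seq(ceiling(p / 2), p)
      fit <- stats::lm.fit(cbind(1, tail_idx), ev[tail_idx])
      line <- fit$coefficients[1] + fit$coefficients[2] * seq_len(p)
      above <- ev > line
      if (!above[1]) 0L else max(which(cumsum(!above) == 0))
    })
  if (k < 1L) stop("retention rule '", retention, "' retains no component")
  vec <- eg$vectors[, seq_len(k), drop = FALSE]
  load <- vec %*% diag(sqrt(ev[seq_len(k)]), k)
  rotmat <- diag(k)
  if (rotation == "varimax" && k > 1L) {
    vm <- stats::varimax(load, normalize = TRUE)
    load <- load %*% vm$rotmat
    rotmat <- vm$rotmat
  }
  # orient axes by the canonical marker variables when available
  markers <- c("dense_litter", "trees_gt1m", "dry_standing_grasses")
  vn <- colnames(x)
  if (is.null(vn)) vn <- paste0("V", seq_len(p))
  for (a in seq_len(min(k, length(markers)))) {
    m <- match(markers[a], vn)
    if (!is.na(m) && load[m, a] < 0) {
      load[, a] <- -load[, a]
      rotmat[, a] <- -rotmat[, a]
    }
  }
  dimnames(load) <- list(vn, paste0("PC", seq_len(k)))
  structure(list(loadings = load,
                 eigenvalues = ev,
                 retained = k,
                 rotmat = rotmat,
                 vectors = vec,
                 pct_variance = 100 * ev / p,
                 cum_pct_variance = cumsum(100 * ev / p),
                 retention = retention,
                 rotation = rotation,
                 transform_map = attr(x, "transform_map")),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("Correlation-matrix PCA (", x$rotation, " rotation), ",
      x$retained, " axes retained by the ", x$retention, " rule\n", sep = "")
  cat("Eigenvalues:", paste(round(x$eigenvalues, 3), collapse = " "), "\n")
  cat("Cumulative % variance of retained axes:",
      round(x$cum_pct_variance[x$retained], 1), "\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' Rotated component scores, optionally eigenvalue-weighted
#'
#' Computes unit-variance rotated component scores and, when requested, the
#' eigenvalue-weighted copy in which each axis score is multiplied by the
#' (pre-rotation) eigenvalue of its component, so that axes enter
#' multidimensional distance computations in proportion to the variability
#' they represent.
#'
#' @param model a `pca_model`.
#' @param x the standardised matrix the model was fitted on (or new data with
#'   the same columns).
#' @param device_id optional identifier vector for the rows.
#' @param weighted logical; multiply each axis by its eigenvalue.
#' @return data frame with `device_id` (if given) and one column per retained
#'   component; attribute `weighted` records the choice.
#' @export
weighted_scores <- function(model, x, device_id = NULL, weighted = TRUE) {
  x <- as.matrix(x)
  if (ncol(x) != nrow(model$loadings)) stop("dimension mismatch with model")
  k <- model$retained
  u <- x %*% model$vectors %*% diag(1 / sqrt(model$eigenvalues[seq_len(k)]), k)
  s <- u %*% model$rotmat
  if (weighted) s <- s %*% diag(model$eigenvalues[seq_len(k)], k)
  s <- as.data.frame(s)
  names(s) <- colnames(model$loadings)
  if (!is.null(device_id)) s <- cbind(device_id = device_id, s)
  attr(s, "weighted") <- weighted
  s
}
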