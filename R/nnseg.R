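#' Nearest-neighbour graph of a point set in k dimensions
#'
#' Identifies, for each point, its nearest neighbour by Euclidean distance in
#' the given coordinate space (any dimension; in the segregation analysis the
#' space is that of the eigenvalue-weighted rotated PCA scores). Ties at
#' exactly equal distance are broken by the lowest index; coincident points
#' are permitted but logged with a warning. Also computes the two structural
#' constants of Dixon's variance formulas: `R`, the number of ordered
#' reflexive (mutual nearest-neighbour) pairs, and `Q`, the number of ordered
#' pairs of distinct points sharing the same nearest neighbour.
#'
#' @param points numeric matrix or data frame, one row per point.
#' @return object of class `nn_graph`: list with `nn_index`, `R`, `Q`, `Q_k`
#'   (named vector: number of points serving as nearest neighbour to exactly k
#'   others) and `n`.
#' @export
nn_graph <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 3L) stop("at least 3 points are required")
  d <- as.matrix(stats::dist(points))
  if (any(d[upper.tri(d)] == 0))
    warning("coincident points at distance 0; ties broken by lowest index")
  diag(d) <- Inf
  nn <- apply(d, 1L, which.min)  # which.min takes the lowest index on ties
  serves <- tabulate(nn, nbins = n)
  qk <- table(serves[serves > 0])
  structure(list(nn_index = as.integer(nn),
                 R = sum(nn[nn] == seq_len(n)),
                 Q = sum(serves * (serves - 1L)),
                 Q_k = qk,
                 n = n),
            class = "nn_graph")
}

#' Nearest-neighbour contingency counts for a binary labelling
#'
#' Tallies the ordered (point, nearest neighbour) label pairs: N11 both used,
#' N10 used point with non-used neighbour, N01 and N00 likewise. Every point
#' contributes exactly one ordered pair, so the four counts sum to n.
#'
#' @param labels logical or 0/1 vector, one per point (1 = used).
#' @param graph an `nn_graph`.
#' @return object of class `pair_counts`: list with `N11`, `N10`, `N01`,
#'   `N00`, `n1`, `n0`, `n`.
#' @export
pair_counts <- function(labels, graph) {
  lab <- as.integer(as.logical(labels))
  if (length(lab) != graph$n) stop("labels do not match graph size")
  nb <- lab[graph$nn_index]
  structure(list(N11 = sum(lab == 1L & nb == 1L),
                 N10 = sum(lab == 1L & nb == 0L),
                 N01 = sum(lab == 0L & nb == 1L),
                 N00 = sum(lab == 0L & nb == 0L),
                 n1 = sum(lab), n0 = sum(1L - lab), n = graph$n),
            class = "pair_counts")
}

#' Moments of the nearest-neighbour pair counts under random labelling
#'
#' Expected values, variances and covariance of N11 and N00 when n1 "used"
#' labels are assigned at random to the n fixed points (Dixon's
#' nearest-neighbour contingency test). With p11, p111, p1111 the
#' probabilities that 2, 3, 4 randomly chosen distinct points are all used
#' (falling-factorial ratios), the variance of N11 is
#' (n+R) p11 + (2n-2R+Q) p111 + (n^2-3n-Q+R) p1111 - (n p11)^2,
#' and the covariance of N11 with N00 is (n^2-3n-Q+R) p1100 - n^2 p11 p00.
#'
#' @param n1,n0 class sizes (used, non-used); `n = n1 + n0`.
#' @param n total points.
#' @param R,Q structural constants from [nn_graph()].
#' @return list with `E11`, `E00`, `E10` (= E01), `Var11`, `Var00`, `Cov`.
#' @export
dixon_moments <- function(n1, n0, n = n1 + n0, R, Q) {
  if (n1 + n0 != n) stop("n1 + n0 must equal n")
  if (n1 < 2 && n0 < 2) stop("degenerate labelling: need a class with >= 2 members")
  ff <- function(m, k) prod(m - seq_len(k) + 1)  # falling factorial m(m-1)...(m-k+1)
  pk <- function(m, k) ff(m, k) / ff(n, k)
  var_nkk <- function(m) {
    p2 <- pk(m, 2); p3 <- pk(m, 3); p4 <- pk(m, 4)
    (n + R) * p2 + (2 * n - 2 * R + Q) * p3 + (n^2 - 3 * n - Q + R) * p4 - (n * p2)^2
  }
  p11 <- pk(n1, 2); p00 <- pk(n0, 2)
  p1100 <- n1 * (n1 - 1) * n0 * (n0 - 1) / ff(n, 4)
  list(E11 = n1 * (n1 - 1) / (n - 1),
       E00 = n0 * (n0 - 1) / (n - 1),
       E10 = n1 * n0 / (n - 1),
       Var11 = var_nkk(n1),
       Var00 = var_nkk(n0),
       Cov = (n^2 - 3 * n - Q + R) * p1100 - n^2 * p11 * p00)
}

#' Dixon's segregation test of a binary labelling over a point pattern
#'
#' Tests the null hypothesis of random labelling with the omnibus statistic
#' C = d' Sigma^{-1} d, d = (N11 - E11, N00 - E00), asymptotically chi-square
#' with 2 df, and with per-pair asymptotically normal Z statistics
#' Z = (N - E)/sqrt(Var). Positive Z indicates aggregation of that class
#' (more same-label nearest-neighbour pairs than expected).
#'
#' @param counts a `pair_counts`.
#' @param moments moments from [dixon_moments()] (computed if omitted, using
#'   `graph`).
#' @param graph the `nn_graph` (needed only when `moments` is missing).
#' @return object of class `segregation_test`: list with `C`, `df`, `P_C`,
#'   `Z11`, `P11`, `Z00`, `P00`, `E11`, `E00`, observed counts and class
#'   sizes.
#' @export
dixon_test <- function(counts, moments = NULL, graph = NULL) {
  if (is.null(moments)) {
    if (is.null(graph)) stop("supply either moments or graph")
    moments <- dixon_moments(counts$n1, counts$n0, counts$n, graph$R, graph$Q)
  }
  if (moments$Var11 <= 0 || moments$Var00 <= 0) stop("non-positive variance")
  d <- c(counts$N11 - moments$E11, counts$N00 - moments$E00)
  sig <- matrix(c(moments$Var11, moments$Cov, moments$Cov, moments$Var00), 2L)
  det_s <- det(sig)
  if (!is.finite(det_s) || det_s <= 0) stop("singular covariance matrix")
  C <- drop(t(d) %*% solve(sig, d))
  z11 <- d[1] / sqrt(moments$Var11)
  z00 <- d[2] / sqrt(moments$Var00)
  structure(list(C = C, df = 2L,
                 P_C = stats::pchisq(C, 2L, lower.tail = FALSE),
                 Z11 = z11, P11 = 2 * stats::pnorm(-abs(z11)),
                 Z00 = z00, P00 = 2 * stats::pnorm(-abs(z00)),
                 E11 = moments$E11, E00 = moments$E00,
                 N11 = counts$N11, N00 = counts$N00,
                 n1 = counts$n1, n0 = counts$n0, n = counts$n),
            class = "segregation_test")
}

#' @export
print.segregation_test <- function(x, digits = 3, ...) {
  cat("Nearest-neighbour contingency segregation test (random labelling null)\n")
  cat(sprintf("  n = %d (used %d / non-used %d)\n", x$n, x$n1, x$n0))
  cat(sprintf("  N11 = %d (expected %.1f), Z = %.3f, P = %.3g\n",
              x$N11, x$E11, x$Z11, x$P11))
  cat(sprintf("  N00 = %d (expected %.1f), Z = %.3f, P = %.3g\n",
              x$N00, x$E00, x$Z00, x$P00))
  cat(sprintf("  C = %.3f on %d df, P = %.3g\n", x$C, x$df, x$P_C))
  invisible(x)
}

#' Monte-Carlo random-labelling null distributions
#'
#' Companion to the asymptotic test: permutes the n1 "used" labels uniformly
#' over the fixed points and records N11, N00 and C for each permutation.
#'
#' @param points coordinate matrix.
#' @param n1 number of used labels.
#' @param n_sim number of permutations (>= 1000).
#' @param seed integer seed.
#' @return list with vectors `N11`, `N00`, `C`, plus the `graph` and analytic
#'   `moments` used.
#' @export
mc_random_labelling <- function(points, n1, n_sim = 1999L, seed = NULL) {
  if (n_sim < 1000L) stop("n_sim must be >= 1000")
  if (!is.null(seed)) set.seed(seed)
  g <- nn_graph(points)
  n <- g$n
  if (n1 > n) stop("n1 exceeds n")
  mom <- if (n1 >= 2 || (n - n1) >= 2)
    dixon_moments(n1, n - n1, n, g$R, g$Q) else NULL
  sig_inv <- if (!is.null(mom)) {
    s <- matrix(c(mom$Var11, mom$Cov, mom$Cov, mom$Var00), 2L)
    if (det(s) > 0) solve(s) else NULL
  } else NULL
  N11 <- N00 <- Cs <- numeric(n_sim)
  lab <- integer(n)
  for (s in seq_len(n_sim)) {
    lab[] <- 0L
    lab[sample.int(n, n1)] <- 1L
    nb <- lab[g$nn_index]
    N11[s] <- sum(lab & nb)
    N00[s] <- sum(!lab & !nb)
    if (!is.null(sig_inv)) {
      d <- c(N11[s] - mom$E11, N00[s] - mom$E00)
      Cs[s] <- drop(t(d) %*% sig_inv %*% d)
    }
  }
  list(N11 = N11, N00 = N00, C = Cs, graph = g, moments = mom)
}
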