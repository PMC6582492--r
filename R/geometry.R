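#' Pairwise Euclidean distances between devices
#'
#' @param points numeric matrix (or data frame) of coordinates in metres, one
#'   row per device, any number of columns.
#' @return symmetric distance matrix with zero diagonal.
#' @examples
#' pairwise_distances(rbind(c(0, 0), c(3, 4)))
#' @export
pairwise_distances <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L)
    stop("at least 2 points are required")
  if (!all(is.finite(points)))
    stop("coordinates must be finite")
  d <- as.matrix(stats::dist(points))
  dimnames(d) <- NULL
  d
}

#' Binary spatial weight matrices for a set of distance classes
#'
#' Builds one binary, symmetric weight matrix per distance class. A pair
#' (i, j) belongs to the class with bounds (lower, upper] iff
#' lower < d(i, j) <= upper, so consecutive classes are mutually exclusive.
#' The default bounds are the four classes of a 5-m lattice: (0, 8.5],
#' (8.5, 12.5], (12.5, 17], (17, 22] metres, for which an interior device of a
#' 10 x 10 grid has 8, 12, 16 and 24 neighbours respectively.
#'
#' @param dist_matrix symmetric distance matrix (e.g. from
#'   [pairwise_distances()]).
#' @param class_bounds list of `c(lower, upper)` pairs, strictly increasing and
#'   non-overlapping.
#' @return list of `weight_matrix` objects (binary matrices with attributes
#'   `class_bounds` and `class_index`).
#' @export
distance_class_weights <- function(dist_matrix,
                                   class_bounds = list(c(0, 8.5), c(8.5, 12.5),
                                                       c(12.5, 17), c(17, 22))) {
  bounds <- do.call(rbind, lapply(class_bounds, function(b) {
    if (length(b) != 2L || b[1] >= b[2]) stop("each class bound must be c(lower, upper) with lower < upper")
    b
  }))
  if (nrow(bounds) > 1L && any(bounds[-1L, 1L] < bounds[-nrow(bounds), 2L]))
    stop("class bounds must be non-overlapping and increasing")
  out <- vector("list", nrow(bounds))
  for (k in seq_len(nrow(bounds))) {
    w <- (dist_matrix > bounds[k, 1L] & dist_matrix <= bounds[k, 2L]) * 1L
    diag(w) <- 0L
    attr(w, "class_bounds") <- bounds[k, ]
    attr(w, "class_index") <- k
    class(w) <- c("weight_matrix", class(w))
    out[[k]] <- w
  }
  out
}

# Unordered (i < j) join list of a binary weight matrix; used by the
# envelope machinery so each simulation costs O(#joins), not O(n^2).
weight_joins <- function(W) {
  idx <- which(W != 0 & upper.tri(W), arr.ind = TRUE)
  list(i = idx[, 1L], j = idx[, 2L], n_joins = nrow(idx))
}

#' Distance from each device to the nearest tall tree
#'
#' Computes, per device, the distance to the nearest tree taller than 3 m
#' (`d_tree3`) and to the nearest algarrobo taller than 4 m (`d_alg4`).
#' When no tree qualifies the distance is `Inf`.
#'
#' @param devices data frame with columns `device_id`, `x`, `y`.
#' @param trees data frame with columns `x`, `y`, `height`, `is_algarrobo`
#'   (may have zero rows).
#' @return data frame with columns `device_id`, `d_tree3`, `d_alg4`.
#' @export
nearest_tree_distances <- function(devices, trees) {
  min_dist <- function(keep) {
    if (!any(keep)) return(rep(Inf, nrow(devices)))
    dx <- outer(devices$x, trees$x[keep], "-")
    dy <- outer(devices$y, trees$y[keep], "-")
    apply(sqrt(dx^2 + dy^2), 1L, min)
  }
  tall <- nrow(trees) > 0 & if (nrow(trees)) trees$height > 3 else logical(0)
  alg <- nrow(trees) > 0 & if (nrow(trees)) trees$height > 4 & trees$is_algarrobo else logical(0)
  data.frame(device_id = devices$device_id,
             d_tree3 = min_dist(tall),
             d_alg4 = min_dist(alg),
             stringsAsFactors = FALSE)
}

#' Distance-to-tree (DTT) relative use weights
#'
#' Maps tree distances to the relative probability of use of the
#' heterogeneous-Poisson null model: 0.6 for devices at < 5 m of an algarrobo
#' > 4 m high, 0.3 at 5-10 m (closed at 10), 0.1 at < 10 m of any tree > 3 m
#' high, and 0 otherwise. Rules are evaluated in that order; the algarrobo
#' bands take precedence over the generic tree band.
#'
#' @param tree_distances data frame from [nearest_tree_distances()].
#' @return numeric vector of weights in \{0, 0.1, 0.3, 0.6\}, named by
#'   `device_id`.
#' @export
dtt_weights <- function(tree_distances) {
  da <- tree_distances$d_alg4
  dt <- tree_distances$d_tree3
  w <- ifelse(da < 5, 0.6,
       ifelse(da <= 10, 0.3,
       ifelse(dt < 10, 0.1, 0)))
  names(w) <- tree_distances$device_id
  w
}
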