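# Deterministic sub-seed derivation: one master seed feeds named substreams so
# that each generative stage is reproducible independently of the others.
derive_seed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Regular grids of seed-offer devices
#'
#' Builds the device table of a seed-offer experiment: `n_grids` rectangular
#' lattices of `rows` x `cols` devices spaced `spacing_m` metres apart. The
#' field design is three 10 x 10 grids at 5-m spacing (300 devices).
#'
#' @param n_grids number of grids (default grid ids J, F, V).
#' @param rows,cols lattice dimensions (>= 2).
#' @param spacing_m inter-device spacing in metres (> 0).
#' @param origins optional list of `c(x, y)` origins per grid; default places
#'   grids far apart along x.
#' @param grid_ids optional character ids.
#' @return data frame with `device_id`, `grid_id`, `row`, `col` (0-based),
#'   `x`, `y`.
#' @export
make_grids <- function(n_grids = 3L, rows = 10L, cols = 10L, spacing_m = 5,
                       origins = NULL, grid_ids = NULL) {
  if (rows < 2L || cols < 2L) stop("rows and cols must be >= 2")
  if (spacing_m <= 0) stop("spacing must be positive")
  if (is.null(grid_ids))
    grid_ids <- if (n_grids <= 3L) c("J", "F", "V")[seq_len(n_grids)]
                else paste0("G", seq_len(n_grids))
  if (is.null(origins))
    origins <- lapply(seq_len(n_grids) - 1L,
                      function(g) c(g * (cols + 10) * spacing_m, 0))
  out <- do.call(rbind, lapply(seq_len(n_grids), function(g) {
    idx <- expand.grid(col = seq_len(cols) - 1L, row = seq_len(rows) - 1L)
    data.frame(device_id = sprintf("%s%03d", grid_ids[g], seq_len(rows * cols)),
               grid_id = grid_ids[g],
               row = idx$row, col = idx$col,
               x = origins[[g]][1] + spacing_m * idx$col,
               y = origins[[g]][2] + spacing_m * idx$row,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Random tall-tree map over a rectangular extent
#'
#' Homogeneous Poisson number of trees over the extent, uniform positions,
#' heights drawn from `height_law` (support above 3 m so every mapped tree is
#' "tall"), and a Bernoulli algarrobo indicator. Grid-specific tree densities
#' reproduce the field situation in which grids differ in their distance to
#' tall trees.
#'
#' @param extent `c(xmin, xmax, ymin, ymax)` in metres.
#' @param intensity_per_ha expected trees per hectare (>= 0).
#' @param height_law function(n) returning n heights in metres > 3; default
#'   3 + Exp(mean 1.5).
#' @param frac_algarrobo probability a tree is an algarrobo.
#' @param seed integer seed.
#' @return data frame with `tree_id`, `x`, `y`, `height`, `is_algarrobo`.
#' @export
place_trees <- function(extent, intensity_per_ha, height_law = NULL,
                        frac_algarrobo = 0.7, seed = NULL) {
  if (intensity_per_ha < 0) stop("intensity must be >= 0")
  if (is.null(height_law)) height_law <- function(n) 3 + stats::rexp(n, 1 / 1.5)
  if (!is.null(seed)) set.seed(seed)
  area_ha <- (extent[2] - extent[1]) * (extent[4] - extent[3]) / 1e4
  n <- stats::rpois(1L, intensity_per_ha * area_ha)
  if (n == 0L) {
    if (intensity_per_ha == 0) warning("tree intensity 0: empty tree map")
    return(data.frame(tree_id = character(0), x = numeric(0), y = numeric(0),
                      height = numeric(0), is_algarrobo = logical(0)))
  }
  data.frame(tree_id = sprintf("T%03d", seq_len(n)),
             x = stats::runif(n, extent[1], extent[2]),
             y = stats::runif(n, extent[3], extent[4]),
             height = height_law(n),
             is_algarrobo = stats::runif(n) < frac_algarrobo,
             stringsAsFactors = FALSE)
}

#' Default microhabitat archetype parameters
#'
#' Per-category intercept-point probabilities for the seven vegetation
#' strata plus the dense-litter probability and the category mixing weights.
#' Categories mirror the a-priori field classification: beneath trees, tall
#' shrubs, low shrubs, grasses, bare soil, and intermediate. Profiles are
#' chosen so the generated covers carry the field's three-axis structure: a
#' general woody-cover-and-litter versus open axis, a tree axis, and a
#' grass versus low-shrub axis.
#'
#' @return list with `profiles` (category x variable probabilities),
#'   `litter_p`, `category_weights`, `canopy_radius_m`.
#' @export
default_archetypes <- function() {
  vars <- c("grasses", "dry_standing_grasses", "low_shrubs",
            "tall_shrubs_lt1m", "tall_shrubs_gt1m", "trees_lt1m", "trees_gt1m")
  profiles <- rbind(
    tree         = c(0.10, 0.05, 0.05, 0.15, 0.15, 0.55, 0.60),
    tall_shrub   = c(0.10, 0.05, 0.10, 0.60, 0.55, 0.05, 0.05),
    low_shrub    = c(0.10, 0.05, 0.60, 0.10, 0.05, 0.03, 0.03),
    grass        = c(0.60, 0.45, 0.08, 0.05, 0.03, 0.02, 0.02),
    bare         = c(0.02, 0.01, 0.02, 0.02, 0.01, 0.01, 0.01),
    intermediate = c(0.25, 0.15, 0.20, 0.20, 0.15, 0.08, 0.08))
  colnames(profiles) <- vars
  list(profiles = profiles,
       litter_p = c(tree = 0.85, tall_shrub = 0.80, low_shrub = 0.45,
                    grass = 0.35, bare = 0.05, intermediate = 0.50),
       category_weights = c(tall_shrub = 0.22, low_shrub = 0.18,
                            grass = 0.18, bare = 0.20, intermediate = 0.22),
       canopy_radius_m = 2)
}

#' Synthetic microhabitat cover table
#'
#' Assigns each device a latent microhabitat category (devices within the
#' canopy radius of a mapped tree are forced to "tree"; the rest are drawn
#' from the category mixing weights) and simulates the 20-point intercept
#' sampling: at each of 20 points every vegetation stratum is touched
#' independently with its category probability, a point with no stratum
#' counts as "no vegetation", and each point records dense litter or bare
#' soil. All covers are therefore multiples of 1/20, dense_litter +
#' bare_ground = 1, and no_vegetation >= 1 - (sum of the seven vegetation
#' covers).
#'
#' @param devices device table from [make_grids()].
#' @param trees tree table (may be empty).
#' @param archetype_params list as from [default_archetypes()].
#' @param seed integer seed.
#' @return data frame with `device_id`, the ten cover fractions, `category`.
#' @export
gen_microhabitat <- function(devices, trees, archetype_params = default_archetypes(),
                             seed = NULL) {
  ap <- archetype_params
  if (any(ap$profiles < 0 | ap$profiles > 1) || any(ap$litter_p < 0 | ap$litter_p > 1))
    stop("archetype probabilities must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(devices)
  under_tree <- rep(FALSE, n)
  if (nrow(trees) > 0) {
    td <- nearest_tree_distances(devices, trees)
    under_tree <- td$d_tree3 <= ap$canopy_radius_m
  }
  cats <- character(n)
  cats[under_tree] <- "tree"
  free <- !under_tree
  cats[free] <- sample(names(ap$category_weights), sum(free), replace = TRUE,
                       prob = ap$category_weights)
  vars <- colnames(ap$profiles)
  npts <- 20L
  covers <- matrix(0, n, length(vars), dimnames = list(NULL, vars))
  no_veg <- numeric(n)
  for (i in seq_len(n)) {
    pr <- ap$profiles[cats[i], ]
    touches <- matrix(stats::runif(npts * length(vars)) < rep(pr, each = npts),
                      npts, length(vars))
    covers[i, ] <- colSums(touches) / npts
    no_veg[i] <- sum(rowSums(touches) == 0L) / npts
  }
  litter <- stats::rbinom(n, npts, ap$litter_p[cats]) / npts
  out <- data.frame(device_id = devices$device_id, covers,
                    no_vegetation = no_veg,
                    bare_ground = 1 - litter,
                    dense_litter = litter,
                    category = cats,
                    stringsAsFactors = FALSE)
  out[, c("device_id", cover_variables(), "category")]
}

#' Generative specification of a synthetic removal process
#'
#' @param model `"CSR"`, `"DTT"`, `"MICROHAB"` or `"COMBINED"`.
#' @param p_use matrix of marginal use probabilities, rows = grids (named),
#'   columns = seasons W/Sp/Su/A; or a single number recycled. Defaults
#'   follow the field pattern: autumn/winter > spring > summer and
#'   J > F > V.
#' @param beta selection coefficients per score axis (MICROHAB/COMBINED).
#' @param rho probability that a used device is hit again on day 2, given it
#'   was hit on day 1 (day-to-day persistence; default 0.6).
#' @param seed master integer seed; each (grid, season) derives a substream.
#' @return object of class `generative_spec`.
#' @export
generative_spec <- function(model = c("CSR", "DTT", "MICROHAB", "COMBINED"),
                            p_use = NULL, beta = c(-1, 0, 0), rho = 0.6,
                            seed = 1L) {
  model <- match.arg(model)
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]")
  if (any(!is.finite(beta))) stop("beta must be finite")
  if (is.null(p_use)) {
    p_use <- rbind(J = c(W = 0.70, Sp = 0.45, Su = 0.30, A = 0.75),
                   F = c(W = 0.55, Sp = 0.30, Su = 0.20, A = 0.60),
                   V = c(W = 0.40, Sp = 0.18, Su = 0.10, A = 0.45))
  }
  if (any(p_use < 0 | p_use > 1)) stop("use probabilities must be in [0, 1]")
  structure(list(model = model, p_use = p_use, beta = beta, rho = rho,
                 seed = as.integer(seed)),
            class = "generative_spec")
}

spec_p_use <- function(spec, grid, season) {
  p <- spec$p_use
  if (is.matrix(p)) {
    g <- if (grid %in% rownames(p)) grid else 1L
    s <- if (season %in% colnames(p)) season else 1L
    p[g, s]
  } else p[1]
}

#' Simulate per-day seed-removal outcomes
#'
#' For each grid and season the number of used devices is a Binomial draw
#' with the spec's marginal probability; the used set is then selected
#' uniformly (CSR), by weighted sampling without replacement with the
#' distance-to-tree weights (DTT), with probability proportional to
#' logistic(beta . score) (MICROHAB), or the product of the two (COMBINED).
#' A used device is hit on day 1 and again on day 2 with probability `rho`,
#' generating the day-to-day dependence observed in the field.
#'
#' @param devices device table.
#' @param trees tree table (required for DTT/COMBINED).
#' @param scores data frame of per-device scores (required for
#'   MICROHAB/COMBINED; row order must match `devices`).
#' @param spec a `generative_spec`.
#' @param seasons seasons to simulate.
#' @return data frame with `device_id`, `grid_id`, `season`, `day`,
#'   `removed`: one record per device x season x day.
#' @export
simulate_removal <- function(devices, trees = NULL, scores = NULL, spec,
                             seasons = c("W", "Sp", "Su", "A")) {
  if (spec$model %in% c("MICROHAB", "COMBINED") && is.null(scores))
    stop("scores are required for the ", spec$model, " model")
  if (spec$model %in% c("DTT", "COMBINED") && is.null(trees))
    stop("trees are required for the ", spec$model, " model")
  base_w <- rep(1, nrow(devices))
  if (spec$model %in% c("DTT", "COMBINED")) {
    td <- nearest_tree_distances(devices, trees)
    base_w <- dtt_weights(td)
  }
  if (spec$model %in% c("MICROHAB", "COMBINED")) {
    smat <- as.matrix(scores[, setdiff(names(scores), "device_id"), drop = FALSE])
    k <- min(ncol(smat), length(spec$beta))
    eta <- drop(smat[, seq_len(k), drop = FALSE] %*% spec$beta[seq_len(k)])
    base_w <- base_w * stats::plogis(eta)
  }
  out <- vector("list", 0L)
  for (g in unique(devices$grid_id)) {
    gi <- which(devices$grid_id == g)
    for (s in seasons) {
      set.seed(derive_seed(spec$seed, paste0("removal/", g, "/", s)))
      ng <- length(gi)
      n_used <- stats::rbinom(1L, ng, spec_p_use(spec, g, s))
      w <- base_w[gi]
      if (n_used > sum(w > 0))
        stop("grid ", g, ", season ", s, ": ", n_used,
             " devices requested but only ", sum(w > 0), " have positive weight")
      used_idx <- if (spec$model == "CSR") sample.int(ng, n_used)
                  else sample.int(ng, n_used, prob = w)
      used <- logical(ng)
      used[used_idx] <- TRUE
      day2 <- used & stats::runif(ng) < spec$rho
      out[[length(out) + 1L]] <- data.frame(
        device_id = rep(devices$device_id[gi], 2L),
        grid_id = g,
        season = s,
        day = rep(1:2, each = ng),
        removed = c(used, day2),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
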