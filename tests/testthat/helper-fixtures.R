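# Fixtures are built in code; nothing is read from disk.

grid_10x10 <- function() make_grids(1, 10, 10, 5)

# A sparse, clustered tall-tree map over a single 10x10 grid: two corner
# clusters leave a band of devices with zero distance-to-tree weight,
# the situation in which the DTT null differs most from CSR.
two_cluster_trees <- function() {
  data.frame(tree_id = paste0("T", 1:6),
             x = c(5, 15, 10, 35, 40, 30),
             y = c(5, 10, 35, 40, 35, 5),
             height = c(5, 4.5, 6, 5, 4.2, 5.5),
             is_algarrobo = TRUE,
             stringsAsFactors = FALSE)
}

# Full synthetic field setting: three grids, per-grid tree maps, covers,
# fitted PCA and unit-variance rotated scores.
synth_microhab <- function(seed = 1) {
  dev <- make_grids()
  intens <- c(J = 150, F = 110, V = 60)
  trees <- do.call(rbind, lapply(unique(dev$grid_id), function(g) {
    d <- dev[dev$grid_id == g, ]
    tr <- place_trees(c(min(d$x) - 10, max(d$x) + 10,
                        min(d$y) - 10, max(d$y) + 10),
                      intens[[g]], seed = seed + match(g, names(intens)))
    if (nrow(tr)) tr$tree_id <- paste0(g, tr$tree_id)
    tr
  }))
  covers <- gen_microhabitat(dev, trees, seed = seed)
  z <- transform_covers(covers)
  model <- pca_varimax(z)
  scores <- weighted_scores(model, z, dev$device_id, weighted = FALSE)
  list(devices = dev, trees = trees, covers = covers, z = z,
       model = model, scores = scores)
}

# Per-season usage aligned to the device-table row order.
usage_vector <- function(removal, devices, season = "W") {
  ut <- make_usage(removal)
  ut <- ut[ut$season == season, ]
  ut$used[match(devices$device_id, ut$device_id)]
}

# Independent binomial-GLM oracle: maximise the log-likelihood directly over
# the coefficient vector of a given model matrix (never calls glm).
brute_force_deviance <- function(X, y, n) {
  sat <- sum(stats::dbinom(y, n, ifelse(n > 0, y / n, 0), log = TRUE))
  nll <- function(b) {
    p <- stats::plogis(drop(X %*% b))
    -sum(stats::dbinom(y, n, p, log = TRUE))
  }
  gr <- function(b) {
    p <- stats::plogis(drop(X %*% b))
    -drop(t(X) %*% (y - n * p))
  }
  opt <- stats::optim(rep(0, ncol(X)), nll, gr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  2 * (sat + opt$value)
}
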