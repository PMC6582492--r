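# unconstrained random cover table: enough variation in all ten variables for
# exercising the transformation/ordination machinery (domain invariants are
# covered by the generator tests)
random_covers <- function(n, seed = 1) {
  set.seed(seed)
  vars <- cover_variables()
  m <- matrix(rbinom(n * 8, 20, runif(8, 0.1, 0.6)[rep(1:8, each = n)]) / 20, n, 8)
  litter <- rbinom(n, 20, 0.5) / 20
  out <- data.frame(device_id = paste0("d", seq_len(n)), m,
                    bare = 1 - litter, litter = litter)
  names(out) <- c("device_id", vars)
  out
}

test_that("cover transformation matches the arcsine-square-root oracle", {
  cov <- random_covers(60)
  z <- transform_covers(cov)
  for (v in cover_variables()) {
    oracle <- as.numeric(scale(asin(sqrt(cov[[v]]))))
    expect_equal(unname(z[, v]), oracle, tolerance = 1e-12)
  }
  expect_equal(colMeans(z), setNames(rep(0, 10), cover_variables()),
               tolerance = 1e-10)
  expect_equal(apply(z, 2, var), setNames(rep(1, 10), cover_variables()),
               tolerance = 1e-10)
  # arcsin(sqrt(.)) endpoints: 0 -> 0 and 1 -> pi/2 before standardisation
  expect_equal(asin(sqrt(c(0, 1))), c(0, pi / 2))
})

test_that("alternative transformations and degenerate input are handled", {
  cov <- random_covers(40, seed = 2)
  z <- transform_covers(cov, transform_map = c(grasses = "log", low_shrubs = "sqrt"))
  expect_equal(unname(z[, "grasses"]),
               as.numeric(scale(log(cov$grasses + 0.025))), tolerance = 1e-12)
  expect_equal(unname(z[, "low_shrubs"]),
               as.numeric(scale(sqrt(cov$low_shrubs))), tolerance = 1e-12)
  cov$grasses <- 0.5
  expect_error(transform_covers(cov), "zero-variance")
  expect_error(transform_covers(random_covers(10), default = "cubic"), "unknown")
})

test_that("broken-stick proportions follow the closed form", {
  b <- broken_stick(10)
  expect_equal(b[1], sum(1 / (1:10)) / 10, tolerance = 1e-12)
  expect_equal(b[1], 0.29290, tolerance = 1e-4)
  expect_equal(sum(b), 1, tolerance = 1e-12)
  expect_equal(broken_stick(1), 1)
  expect_error(broken_stick(0), ">= 1")
})

test_that("PCA eigenstructure is exact on canonical cases", {
  set.seed(3)
  x <- rnorm(200)
  two <- cbind(a = x, b = 2 * x + 1)  # perfectly correlated pair
  m <- pca_varimax(scale(two), rotation = "none")
  expect_equal(m$eigenvalues, c(2, 0), tolerance = 1e-10)
  expect_equal(sum(pca_varimax(transform_covers(random_covers(200)))$eigenvalues),
               10, tolerance = 1e-8)
  # independent noise: broken-stick retains nothing
  noise <- matrix(rnorm(1200), ncol = 6)
  expect_error(pca_varimax(noise, retention = "broken_stick"), "retains no")
  expect_error(pca_varimax(cbind(noise, NA)), "non-finite")
})

test_that("Kaiser retention keeps eigenvalues above one", {
  s <- synth_microhab(seed = 4)
  ev <- s$model$eigenvalues
  expect_equal(s$model$retained, sum(ev > 1))
  expect_gte(s$model$retained, 3)
  expect_equal(s$model$pct_variance, 100 * ev / 10)
  expect_true(all(diff(s$model$cum_pct_variance) >= -1e-12))
  expect_true(all(diff(ev) <= 1e-12))  # descending before rotation
})

test_that("varimax preserves communalities and marker-variable orientation", {
  s <- synth_microhab(seed = 5)
  unrot <- pca_varimax(s$z, rotation = "none")
  k <- s$model$retained
  expect_equal(rowSums(s$model$loadings^2),
               rowSums(unrot$loadings[, seq_len(k)]^2), tolerance = 1e-8)
  expect_gt(s$model$loadings["dense_litter", 1], 0)
  expect_gt(s$model$loadings["trees_gt1m", 2], 0)
  if (k >= 3) expect_gt(s$model$loadings["dry_standing_grasses", 3], 0)
})

test_that("scores are centred, unit variance, and eigenvalue weighting scales them", {
  s <- synth_microhab(seed = 6)
  k <- s$model$retained
  sc <- weighted_scores(s$model, s$z, weighted = FALSE)
  expect_equal(unname(colMeans(sc)), rep(0, k), tolerance = 1e-8)
  expect_equal(unname(apply(sc, 2, var)), rep(1, k), tolerance = 1e-8)
  scw <- weighted_scores(s$model, s$z, weighted = TRUE)
  for (j in seq_len(k))
    expect_equal(scw[[j]], sc[[j]] * s$model$eigenvalues[j], tolerance = 1e-10)
  # a zero score stays zero and a unit eigenvalue would leave it unchanged
  expect_true(all(abs(scw[sc == 0]) < 1e-12))
  expect_error(weighted_scores(s$model, s$z[, 1:5]), "dimension mismatch")
})

test_that("per-grid PCA scores correlate with the pooled analysis", {
  s <- synth_microhab(seed = 7)
  pooled <- s$scores
  cors <- unlist(lapply(unique(s$devices$grid_id), function(g) {
    gi <- s$devices$grid_id == g
    zg <- transform_covers(s$covers[gi, ])
    mg <- pca_varimax(zg)
    sg <- weighted_scores(mg, zg, weighted = FALSE)
    k <- min(3, mg$retained)
    vapply(seq_len(k), function(j) abs(cor(sg[[j]], pooled[gi, j + 1])), 0)
  }))
  # most axes reproduce the pooled ordination within each grid
  expect_gte(mean(cors > 0.8), 2 / 3)
  expect_true(all(cors > 0.5))
})
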