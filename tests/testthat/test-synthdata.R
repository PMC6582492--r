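test_that("grids are exact lattices with unique devices", {
  dev <- make_grids(3, 10, 10, 5)
  expect_equal(nrow(dev), 300)
  expect_false(anyDuplicated(dev$device_id) > 0)
  expect_equal(sort(unique(dev$grid_id)), sort(c("J", "F", "V")))
  small <- make_grids(1, 2, 2, 5)
  expect_equal(small[, c("x", "y")],
               data.frame(x = c(0, 5, 0, 5), y = c(0, 0, 5, 5)))
  one <- make_grids(1, 10, 10, 5)
  expect_equal(max(pairwise_distances(cbind(one$x, one$y))), sqrt(2 * 45^2),
               tolerance = 1e-10)  # 63.64 m
  # lattice identity: coordinates are spacing * index plus the grid origin
  expect_equal(dev$x - ave(dev$x, dev$grid_id, FUN = min), 5 * dev$col)
  expect_equal(dev$y - ave(dev$y, dev$grid_id, FUN = min), 5 * dev$row)
  expect_error(make_grids(1, 1, 10), ">= 2")
  expect_error(make_grids(1, 10, 10, 0), "positive")
})

test_that("tree placement is Poisson with reproducible seeds", {
  expect_warning(none <- place_trees(c(0, 100, 0, 20), 0, seed = 1), "empty")
  expect_equal(nrow(none), 0)
  a <- place_trees(c(0, 50, 0, 40), 80, seed = 2)
  b <- place_trees(c(0, 50, 0, 40), 80, seed = 2)
  expect_identical(a, b)
  expect_true(all(a$height > 3))
  expect_error(place_trees(c(0, 10, 0, 10), -1), ">= 0")
  # Poisson mean: intensity 50/ha on 0.2 ha -> mean 10
  set.seed(3)
  counts <- vapply(1:2000, function(i)
    nrow(place_trees(c(0, 50, 0, 40), 50, seed = 10000 + i)), 0)
  expect_lt(abs(mean(counts) - 10), 3 * sqrt(10 / 2000))
})

test_that("generated covers respect the intercept-sampling invariants", {
  dev <- grid_10x10()
  cov <- gen_microhabitat(dev, two_cluster_trees(), seed = 4)
  m <- as.matrix(cov[, cover_variables()])
  expect_true(all(abs(m * 20 - round(m * 20)) < 1e-9))      # multiples of 1/20
  expect_true(all(abs(cov$dense_litter + cov$bare_ground - 1) <= 1 / 40 + 1e-9))
  veg7 <- rowSums(m[, 1:7])
  expect_true(all(cov$no_vegetation >= 1 - veg7 - 1e-9))
  # devices under a mapped canopy are forced to the tree category
  td <- nearest_tree_distances(dev, two_cluster_trees())
  expect_true(all(cov$category[td$d_tree3 <= 2] == "tree"))
  expect_identical(cov, gen_microhabitat(dev, two_cluster_trees(), seed = 4))
})

test_that("a degenerate bare archetype yields bare ground only", {
  ap <- default_archetypes()
  ap$profiles[] <- 0
  ap$litter_p[] <- 0
  ap$category_weights <- c(bare = 1)
  dev <- make_grids(1, 3, 3, 5)
  cov <- gen_microhabitat(dev, two_cluster_trees()[0, ], ap, seed = 5)
  expect_true(all(cov$bare_ground == 1))
  expect_true(all(as.matrix(cov[, cover_variables()[1:7]]) == 0))
  expect_true(all(cov$no_vegetation == 1))
  ap$profiles[1] <- 1.5
  expect_error(gen_microhabitat(dev, two_cluster_trees()[0, ], ap), "\\[0, 1\\]")
})

test_that("default covers carry at least three axes of structure", {
  s <- synth_microhab(seed = 6)
  expect_gte(sum(s$model$eigenvalues > 1), 3)
})

test_that("CSR removal hits the binomial marginal and stays uniform over devices", {
  dev <- grid_10x10()
  used_tot <- numeric(100)
  n_used <- numeric(400)
  for (r in 1:400) {
    spec <- generative_spec("CSR", p_use = 0.5, seed = 20000 + r)
    rem <- simulate_removal(dev, spec = spec, seasons = "W")
    u <- usage_vector(rem, dev)
    used_tot <- used_tot + u
    n_used[r] <- sum(u)
  }
  expect_lt(abs(mean(n_used) - 50), 3 * sqrt(100 * 0.25) / sqrt(400))
  gof <- chisq.test(used_tot, p = rep(1 / 100, 100))
  expect_gt(gof$p.value, 0.01)
})

test_that("DTT removal never touches zero-weight devices", {
  dev <- data.frame(device_id = sprintf("d%02d", 1:10), grid_id = "G",
                    x = seq(0, 18, by = 2), y = 0)
  tr <- data.frame(tree_id = "T1", x = 0, y = 0, height = 5, is_algarrobo = TRUE)
  w <- dtt_weights(nearest_tree_distances(dev, tr))
  expect_equal(sum(w == 0), 4)   # devices beyond 10 m of the only tall tree
  for (r in 1:100) {
    spec <- generative_spec("DTT", p_use = 0.2, seed = 30000 + r)
    rem <- simulate_removal(dev, tr, spec = spec, seasons = "W")
    u <- usage_vector(rem, dev)
    expect_true(all(!u[w == 0]))
  }
  spec <- generative_spec("DTT", p_use = 1, seed = 31)
  expect_error(simulate_removal(dev, tr, spec = spec, seasons = "W"),
               "positive weight")
})

test_that("DTT inclusion frequencies follow the weight ordering", {
  dev <- grid_10x10()
  # two algarrobo clusters plus one isolated plain tall tree: all four weight
  # bands (0.6 / 0.3 / 0.1 / 0) are populated
  tr <- two_cluster_trees()
  tr <- rbind(tr, data.frame(tree_id = "T7", x = 45, y = 0, height = 3.5,
                             is_algarrobo = FALSE))
  w <- dtt_weights(nearest_tree_distances(dev, tr))
  expect_setequal(unique(w), c(0, 0.1, 0.3, 0.6))
  freq <- numeric(100)
  for (r in 1:300) {
    spec <- generative_spec("DTT", p_use = 0.3, seed = 40000 + r)
    rem <- simulate_removal(dev, tr, spec = spec, seasons = "W")
    freq <- freq + usage_vector(rem, dev)
  }
  freq <- freq / 300
  expect_equal(mean(freq[w == 0]), 0)
  expect_gt(mean(freq[w == 0.6]), mean(freq[w == 0.3]))
  expect_gt(mean(freq[w == 0.3]), mean(freq[w == 0.1]))
  expect_gt(mean(freq[w == 0.1]), mean(freq[w == 0]))
})

test_that("removal simulation is reproducible and day-2 persistence matches rho", {
  s <- synth_microhab(seed = 7)
  spec <- generative_spec("MICROHAB", beta = c(-1, 0, 0), rho = 0.6, seed = 8)
  r1 <- simulate_removal(s$devices, s$trees, s$scores, spec)
  r2 <- simulate_removal(s$devices, s$trees, s$scores, spec)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 300 * 4 * 2)
  d1 <- r1[r1$day == 1, ]; d2 <- r1[r1$day == 2, ]
  expect_true(all(!d2$removed[!d1$removed]))  # only used devices repeat
  n_used <- sum(d1$removed)
  p2 <- sum(d2$removed) / n_used
  expect_lt(abs(p2 - 0.6), 3 * sqrt(0.6 * 0.4 / n_used))
  expect_error(simulate_removal(s$devices, s$trees, NULL, spec), "scores")
})

test_that("negative beta on PC1 selects low-PC1 microhabitats", {
  s <- synth_microhab(seed = 9)
  spec <- generative_spec("MICROHAB", p_use = 0.5, beta = c(-1, 0, 0), seed = 10)
  rem <- simulate_removal(s$devices, scores = s$scores, spec = spec, seasons = "W")
  u <- usage_vector(rem, s$devices)
  expect_lt(mean(s$scores$PC1[u]), mean(s$scores$PC1))
})

test_that("generative spec validates its parameters", {
  expect_error(generative_spec("CSR", rho = 1.2), "rho")
  expect_error(generative_spec("CSR", p_use = 2), "\\[0, 1\\]")
  expect_error(generative_spec("MICROHAB", beta = c(NA, 0, 0)), "finite")
  sp <- generative_spec("DTT", seed = 3)
  expect_s3_class(sp, "generative_spec")
  expect_equal(sp$rho, 0.6)
})
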