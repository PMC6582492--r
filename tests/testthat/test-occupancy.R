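removal_rows <- function(d1, d2, season = "W") {
  n <- length(d1)
  data.frame(device_id = rep(sprintf("d%03d", 1:n), 2),
             season = season, day = rep(1:2, each = n),
             removed = c(d1, d2), stringsAsFactors = FALSE)
}

test_that("usage is the OR of the two offer days", {
  rem <- removal_rows(c(TRUE, FALSE, TRUE, FALSE), c(FALSE, FALSE, TRUE, TRUE))
  u <- make_usage(rem)
  expect_equal(u$used[match(sprintf("d%03d", 1:4), u$device_id)],
               c(TRUE, FALSE, TRUE, TRUE))
  expect_error(make_usage(rem[rem$day == 1, ]), "missing day")
})

test_that("day-dependence test flags association between consecutive days", {
  perfect <- day_dependence_test(removal_rows(rep(c(TRUE, FALSE), c(50, 50)),
                                              rep(c(TRUE, FALSE), c(50, 50))))
  expect_lt(perfect$P, 1e-20)
  expect_gt(perfect$excess_double, 0)
  expect_gt(perfect$excess_never, 0)

  balanced <- day_dependence_test(removal_rows(
    rep(c(TRUE, TRUE, FALSE, FALSE), each = 25),
    rep(c(TRUE, FALSE, TRUE, FALSE), each = 25)))
  expect_equal(balanced$P, 1)

  or9 <- day_dependence_test(removal_rows(
    rep(c(TRUE, FALSE), c(40, 40)),
    rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 10, 10, 30))))
  expect_equal(unname(or9$odds_ratio), 9)

  expect_warning(
    degenerate <- day_dependence_test(removal_rows(rep(TRUE, 10), rep(TRUE, 10))),
    "degenerate")
  expect_equal(degenerate$P, 1)
})

cells_fixture <- function(used) {
  data.frame(season = rep(c("W", "Sp", "Su", "A"), 3),
             grid_id = rep(c("J", "F", "V"), each = 4),
             used = used, total = 100)
}

test_that("binomial GLM reproduces closed-form fits", {
  cells <- cells_fixture(c(70, 45, 30, 75, 55, 30, 20, 60, 45, 20, 12, 50))
  null <- fit_binomial_glm(cells, "1")
  expect_equal(unname(plogis(null$coefficients)), sum(cells$used) / sum(cells$total),
               tolerance = 1e-8)
  full <- fit_binomial_glm(cells, "season * grid")
  expect_equal(full$deviance, 0, tolerance = 1e-8)
  expect_equal(full$df_residual, 0)
  expect_error(fit_binomial_glm(transform(cells, total = 0)), "positive")
})

test_that("GLM deviance matches direct likelihood maximisation", {
  # two cells, intercept only
  y <- c(30, 60); n <- c(100, 100)
  oracle <- brute_force_deviance(matrix(1, 2, 1), y, n)
  f <- fit_binomial_glm(data.frame(season = "W", grid_id = c("a", "b"),
                                   used = y, total = n), "1")
  expect_equal(f$deviance, oracle, tolerance = 1e-6)

  # 12-cell main-effects design
  cells <- cells_fixture(c(70, 45, 30, 75, 55, 30, 20, 60, 45, 20, 12, 50))
  f2 <- fit_binomial_glm(cells, "season + grid")
  X <- model.matrix(~ season + grid_id, transform(cells,
        season = factor(season, c("W", "Sp", "Su", "A"))))
  oracle2 <- brute_force_deviance(X, cells$used, cells$total)
  expect_equal(f2$deviance, oracle2, tolerance = 1e-6)
})

test_that("deviance table is additive along the elimination path", {
  cells <- cells_fixture(c(70, 45, 30, 75, 55, 30, 20, 60, 45, 20, 12, 50))
  an <- removal_deviance_analysis(cells)
  tab <- an$table
  expect_equal(tab$model, c("full", "main", "season", "grid", "null"))
  expect_true(all(diff(tab$deviance[c(1, 2, 5)]) >= -1e-8))  # nested: non-increasing richness
  # delta(full -> null) decomposes through any intermediate model
  d_full_null <- tab$deviance[5] - tab$deviance[1]
  expect_equal(d_full_null,
               tab$delta_deviance[2] + tab$delta_deviance[5], tolerance = 1e-10)
  # model compared with itself
  self <- deviance_table(list(a = an$fits$main, b = an$fits$main), vs = 1L)
  expect_equal(self$delta_deviance[2], 0)
  expect_equal(self$P[2], 1)
  expect_error(deviance_table(list(an$fits$null, an$fits$full)), "not nested")
})

test_that("a true grid effect is detected by the deviance test", {
  set.seed(71)
  logits <- rep(c(-0.5, 0, 0.5), each = 4)
  hits <- 0
  for (r in 1:200) {
    used <- rbinom(12, 100, plogis(logits))
    cells <- cells_fixture(used)
    main <- fit_binomial_glm(cells, "season + grid")
    season <- fit_binomial_glm(cells, "season")
    p <- pchisq(season$deviance - main$deviance, 2, lower.tail = FALSE)
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits / 200, 0.9)
})

test_that("overdispersion ratio is deviance per residual df", {
  fake <- structure(list(deviance = 10.423, df_residual = 6), class = "usage_glm")
  expect_equal(overdispersion_ratio(fake), 10.423 / 6)  # prints as 1.74
  expect_equal(round(overdispersion_ratio(fake), 2), 1.74)
  fake$deviance <- 0
  expect_equal(overdispersion_ratio(fake), 0)
  fake$df_residual <- 0
  expect_error(overdispersion_ratio(fake), "zero")
})

test_that("Poisson-binomial pmf matches enumeration", {
  expect_equal(poisson_binomial_pmf(rep(0.5, 4)),
               c(0.0625, 0.25, 0.375, 0.25, 0.0625), tolerance = 1e-12)
  expect_equal(poisson_binomial_pmf(c(0.2, 0.4)), c(0.48, 0.44, 0.08),
               tolerance = 1e-12)
  set.seed(72)
  for (r in 1:5) {
    p <- runif(sample(1:6, 1))
    expect_equal(sum(poisson_binomial_pmf(p)), 1, tolerance = 1e-12)
  }
  expect_error(poisson_binomial_pmf(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("season-independence test compares against product-Bernoulli expectations", {
  set.seed(73)
  counts <- rbinom(100, 4, 0.5)
  r <- suppressWarnings(season_independence_test(counts, rep(0.5, 4)))
  expect_equal(r$expected, 100 * c(0.0625, 0.25, 0.375, 0.25, 0.0625))
  expect_equal(r$df, 4)
  expect_equal(r$df_est, 3)
  expect_equal(sum(r$observed), 100)
  # all seasons certain: any count < 4 is impossible under the null
  r2 <- suppressWarnings(season_independence_test(c(rep(4, 99), 3), rep(1, 4)))
  expect_true(r2$infinite)
  expect_true(is.infinite(r2$chisq))
  r3 <- suppressWarnings(season_independence_test(rep(4, 100), rep(1, 4)))
  expect_false(r3$infinite)
  expect_equal(r3$chisq, 0)
})

test_that("positive day persistence inflates the always/never categories", {
  # devices with persistent identity across seasons: simulate via a shared
  # device effect, the mechanism behind the field's excess 0/4 and 4/4 counts
  set.seed(74)
  quality <- rnorm(100, 0, 1.5)
  counts <- rowSums(sapply(1:4, function(s) runif(100) < plogis(quality)))
  p_s <- rep(mean(counts) / 4, 4)
  r <- suppressWarnings(season_independence_test(counts, p_s))
  expd <- r$expected
  obs <- r$observed
  expect_gt(obs[1] + obs[5], expd[1] + expd[5])  # excess at 0/4 and 4/4
  expect_lt(r$P, 0.01)
})
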