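test_that("split plans partition the samples at the documented sizes", {
  plan <- makeSplitPlan(45, master_seed = 3)
  expect_length(plan$splits, 5L)
  for (s in plan$splits) {
    expect_length(s$train, 31L)  # floor(0.7 * 45)
    expect_length(s$test, 14L)
    expect_length(intersect(s$train, s$test), 0L)
    expect_setequal(union(s$train, s$test), 1:45)
  }
  expect_identical(makeSplitPlan(45, master_seed = 3), plan)
  expect_false(identical(makeSplitPlan(45, master_seed = 4), plan))
  expect_error(makeSplitPlan(45, train_fraction = 1.2, master_seed = 1),
               "train_fraction")
  expect_error(makeSplitPlan(5, master_seed = 1), "n")
})

test_that("metrics follow their definitions", {
  expect_equal(unclass(computeMetrics(c(1, 2, 3), c(1, 2, 3)))[1:3],
               list(r_squared = 1, rmse = 0, mae = 0))
  m <- computeMetrics(c(1, 2, 3), c(2, 3, 4))
  expect_equal(m$r_squared, 1)
  expect_equal(m$rmse, sqrt(3 / 2))   # n - 1 denominator
  expect_equal(m$mae, 1)
  expect_error(computeMetrics(c(2, 2, 2), c(1, 2, 3)), "zero variance")
  expect_warning(computeMetrics(c(1, 2, 3), c(2, 2, 2)), "constant")
})

makeGrid <- function(models, iters, fn) {
  do.call(rbind, lapply(models, function(m)
    do.call(rbind, lapply(iters, function(j)
      data.frame(model = m, iteration = j,
                 indicator = c("r_squared", "rmse", "mae"),
                 value = fn(m, j))))))
}

test_that("identical models tie at zero GPI with registration-order ranks", {
  g <- makeGrid(c("A", "B", "C"), 1:5, function(m, j) c(0.9, 1.0, 0.8))
  w <- testthat::capture_warnings(res <- computeGPI(g))
  expect_true(all(grepl("constant", w)) && length(w) == 3L)
  expect_equal(unname(res$gpi), c(0, 0, 0))
  expect_identical(unname(res$ranks), 1:3)
})

test_that("a uniformly dominating model earns the top GPI and rank", {
  better <- function(m, j) if (m == "good") c(0.95, 0.5, 0.4) + j / 100 else
    c(0.70, 1.5, 1.2) + j / 100
  res <- computeGPI(makeGrid(c("bad", "good"), 1:5, better))
  expect_gt(res$gpi[["good"]], res$gpi[["bad"]])
  expect_identical(res$ranks[["good"]], 1L)
  # two-model antisymmetry: swapping the grids negates the GPI difference
  swapped <- computeGPI(makeGrid(c("bad", "good"), 1:5, function(m, j)
    better(if (m == "bad") "good" else "bad", j)))
  d1 <- res$gpi[["good"]] - res$gpi[["bad"]]
  d2 <- swapped$gpi[["good"]] - swapped$gpi[["bad"]]
  expect_equal(d1, -d2)
})

test_that("normalized indicators stay in the unit interval and ranks permute", {
  withr::with_seed(6, {
    g <- makeGrid(c("A", "B", "C"), 1:5, function(m, j) runif(3))
  })
  res <- computeGPI(g)
  expect_true(all(res$normalized$norm_value >= 0 &
                    res$normalized$norm_value <= 1))
  expect_setequal(unname(res$ranks), 1:3)
  expect_error(computeGPI(g[-1, ]), "complete")
})

test_that("descending GPI ranking reproduces the reference rank table", {
  ref <- referenceGPI()
  for (cv in unique(ref$cultivar)) {
    for (tr in unique(ref$trait)) {
      sub <- ref[ref$cultivar == cv & ref$trait == tr, ]
      r <- rankByGPI(setNames(sub$gpi, sub$model))
      expect_identical(unname(r), sub$rank)
    }
  }
})

test_that("residual pooling reports honest summary statistics", {
  perfect <- poolResiduals(list(c(1, 2), c(3, 4)), list(c(1, 2), c(3, 4)))
  expect_identical(perfect$residuals, rep(0, 4))
  expect_identical(perfect$iqr, 0)

  obs <- list(c(5, 6, 7), c(8, 9, 10))
  fit <- list(c(5.5, 5.5, 7.2), c(7.4, 9.1, 9.8))
  d <- poolResiduals(obs, fit)
  expect_identical(d$n, 6L)
  r <- unlist(obs) - unlist(fit)
  expect_equal(d$mean, mean(r))
  # the +/- 2 SD band is symmetric about the residual mean, not about zero
  expect_equal(unname(d$band["upper"] + d$band["lower"]), 2 * d$mean)
})

scenarioFixture <- function(noise_channel = 2.5, seed = 1L, n_times = 12L,
                            noise_trait = c(oil = 0.8, phenols = 2.0)) {
  p <- trajectoryParams("one", noise_sd_channel = noise_channel,
                        noise_sd_trait = noise_trait, seed = seed)
  samples <- generateTrajectory(p, n_times = n_times, reps_per_time = 3)
  buildFeatureTable(samples)
}

fastControls <- function() list(
  ga = gaConfig(population_size = 8L, n_generations = 8L, seed = 1),
  net = list(max_epochs = 1500L)
)

test_that("a scenario report is complete, deterministic and leakage-free", {
  ise <- scenarioFixture()
  plan <- makeSplitPlan(ncol(ise), master_seed = 11)
  ctl <- fastControls()
  rep1 <- runScenario(ise, "oil", plan, ga = ctl$ga, net_control = ctl$net)
  rep2 <- runScenario(ise, "oil", plan, ga = ctl$ga, net_control = ctl$net)
  # 3 models x 5 iterations x 3 indicators
  expect_identical(nrow(rep1$metrics), 45L)
  expect_identical(rep1$metrics, rep2$metrics)
  expect_identical(rep1$gpi, rep2$gpi)
  expect_setequal(unname(rep1$ranks), 1:3)
  # every fitting stage saw exactly the training rows of its split
  for (j in seq_along(plan$splits)) {
    log <- rep1$fit_log[[j]]
    tr <- plan$splits[[j]]$train; te <- plan$splits[[j]]$test
    for (stage in c("standardizer_rows", "pca_rows", "ga_rows",
                    "target_scaling_rows")) {
      expect_identical(log[[stage]], tr)
      expect_length(intersect(log[[stage]], te), 0L)
    }
  }
  # residual counts equal the summed test sizes
  n_te <- sum(lengths(lapply(plan$splits, `[[`, "test")))
  expect_identical(rep1$residuals$BPNN$n, n_te)
})

test_that("perturbing test rows never changes training-fitted statistics", {
  p <- trajectoryParams("one", seed = 2L)
  samples <- generateTrajectory(p, n_times = 12, reps_per_time = 3)
  plan <- makeSplitPlan(nrow(samples), n_repeats = 2L, master_seed = 5)
  te1 <- plan$splits[[1]]$test
  tampered <- samples
  tampered[te1, c("r_mean", "g_mean", "b_mean")] <-
    pmin(tampered[te1, c("r_mean", "g_mean", "b_mean")] + 40, 255)
  ctl <- fastControls()
  r1 <- runScenario(buildFeatureTable(samples), "oil", plan,
                    ga = ctl$ga, net_control = ctl$net)
  r2 <- runScenario(buildFeatureTable(tampered), "oil", plan,
                    ga = ctl$ga, net_control = ctl$net)
  # GA / SPCA selection depends only on the training block
  expect_identical(r1$fit_log[[1]]$nnzl, r2$fit_log[[1]]$nnzl)
  expect_identical(r1$fit_log[[1]]$retained_variables,
                   r2$fit_log[[1]]$retained_variables)
})

test_that("noiseless data make the oil trait essentially perfectly predictable", {
  ise <- scenarioFixture(noise_channel = 0, n_times = 15L,
                         noise_trait = c(oil = 0, phenols = 0))
  plan <- makeSplitPlan(ncol(ise), master_seed = 2)
  ctl <- fastControls()
  rep <- runScenario(ise, "oil", plan, ga = ctl$ga,
                     net_control = list(max_epochs = 4000L))
  expect_gte(min(rep$mean_r_squared), 0.99)
})

test_that("prediction accuracy degrades monotonically with channel noise", {
  mean_best <- vapply(c(0, 5, 15), function(noise) {
    vals <- vapply(1:3, function(seed) {
      ise <- scenarioFixture(noise_channel = noise, seed = seed)
      plan <- makeSplitPlan(ncol(ise), n_repeats = 3L, master_seed = seed)
      ctl <- fastControls()
      rep <- runScenario(ise, "oil", plan, ga = ctl$ga, net_control = ctl$net)
      max(rep$mean_r_squared)
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(mean_best) < 0))
})
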