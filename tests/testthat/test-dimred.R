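test_that("the standardizer centers, scales, drops constants and never refits", {
  withr::with_seed(2, X <- matrix(rnorm(60), 12, 5))
  colnames(X) <- paste0("V", 1:5)
  X[, 4] <- 3  # constant column
  expect_warning(std <- fitStandardizer(X), "constant")
  Xs <- applyStandardizer(std, X)
  expect_identical(colnames(Xs), paste0("V", c(1:3, 5)))
  expect_lt(max(abs(colMeans(Xs))), 1e-10)
  expect_lt(max(abs(apply(Xs, 2, sd) - 1)), 1e-10)
  # new data is transformed with the stored statistics, not its own
  Xnew <- X[1:3, ] + 100
  Xns <- applyStandardizer(std, Xnew)
  expect_equal(Xns, Xs[1:3, ] + sweep(matrix(100, 3, 4), 2, std$sd, "/"),
               ignore_attr = TRUE)
})

test_that("PCA retains the smallest k reaching the variance cutoff", {
  # rank-1 data: one component explains everything
  withr::with_seed(3, {
    u <- rnorm(10); v <- c(1, 2, 3)
  })
  X1 <- u %o% v; colnames(X1) <- paste0("V", 1:3)
  r1 <- fitPCA(X1, 0.85)
  expect_identical(kRetained(r1), 1L)
  expect_equal(explainedVariance(r1), 1)

  # spectrum constructed to have fractions exactly (.60, .26, .10, .04)
  withr::with_seed(4, {
    U <- qr.Q(qr(matrix(rnorm(20 * 4), 20, 4)))
    V <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  })
  U <- sweep(U, 2, colMeans(U))  # center so svd sees the intended spectrum
  U <- qr.Q(qr(U))
  d <- sqrt(19 * c(0.60, 0.26, 0.10, 0.04) * 10)
  X2 <- U %*% diag(d) %*% t(V); colnames(X2) <- paste0("V", 1:4)
  r2 <- fitPCA(X2, 0.85)
  expect_identical(kRetained(r2), 2L)  # 0.60 + 0.26 = 0.86 >= 0.85
  expect_equal(sum(explainedVariance(r2)), 0.86, tolerance = 1e-8)

  expect_error(fitPCA(matrix(c(1, NA, 2, 3), 2, 2)), "non-finite")
})

test_that("PCA matches an independent eigendecomposition oracle", {
  for (trial in 1:20) {
    X <- randomStandardized(20, 8, seed = 100 + trial)
    res <- fitPCA(X, variance_cutoff = 1)
    C <- crossprod(sweep(X, 2, colMeans(X))) / (nrow(X) - 1)
    eig <- eigen(C, symmetric = TRUE)
    ev <- explainedVariance(res) * sum(eig$values)
    expect_lt(max(abs(ev - eig$values[1:kRetained(res)])), 1e-8)
    for (j in seq_len(kRetained(res))) {
      a <- loadings(res)[, j]; b <- eig$vectors[, j]
      expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-8)
    }
    # loadings orthonormal; full decomposition explains everything
    G <- crossprod(loadings(res))
    expect_lt(max(abs(G - diag(ncol(G)))), 1e-10)
    expect_equal(sum(explainedVariance(res)), 1, tolerance = 1e-8)
  }
})

test_that("sparse PCA reduces to PCA at full cardinality and vanishing ridge", {
  X <- randomStandardized(25, 6, seed = 31)
  k <- 3L
  sp <- fitSPCA(X, nnzl = rep(6L, k), ridge_penalty = 1e-12)
  pc <- fitPCA(X, variance_cutoff = 1)
  for (j in 1:k) {
    a <- loadings(sp)[, j]; b <- loadings(pc)[, j]
    expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-6)
  }
})

test_that("sparse PCA respects cardinality constraints for arbitrary targets", {
  X <- randomStandardized(30, 7, seed = 55)
  withr::with_seed(8, {
    for (trial in 1:10) {
      nz <- sample.int(7, sample(1:3, 1), replace = TRUE)
      sp <- fitSPCA(X, nnzl = nz)
      expect_true(all(colSums(abs(loadings(sp)) > 0) <= nz))
      nrm <- sqrt(colSums(loadings(sp)^2))
      expect_lt(max(abs(nrm - 1)), 1e-8)
    }
  })
  expect_error(fitSPCA(X, nnzl = c(0L)), "nnzl")
  expect_error(fitSPCA(X, nnzl = c(9L)), "nnzl")
})

test_that("a dominant variable is recovered by the single-loading component", {
  withr::with_seed(12, {
    Y <- matrix(rnorm(60 * 5), 60, 5)
    Y[, 3] <- Y[, 3] * 10
  })
  colnames(Y) <- paste0("V", 1:5)
  Yc <- sweep(Y, 2, colMeans(Y))
  sp <- fitSPCA(Yc, nnzl = 1L)
  # brute-force oracle: the single-variable loading maximizing variance
  vars <- apply(Yc, 2, function(col) var(col))
  expect_identical(selectVariables(sp), names(which.max(vars)))
  expect_equal(abs(loadings(sp)[3, 1]), 1)
})

test_that("sparse explained variance never exceeds the PCA optimum", {
  X <- randomStandardized(25, 6, seed = 77)
  pc <- fitPCA(X, variance_cutoff = 1)
  withr::with_seed(9, {
    for (trial in 1:5) {
      nz <- sample.int(6, 2, replace = TRUE)
      sp <- fitSPCA(X, nnzl = nz)
      expect_lte(sum(explainedVariance(sp)),
                 sum(explainedVariance(pc)[1:2]) + 1e-8)
    }
  })
})

test_that("variable selection applies the nonzero-union rule", {
  L <- matrix(0, 4, 2, dimnames = list(c("a", "b", "c", "d"), NULL))
  expect_identical(selectVariables(L), character(0))
  L[] <- 1
  expect_identical(selectVariables(L), c("a", "b", "c", "d"))
  L[] <- 0; L[1, 1] <- 0.5; L[1, 2] <- -0.2; L[3, 2] <- 0.1
  expect_identical(selectVariables(L), c("a", "c"))  # "a" counted once
})

test_that("the reference loading table yields the documented 28-variable subset", {
  ref <- referenceLoadings()
  L <- as.matrix(ref[, c("SPC1", "SPC2")])
  rownames(L) <- ref$index
  kept <- selectVariables(L)
  expect_length(kept, 28L)
  expect_setequal(setdiff(ref$index, kept),
                  c("NR", "NG", "NB", "SCI", "NGRDI", "VARI", "RI"))
})

test_that("GA selection is deterministic and matches exhaustive enumeration at small p", {
  X <- randomStandardized(40, 3, seed = 21)
  for (seed in 1:5) {
    cfg <- gaConfig(seed = seed, n_generations = 50)
    g1 <- gaSelectNNZL(X, k = 1, config = cfg)
    g2 <- gaSelectNNZL(X, k = 1, config = cfg)
    expect_identical(g1$nnzl, g2$nnzl)
    # oracle: enumerate all cardinality choices under the same fitness
    pc <- fitPCA(X, variance_cutoff = 1)
    cpv <- explainedVariance(pc)[1]
    fits <- vapply(1:3, function(c) {
      sp <- fitSPCA(X, nnzl = c)
      sum(explainedVariance(sp)) / cpv - cfg$sparsity_weight * c / 3
    }, numeric(1))
    expect_identical(g1$nnzl, which.max(fits))
    expect_equal(g1$fitness, max(fits), tolerance = 1e-10)
  }
})

test_that("with no sparsity pressure the GA keeps full cardinality", {
  X <- randomStandardized(30, 4, seed = 41)
  g <- gaSelectNNZL(X, k = 2,
                    config = gaConfig(seed = 5, sparsity_weight = 0,
                                      n_generations = 40))
  expect_identical(g$nnzl, c(4L, 4L))
  expect_equal(g$fitness, 1, tolerance = 1e-6)
})

test_that("the GA never returns a chromosome worse than its initial population", {
  X <- randomStandardized(35, 5, seed = 61)
  g <- gaSelectNNZL(X, k = 2, config = gaConfig(seed = 13, n_generations = 15))
  expect_gte(g$fitness, max(g$initial_fitness))
  expect_error(gaSelectNNZL(X, k = 9, config = gaConfig(seed = 1)), "exceed")
})
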