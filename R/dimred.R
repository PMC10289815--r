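#' Feature standardizer (center and unit-variance scale)
#'
#' Learns per-feature mean and standard deviation on training data only.
#' Constant features (SD = 0) are flagged and dropped with a warning, so the
#' transform is always well defined. Applying the fitted standardizer to new
#' data never re-estimates the statistics.
#'
#' @param X numeric matrix (samples x features) with column names.
#' @return an object of class \code{Standardizer}.
#' @seealso [applyStandardizer()]
#' @export
fitStandardizer <- function(X) {
  stopIfNot(is.matrix(X) && is.numeric(X), "`X` must be a numeric matrix")
  if (anyNA(X)) stop("`X` contains missing values; impute first", call. = FALSE)
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  dropped <- colnames(X)[sdev == 0]
  if (length(dropped))
    warning("dropping constant feature(s): ", paste(dropped, collapse = ", "),
            call. = FALSE)
  keep <- sdev > 0
  structure(list(mean = mu[keep], sd = sdev[keep],
                 features = colnames(X)[keep], dropped = dropped),
            class = "Standardizer")
}

#' @rdname fitStandardizer
#' @param std a fitted \code{Standardizer}.
#' @export
applyStandardizer <- function(std, X) {
  stopIfNot(inherits(std, "Standardizer"), "`std` must be a Standardizer")
  stopIfNot(all(std$features %in% colnames(X)),
            "`X` lacks features seen at fitting time")
  Xs <- X[, std$features, drop = FALSE]
  sweep(sweep(Xs, 2, std$mean, "-"), 2, std$sd, "/")
}

.signConvention <- function(L) {
  for (j in seq_len(ncol(L)))
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  L
}

#' Principal component analysis with a cumulative-variance cutoff
#'
#' Operates on a standardized feature matrix (so the decomposition is that
#' of the feature correlation structure), via singular value decomposition.
#' The number of retained components is the smallest k whose cumulative
#' explained-variance fraction reaches \code{variance_cutoff}. The sign of
#' each loading column is fixed so its largest-magnitude entry is positive.
#'
#' @param X standardized samples x features matrix (see [fitStandardizer()]).
#' @param variance_cutoff cumulative explained-variance fraction (default
#'   0.85, the conventional ~85\% cutoff).
#' @return a [ReductionResult-class] with \code{method = "pca"}.
#' @export
fitPCA <- function(X, variance_cutoff = 0.85) {
  stopIfNot(is.matrix(X) && is.numeric(X), "`X` must be a numeric matrix")
  if (anyNA(X) || any(!is.finite(X)))
    stop("`X` contains non-finite values", call. = FALSE)
  stopIfNot(nrow(X) >= 2, "need at least 2 samples")
  stopIfNot(variance_cutoff > 0 && variance_cutoff <= 1,
            "`variance_cutoff` must be in (0, 1]")
  n <- nrow(X); p <- ncol(X)
  Xc <- sweep(X, 2, colMeans(X), "-")  # guard: X is expected centered already
  sv <- svd(Xc)
  ev <- sv$d^2 / (n - 1)
  frac <- ev / sum(ev)
  k <- which(cumsum(frac) >= variance_cutoff - 1e-12)[1]
  L <- .signConvention(sv$v[, seq_len(k), drop = FALSE])
  rownames(L) <- colnames(X)
  colnames(L) <- paste0("PC", seq_len(k))
  S <- Xc %*% L
  colnames(S) <- colnames(L); rownames(S) <- rownames(X)
  new("ReductionResult",
      loadings = L, scores = S,
      explainedVariance = frac[seq_len(k)], allFractions = frac,
      kRetained = as.integer(k), method = "pca",
      nnzl = integer(0), retainedVariables = character(0),
      iterations = 0L, converged = TRUE)
}

# Hard-threshold each column to its nnzl largest-magnitude entries.
.hardThreshold <- function(B, nnzl) {
  for (j in seq_len(ncol(B))) {
    o <- order(abs(B[, j]), decreasing = TRUE)
    drop <- o[-seq_len(nnzl[j])]
    B[drop, j] <- 0
  }
  B
}

.normalizeCols <- function(B) {
  nrm <- sqrt(colSums(B^2))
  nrm[nrm == 0] <- 1
  sweep(B, 2, nrm, "/")
}

# Alternating minimization on precomputed cross-products; reused by the GA
# so the Cholesky factor of (X'X + ridge I) is built once per dataset.
.spcaCore <- function(XtX, cholR, A0, nnzl, max_iter, tol) {
  Bn_old <- .hardThreshold(A0, nnzl)
  Bn_old <- .normalizeCols(Bn_old)
  A <- A0
  iter <- 0L; converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    # B-update: ridge regression of each X a_j on X, then hard threshold
    B <- backsolve(cholR, backsolve(cholR, XtX %*% A, transpose = TRUE))
    B <- .hardThreshold(B, nnzl)
    Bn <- .normalizeCols(B)
    if (max(abs(Bn - Bn_old)) < tol) { converged <- TRUE; Bn_old <- Bn; break }
    Bn_old <- Bn
    # A-update: orthogonal Procrustes via SVD of X'X B
    sv <- svd(XtX %*% B)
    A <- sv$u %*% t(sv$v)
  }
  list(loadings = Bn_old, iterations = iter, converged = converged)
}

# Adjusted explained variance of (possibly correlated) sparse components:
# QR decomposition of the scores; component j contributes R[j,j]^2 / (n-1).
.adjustedVariance <- function(X, L) {
  Z <- X %*% L
  R <- qr.R(qr(Z))
  diag(R)^2 / (nrow(X) - 1)
}

#' Cardinality-constrained sparse principal component analysis
#'
#' Alternating-minimization sparse PCA in the elastic-net formulation with a
#' per-component cardinality constraint ("varnum" convention): each B-update
#' ridge-regresses with a small quadratic penalty and hard-thresholds to the
#' \code{nnzl[j]} largest-magnitude coefficients; each A-update solves the
#' orthogonal Procrustes problem via SVD of \eqn{X'XB}. Iteration stops when
#' the maximum absolute change of the normalized loadings falls below
#' \code{tol} or after \code{max_iter} sweeps (default 200, with a 1e-6
#' quadratic penalty). Explained variance is the adjusted explained variance
#' from the QR decomposition of the sparse scores.
#'
#' @param X standardized samples x features matrix.
#' @param nnzl integer vector: target number of nonzero loadings per
#'   component (length = number of components, entries in 1..p).
#' @param max_iter,ridge_penalty,tol alternation controls.
#' @return a [ReductionResult-class] with \code{method = "spca"}.
#' @export
fitSPCA <- function(X, nnzl, max_iter = 200L, ridge_penalty = 1e-6,
                    tol = 1e-6) {
  stopIfNot(is.matrix(X) && is.numeric(X), "`X` must be a numeric matrix")
  if (anyNA(X) || any(!is.finite(X)))
    stop("`X` contains non-finite values", call. = FALSE)
  p <- ncol(X); n <- nrow(X)
  k <- length(nnzl)
  stopIfNot(k >= 1, "`nnzl` must have at least one entry")
  if (any(nnzl < 1 | nnzl > p))
    stop("`nnzl` entries must lie in [1, ", p, "]", call. = FALSE)
  nnzl <- as.integer(nnzl)
  Xc <- sweep(X, 2, colMeans(X), "-")
  XtX <- crossprod(Xc)
  cholR <- chol(XtX + ridge_penalty * diag(p))
  A0 <- svd(Xc, nu = 0, nv = k)$v
  fit <- .spcaCore(XtX, cholR, A0, nnzl, max_iter, tol)
  L <- .signConvention(fit$loadings)
  rownames(L) <- colnames(X)
  colnames(L) <- paste0("SPC", seq_len(k))
  S <- Xc %*% L
  colnames(S) <- colnames(L); rownames(S) <- rownames(X)
  totvar <- sum(diag(XtX)) / (n - 1)
  adj <- .adjustedVariance(Xc, L) / totvar
  retained <- rownames(L)[rowSums(abs(L) > 0) > 0]
  new("ReductionResult",
      loadings = L, scores = S,
      explainedVariance = adj, allFractions = numeric(0),
      kRetained = as.integer(k), method = "spca",
      nnzl = nnzl, retainedVariables = retained,
      iterations = fit$iterations, converged = fit$converged)
}

#' Variables retained by a sparse fit
#'
#' The union of variables with a nonzero loading in any sparse component,
#' each counted once (a variable nonzero in several components is retained
#' once).
#'
#' @param result a sparse [ReductionResult-class], or a loadings matrix.
#' @return character vector of retained variable names.
#' @export
selectVariables <- function(result) {
  L <- if (is(result, "ReductionResult")) result@loadings else as.matrix(result)
  stopIfNot(!is.null(rownames(L)), "loadings must have row names")
  rownames(L)[rowSums(abs(L) > 0) > 0]
}

#' Genetic-algorithm configuration for NNZL selection
#'
#' @param population_size,n_generations,tournament_size,crossover_prob,
#'   mutation_prob,elitism_count standard integer-GA controls.
#' @param sparsity_weight weight of the cardinality penalty in the fitness
#'   (0 = pure explained variance).
#' @param seed mandatory RNG seed; the search is deterministic given it.
#' @export
gaConfig <- function(population_size = 20L, n_generations = 50L,
                     tournament_size = 3L, crossover_prob = 0.8,
                     mutation_prob = 0.1, elitism_count = 1L,
                     sparsity_weight = 0.5, seed) {
  stopIfNot(population_size >= 2, "`population_size` must be >= 2")
  stopIfNot(crossover_prob >= 0 && crossover_prob <= 1 &&
              mutation_prob >= 0 && mutation_prob <= 1,
            "probabilities must lie in [0, 1]")
  stopIfNot(!missing(seed), "`seed` is required")
  structure(list(
    population_size = as.integer(population_size),
    n_generations = as.integer(n_generations),
    tournament_size = as.integer(tournament_size),
    crossover_prob = crossover_prob, mutation_prob = mutation_prob,
    elitism_count = as.integer(elitism_count),
    sparsity_weight = sparsity_weight, seed = as.integer(seed)
  ), class = "GAConfig")
}

# Fitness of a cardinality chromosome: adjusted explained variance of the
# sparse fit relative to the retained-PCA cumulative variance, minus a
# sparsity penalty proportional to total cardinality.
.nnzlFitness <- function(chrom, ctx) {
  key <- paste(chrom, collapse = ",")
  hit <- ctx$memo[[key]]
  if (!is.null(hit)) return(hit)
  fit <- .spcaCore(ctx$XtX, ctx$cholR, ctx$A0, chrom, ctx$max_iter, ctx$tol)
  apev <- sum(.adjustedVariance(ctx$Xc, fit$loadings)) / ctx$totvar
  f <- apev / ctx$cpv - ctx$w * sum(chrom) / (ctx$k * ctx$p)
  ctx$memo[[key]] <- f
  f
}

.gaContext <- function(X, k, config, max_iter, ridge_penalty, tol) {
  p <- ncol(X); n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X), "-")
  XtX <- crossprod(Xc)
  sv <- svd(Xc, nu = 0)
  ev <- sv$d^2 / (n - 1)
  ctx <- new.env(parent = emptyenv())
  ctx$Xc <- Xc; ctx$XtX <- XtX
  ctx$cholR <- chol(XtX + ridge_penalty * diag(p))
  ctx$A0 <- sv$v[, seq_len(k), drop = FALSE]
  ctx$totvar <- sum(diag(XtX)) / (n - 1)
  ctx$cpv <- sum(ev[seq_len(k)]) / sum(ev)
  ctx$max_iter <- max_iter; ctx$tol <- tol
  ctx$k <- k; ctx$p <- p; ctx$w <- config$sparsity_weight
  ctx$memo <- new.env(parent = emptyenv())
  ctx
}

#' Choose the number of nonzero loadings per sparse component by a GA
#'
#' Chromosomes are integer vectors of length k (one cardinality target per
#' component, entries in 1..p). Fitness trades the adjusted explained
#' variance of the sparse fit (relative to the retained-PCA cumulative
#' variance) against total cardinality. Selection is by tournament, with
#' uniform crossover, a +/-1-step integer mutation and elitism; the search
#' is deterministic under the configured seed.
#'
#' @param X standardized samples x features matrix.
#' @param k number of components (from [fitPCA()]'s retained count).
#' @param config a [gaConfig()].
#' @param max_iter,ridge_penalty,tol passed to the inner sparse-PCA fits.
#' @return list with \code{nnzl} (the best chromosome), its \code{fitness},
#'   the \code{initial_fitness} values of the starting population, and the
#'   best-fitness \code{trace} per generation.
#' @export
gaSelectNNZL <- function(X, k, config, max_iter = 200L,
                         ridge_penalty = 1e-6, tol = 1e-6) {
  stopIfNot(inherits(config, "GAConfig"), "`config` must be gaConfig()")
  p <- ncol(X)
  stopIfNot(k >= 1, "`k` must be >= 1")
  if (k > p) stop("`k` must not exceed the number of features", call. = FALSE)
  ctx <- .gaContext(X, k, config, max_iter, ridge_penalty, tol)
  np <- config$population_size
  withLocalSeed(config$seed, {
    pop <- lapply(seq_len(np), function(i) sample.int(p, k, replace = TRUE))
    fitness <- vapply(pop, .nnzlFitness, numeric(1), ctx = ctx)
    initial_fitness <- fitness
    trace <- numeric(config$n_generations)
    for (g in seq_len(config$n_generations)) {
      ord <- order(fitness, decreasing = TRUE)
      elite <- pop[ord[seq_len(config$elitism_count)]]
      tournament <- function() {
        cand <- sample.int(np, config$tournament_size, replace = TRUE)
        pop[[cand[which.max(fitness[cand])]]]
      }
      children <- vector("list", np - config$elitism_count)
      for (i in seq_along(children)) {
        p1 <- tournament(); p2 <- tournament()
        child <- if (runif(1) < config$crossover_prob) {
          mask <- runif(k) < 0.5
          ifelse(mask, p1, p2)
        } else p1
        mut <- runif(k) < config$mutation_prob
        step <- sample(c(-1L, 1L), k, replace = TRUE)
        child[mut] <- clamp(child[mut] + step[mut], 1L, p)
        children[[i]] <- as.integer(child)
      }
      pop <- c(elite, children)
      fitness <- vapply(pop, .nnzlFitness, numeric(1), ctx = ctx)
      trace[g] <- max(fitness)
    }
    best <- which.max(fitness)
    list(nnzl = as.integer(pop[[best]]), fitness = fitness[best],
         initial_fitness = initial_fitness, trace = trace)
  })
}
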