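#' Repeated hold-out split plan
#'
#' Draws \code{n_repeats} independent random train/test partitions of
#' \code{1..n}; every model variant in a comparison consumes the identical
#' plan, so differences between variants are never due to the split. The
#' train set holds \code{floor(train_fraction * n)} samples.
#'
#' @param n number of samples (>= 10).
#' @param train_fraction fraction of samples used for training (default 0.7).
#' @param n_repeats number of hold-out iterations (default 5).
#' @param master_seed seed making the plan reproducible.
#' @return object of class \code{SplitPlan}: \code{splits} is a list of
#'   \code{list(train =, test =)} index pairs.
#' @export
makeSplitPlan <- function(n, train_fraction = 0.7, n_repeats = 5L,
                          master_seed) {
  stopIfNot(n >= 10, "`n` must be >= 10")
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("`train_fraction` must lie strictly between 0 and 1", call. = FALSE)
  stopIfNot(!missing(master_seed), "`master_seed` is required")
  n_train <- floor(train_fraction * n)
  stopIfNot(n_train >= 1 && n_train < n, "degenerate split sizes")
  splits <- withLocalSeed(master_seed, {
    lapply(seq_len(n_repeats), function(j) {
      tr <- sort(sample.int(n, n_train))
      list(train = tr, test = setdiff(seq_len(n), tr))
    })
  })
  structure(list(splits = splits, n = as.integer(n),
                 train_fraction = train_fraction,
                 n_repeats = as.integer(n_repeats),
                 master_seed = as.integer(master_seed)),
            class = "SplitPlan")
}

#' Prediction accuracy metrics
#'
#' The coefficient of determination is the squared Pearson correlation of
#' observed and predicted values; the root mean squared error uses an n - 1
#' denominator; the mean absolute error uses n.
#'
#' @param observed,predicted numeric vectors of equal length (n >= 3).
#' @return object of class \code{MetricSet}: \code{r_squared}, \code{rmse},
#'   \code{mae}, \code{n_test}.
#' @export
computeMetrics <- function(observed, predicted) {
  stopIfNot(length(observed) == length(predicted), "length mismatch")
  n <- length(observed)
  stopIfNot(n >= 3, "need at least 3 observations")
  if (sd(observed) == 0)
    stop("undefined R-squared: observed values have zero variance",
         call. = FALSE)
  r2 <- if (sd(predicted) == 0) {
    warning("constant predictions: R-squared undefined, reported as NA",
            call. = FALSE)
    NA_real_
  } else cor(observed, predicted)^2
  structure(list(
    r_squared = r2,
    rmse = sqrt(sum((predicted - observed)^2) / (n - 1)),
    mae = mean(abs(observed - predicted)),
    n_test = n
  ), class = "MetricSet")
}

#' Composite general performance indicator (GPI) and model ranks
#'
#' For each indicator the metric values of all model x iteration cells in
#' one cultivar x trait scenario are min-max normalized to the unit
#' interval; the scenario median of the normalized cells is the reference.
#' A model's GPI is the signed sum, over iterations and indicators, of the
#' deviation of its normalized value from that median, with sign -1 for the
#' coefficient of determination and +1 for the error indicators, so a
#' larger GPI always means a better model. Ranks are assigned by descending
#' GPI; ties are broken by model registration order.
#'
#' @param metrics long data.frame with columns \code{model},
#'   \code{iteration}, \code{indicator} (\code{"r_squared"}, \code{"rmse"},
#'   \code{"mae"}) and \code{value}; the grid must be complete.
#' @param alpha sign per indicator.
#' @return object of class \code{GPIResult}: named \code{gpi}, named
#'   \code{ranks}, the normalized table, the per-indicator medians and the
#'   sign map.
#' @export
computeGPI <- function(metrics,
                       alpha = c(r_squared = -1, rmse = 1, mae = 1)) {
  need <- c("model", "iteration", "indicator", "value")
  stopIfNot(all(need %in% colnames(metrics)), "missing metric columns")
  models <- unique(as.character(metrics$model))  # registration order
  inds <- names(alpha)
  stopIfNot(all(metrics$indicator %in% inds), "unknown indicator")
  tab <- table(metrics$model, metrics$iteration, metrics$indicator)
  stopIfNot(all(tab == 1), "metric grid must be complete (one value per cell)")
  norm <- metrics
  norm$norm_value <- NA_real_
  med <- setNames(numeric(length(inds)), inds)
  for (i in inds) {
    sel <- norm$indicator == i
    v <- norm$value[sel]
    rng <- range(v)
    if (diff(rng) == 0) {
      warning("indicator '", i, "' constant across all cells; ",
              "normalized values set to 0.5", call. = FALSE)
      norm$norm_value[sel] <- 0.5
    } else {
      norm$norm_value[sel] <- (v - rng[1]) / diff(rng)
    }
    med[i] <- median(norm$norm_value[sel])
  }
  gpi <- vapply(models, function(m) {
    rows <- norm[norm$model == m, ]
    sum(alpha[rows$indicator] * (med[rows$indicator] - rows$norm_value))
  }, numeric(1))
  ord <- order(-gpi, seq_along(gpi))
  ranks <- integer(length(models)); ranks[ord] <- seq_along(models)
  names(ranks) <- models
  structure(list(gpi = gpi, ranks = ranks, normalized = norm,
                 medians = med, alpha = alpha),
            class = "GPIResult")
}

#' Rank models by descending GPI
#'
#' @param gpi named numeric GPI values (names give registration order).
#' @return integer ranks (1 = best), ties broken by registration order.
#' @export
rankByGPI <- function(gpi) {
  ord <- order(-gpi, seq_along(gpi))
  ranks <- integer(length(gpi)); ranks[ord] <- seq_along(gpi)
  names(ranks) <- names(gpi)
  ranks
}

#' Pool test-set residuals across hold-out iterations
#'
#' Residuals are observed minus fitted on the test sets, concatenated over
#' iterations. Reports the mean (not assumed zero), SD, the +/- 2 SD band
#' about the mean, the interquartile range and a locally weighted smooth of
#' residual versus fitted value (span 0.75).
#'
#' @param observed,fitted numeric vectors (concatenated test sets), or lists
#'   of per-iteration vectors.
#' @return object of class \code{ResidualDiagnostics}.
#' @export
poolResiduals <- function(observed, fitted) {
  if (is.list(observed)) observed <- unlist(observed, use.names = FALSE)
  if (is.list(fitted)) fitted <- unlist(fitted, use.names = FALSE)
  stopIfNot(length(observed) == length(fitted), "length mismatch")
  res <- observed - fitted
  m <- mean(res); s <- if (length(res) > 1) sd(res) else 0
  smooth <- if (length(res) >= 4) lowess(fitted, res, f = 0.75) else NULL
  structure(list(
    residuals = res, fitted = fitted, n = length(res),
    mean = m, sd = s, iqr = IQR(res),
    band = c(lower = m - 2 * s, upper = m + 2 * s),
    smooth = smooth
  ), class = "ResidualDiagnostics")
}

# Median-impute undefined feature values using training-set medians only.
.imputeByTrainMedian <- function(Xtr, Xte) {
  med <- apply(Xtr, 2, median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  fill <- function(X) {
    for (j in seq_len(ncol(X))) {
      bad <- !is.finite(X[, j])
      if (any(bad)) X[bad, j] <- med[j]
    }
    X
  }
  list(train = fill(Xtr), test = fill(Xte))
}

#' Benchmark the three network variants on one cultivar x trait scenario
#'
#' For every split of the plan, fits on the training rows only: the feature
#' standardizer, then (a) \code{BPNN} on all 35 standardized indexes, (b)
#' \code{PCA_BPNN} on the retained principal-component scores (the
#' train-fitted projection applied to the test rows), and (c)
#' \code{SPCA_BPNN} on the standardized indexes surviving the GA-driven
#' sparse-PCA nonzero-loading filter. All three variants share the identical
#' split. Per-split metrics, the scenario GPI and ranks, pooled residual
#' diagnostics and a fit log (which rows each fitting stage saw) are
#' returned.
#'
#' @param ise an [OliveIndexSet-class] holding one cultivar's samples.
#' @param trait response column in \code{colData} (\code{"oil"} or
#'   \code{"phenols"}).
#' @param plan a [makeSplitPlan()] for \code{ncol(ise)} samples.
#' @param pca_cutoff cumulative-variance cutoff for the retained PCs.
#' @param ga a [gaConfig()]; its seed is re-derived per split.
#' @param spca_control list with \code{max_iter}, \code{ridge_penalty},
#'   \code{tol} for the sparse fits.
#' @param net_control named list of [networkSpec()] overrides (e.g.
#'   \code{max_epochs}).
#' @param clip_z_margin test-set standardized features are clamped to the
#'   training set's observed per-feature range widened by this many z units
#'   (leakage-safe: training statistics only). Ratio-type indexes such as
#'   the hue arctangents saturate and can standardize to extreme values when
#'   a noisy test sample crosses a denominator sign change the training
#'   split never saw; unclamped, a single such point saturates the network
#'   and voids the split. \code{NULL} disables the guard.
#' @return object of class \code{ScenarioReport}.
#' @export
runScenario <- function(ise, trait, plan, pca_cutoff = 0.85,
                        ga = gaConfig(seed = plan$master_seed),
                        spca_control = list(max_iter = 200L,
                                            ridge_penalty = 1e-6, tol = 1e-6),
                        net_control = list(), clip_z_margin = 3) {
  stopIfNot(is(ise, "OliveIndexSet"), "`ise` must be an OliveIndexSet")
  stopIfNot(inherits(plan, "SplitPlan"), "`plan` must be a SplitPlan")
  cd <- SummarizedExperiment::colData(ise)
  stopIfNot(trait %in% colnames(cd), "trait column not found")
  X_all <- indexMatrix(ise)
  y_all <- as.numeric(cd[[trait]])
  stopIfNot(plan$n == nrow(X_all), "plan size must match the sample count")
  models <- c("BPNN", "PCA_BPNN", "SPCA_BPNN")

  metric_rows <- list(); pred_store <- list(); fit_log <- list()
  flags <- list()
  for (j in seq_len(plan$n_repeats)) {
    tr <- plan$splits[[j]]$train; te <- plan$splits[[j]]$test
    imp <- .imputeByTrainMedian(X_all[tr, , drop = FALSE],
                                X_all[te, , drop = FALSE])
    std <- fitStandardizer(imp$train)
    Xtr <- applyStandardizer(std, imp$train)
    Xte <- applyStandardizer(std, imp$test)
    if (!is.null(clip_z_margin)) {
      lo <- apply(Xtr, 2, min) - clip_z_margin
      hi <- apply(Xtr, 2, max) + clip_z_margin
      Xte <- sweep(Xte, 2, lo, pmax)
      Xte <- sweep(Xte, 2, hi, pmin)
    }
    ytr <- y_all[tr]; yte <- y_all[te]

    pca <- fitPCA(Xtr, variance_cutoff = pca_cutoff)
    ga_j <- ga; ga_j$seed <- deriveSeed(ga$seed, 77L, j)
    sel <- gaSelectNNZL(Xtr, k = pca@kRetained, config = ga_j,
                        max_iter = spca_control$max_iter,
                        ridge_penalty = spca_control$ridge_penalty,
                        tol = spca_control$tol)
    sp <- fitSPCA(Xtr, sel$nnzl, max_iter = spca_control$max_iter,
                  ridge_penalty = spca_control$ridge_penalty,
                  tol = spca_control$tol)
    vars <- selectVariables(sp)

    inputs <- list(
      BPNN = list(train = Xtr, test = Xte),
      PCA_BPNN = list(train = pca@scores,
                      test = sweep(Xte, 2, colMeans(Xtr), "-") %*% pca@loadings),
      SPCA_BPNN = list(train = Xtr[, vars, drop = FALSE],
                       test = Xte[, vars, drop = FALSE])
    )
    fit_log[[j]] <- list(
      standardizer_rows = tr, pca_rows = tr, ga_rows = tr,
      target_scaling_rows = tr,
      nnzl = sel$nnzl, retained_variables = vars
    )
    for (m in models) {
      inp <- inputs[[m]]
      spec_args <- c(list(n_inputs = ncol(inp$train),
                          seed = deriveSeed(plan$master_seed, j, match(m, models))),
                     net_control)
      spec <- do.call(networkSpec, spec_args)
      net <- trainBPNN(spec, inp$train, ytr)
      pred <- predict(net, inp$test)
      ms <- computeMetrics(yte, pred)
      metric_rows[[length(metric_rows) + 1L]] <- data.frame(
        model = m, iteration = j,
        indicator = c("r_squared", "rmse", "mae"),
        value = c(ms$r_squared, ms$rmse, ms$mae),
        stringsAsFactors = FALSE
      )
      pred_store[[m]]$observed[[j]] <- yte
      pred_store[[m]]$fitted[[j]] <- pred
      flags[[m]][[j]] <- list(converged = net@converged, epochs = net@epochs)
    }
  }
  metrics <- do.call(rbind, metric_rows)
  gpi <- computeGPI(metrics)
  residuals <- lapply(pred_store, function(s)
    poolResiduals(s$observed, s$fitted))
  mean_r2 <- vapply(models, function(m)
    mean(metrics$value[metrics$model == m & metrics$indicator == "r_squared"]),
    numeric(1))
  structure(list(
    trait = trait,
    cultivar = unique(as.character(cd$cultivar))[1],
    models = models,
    metrics = metrics, mean_r_squared = mean_r2,
    gpi = gpi$gpi, ranks = gpi$ranks,
    residuals = residuals, flags = flags, fit_log = fit_log,
    seeds = list(master_seed = plan$master_seed, ga_seed = ga$seed),
    config = list(pca_cutoff = pca_cutoff, ga = unclass(ga),
                  spca = spca_control, net = net_control,
                  train_fraction = plan$train_fraction,
                  n_repeats = plan$n_repeats)
  ), class = "ScenarioReport")
}
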