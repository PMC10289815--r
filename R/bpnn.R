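#' Hidden-layer size from the N/3 + 2 rule
#'
#' The number of hidden nodes is the number of input covariates divided by
#' three, plus two, rounded half-up.
#'
#' @param n_inputs number of input covariates (>= 1).
#' @return integer hidden-layer size.
#' @examples
#' hiddenNodes(35)  # 14
#' hiddenNodes(2)   # 3
#' @export
hiddenNodes <- function(n_inputs) {
  stopIfNot(is.numeric(n_inputs) && n_inputs >= 1, "`n_inputs` must be >= 1")
  as.integer(roundHalfUp(n_inputs / 3 + 2))
}

#' Network and training specification
#'
#' Topology is one input layer, one logistic hidden layer sized by the
#' N/3 + 2 rule, and one linear output node. Targets are min-max scaled to
#' the unit interval on the training set; predictions are mapped back.
#' Training uses resilient backpropagation (Rprop+ with weight backtracking)
#' on the summed-squared-error gradient.
#'
#' @param n_inputs number of input covariates.
#' @param n_hidden hidden nodes; defaults to [hiddenNodes()].
#' @param eta_plus,eta_minus step-size increase/decrease factors.
#' @param delta_init,delta_min,delta_max initial and bounding step sizes.
#' @param gradient_threshold stop when the largest absolute gradient entry
#'   falls below this value.
#' @param max_epochs epoch budget; hitting it flags non-convergence.
#' @param seed RNG seed for the uniform(-0.5, 0.5) weight initialization.
#' @export
networkSpec <- function(n_inputs, n_hidden = hiddenNodes(n_inputs),
                        eta_plus = 1.2, eta_minus = 0.5,
                        delta_init = 0.1, delta_min = 1e-6, delta_max = 50,
                        gradient_threshold = 0.01, max_epochs = 10000L,
                        seed = 1L) {
  stopIfNot(n_inputs >= 1 && n_hidden >= 1, "invalid topology")
  structure(list(
    n_inputs = as.integer(n_inputs), n_hidden = as.integer(n_hidden),
    eta_plus = eta_plus, eta_minus = eta_minus,
    delta_init = delta_init, delta_min = delta_min, delta_max = delta_max,
    gradient_threshold = gradient_threshold,
    max_epochs = as.integer(max_epochs), seed = as.integer(seed)
  ), class = "NetworkSpec")
}

# Forward pass on the scaled-target net. X has no bias column here.
.bpnnForward <- function(W1, W2, X) {
  H <- plogis(cbind(1, X) %*% W1)
  list(H = H, yhat = drop(cbind(1, H) %*% W2))
}

# Gradient of E = 0.5 * sum((yhat - u)^2) w.r.t. both weight matrices.
.bpnnGradient <- function(W1, W2, X, u) {
  fw <- .bpnnForward(W1, W2, X)
  d2 <- fw$yhat - u
  gW2 <- crossprod(cbind(1, fw$H), d2)
  dH <- (d2 %*% t(W2[-1, , drop = FALSE])) * fw$H * (1 - fw$H)
  gW1 <- crossprod(cbind(1, X), dH)
  list(gW1 = gW1, gW2 = gW2,
       error = 0.5 * sum(d2^2))
}

#' Train the regression network by Rprop+
#'
#' Weights start uniform(-0.5, 0.5) from the spec's seed. Each epoch updates
#' every weight by its own adaptive step: steps grow by \code{eta_plus} when
#' the partial derivative keeps its sign, shrink by \code{eta_minus} (and the
#' previous update is reverted) when it flips. Training stops when the
#' largest absolute gradient entry drops below \code{gradient_threshold} or
#' at \code{max_epochs}, in which case the state is flagged non-converged.
#'
#' @param spec a [networkSpec()].
#' @param X_train samples x n_inputs matrix of (standardized) covariates.
#' @param y_train numeric targets in original units.
#' @return an [RpropNet-class].
#' @export
trainBPNN <- function(spec, X_train, y_train) {
  stopIfNot(inherits(spec, "NetworkSpec"), "`spec` must be networkSpec()")
  X <- as.matrix(X_train)
  stopIfNot(ncol(X) == spec$n_inputs, "X_train column count must match spec")
  stopIfNot(nrow(X) == length(y_train), "X_train rows must match y_train")
  if (anyNA(X) || any(!is.finite(X)) || any(!is.finite(y_train)))
    stop("non-finite training inputs", call. = FALSE)
  stopIfNot(nrow(X) >= spec$n_hidden,
            "need at least as many training rows as hidden nodes")
  yr <- range(y_train)
  if (yr[1] == yr[2])
    stop("constant training targets: min-max scaling undefined", call. = FALSE)
  u <- (y_train - yr[1]) / (yr[2] - yr[1])

  p <- spec$n_inputs; h <- spec$n_hidden
  withLocalSeed(spec$seed, {
    W1 <- matrix(runif((p + 1) * h, -0.5, 0.5), p + 1, h)
    W2 <- matrix(runif(h + 1, -0.5, 0.5), h + 1, 1)
  })
  D1 <- matrix(spec$delta_init, p + 1, h)
  D2 <- matrix(spec$delta_init, h + 1, 1)
  pg1 <- matrix(0, p + 1, h); pg2 <- matrix(0, h + 1, 1)
  pd1 <- matrix(0, p + 1, h); pd2 <- matrix(0, h + 1, 1)
  trace <- numeric(spec$max_epochs)
  converged <- FALSE
  epoch <- 0L

  rpropStep <- function(g, pg, D, pdw) {
    s <- sign(g * pg)
    up <- s > 0; down <- s < 0
    D[up] <- pmin(D[up] * spec$eta_plus, spec$delta_max)
    D[down] <- pmax(D[down] * spec$eta_minus, spec$delta_min)
    dw <- -sign(g) * D
    dw[down] <- -pdw[down]   # backtrack the previous update
    g[down] <- 0             # skip the adaptation next epoch
    list(dw = dw, D = D, g = g)
  }

  while (epoch < spec$max_epochs) {
    epoch <- epoch + 1L
    gr <- .bpnnGradient(W1, W2, X, u)
    trace[epoch] <- gr$error
    if (max(abs(gr$gW1), abs(gr$gW2)) < spec$gradient_threshold) {
      converged <- TRUE
      break
    }
    s1 <- rpropStep(gr$gW1, pg1, D1, pd1)
    s2 <- rpropStep(gr$gW2, pg2, D2, pd2)
    W1 <- W1 + s1$dw; W2 <- W2 + s2$dw
    D1 <- s1$D; D2 <- s2$D
    pg1 <- s1$g; pg2 <- s2$g
    pd1 <- s1$dw; pd2 <- s2$dw
  }
  new("RpropNet", W1 = W1, W2 = W2, spec = unclass(spec),
      yRange = yr, errorTrace = trace[seq_len(epoch)],
      converged = converged, epochs = epoch)
}

#' Predict in original target units
#'
#' Forward pass through the trained network followed by the inverse min-max
#' scaling learned on the training targets. Deterministic.
#'
#' @param object an [RpropNet-class].
#' @param newdata samples x n_inputs matrix.
#' @param ... ignored.
#' @return numeric predictions in original units.
#' @export
setMethod("predict", "RpropNet", function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object@spec$n_inputs)
    stop("`newdata` must have ", object@spec$n_inputs, " columns",
         call. = FALSE)
  out <- .bpnnForward(object@W1, object@W2, X)$yhat
  object@yRange[1] + out * (object@yRange[2] - object@yRange[1])
})
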