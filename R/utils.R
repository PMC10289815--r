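#' @importFrom methods new validObject is slot
#' @importFrom stats median sd cor runif rnorm lowess quantile IQR plogis setNames
#' @importFrom utils read.csv write.csv head
NULL

# Run code with a private RNG stream; the caller's .Random.seed is untouched.
withLocalSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Commercial rounding: 0.5 always rounds away from zero (here inputs are >= 0).
roundHalfUp <- function(x) floor(x + 0.5)

stopIfNot <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# Small deterministic seed mixer; keeps derived seeds inside 32-bit range.
deriveSeed <- function(master, ...) {
  parts <- c(master, ...)
  s <- 0
  for (p in parts) s <- (s * 69069 + as.double(p)) %% 2147483629
  as.integer(s)
}
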