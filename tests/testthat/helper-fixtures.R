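# Shared fixture builders; everything is generated in code at test time.

# Noise-free single-cultivar parameters for deterministic-path tests.
quietParams <- function(cultivar = "fixture", seed = 1L, ...) {
  trajectoryParams(cultivar,
                   noise_sd_trait = c(oil = 0, phenols = 0),
                   noise_sd_channel = 0, seed = seed, ...)
}

# Small standardized random matrix with named columns.
randomStandardized <- function(n, p, seed) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
  })
  colnames(X) <- paste0("V", seq_len(p))
  applyStandardizer(fitStandardizer(X), X)
}

# Flat color image (height x width x 3) on a uniform background.
flatImage <- function(h, w, rgb) {
  array(rep(rgb, each = h * w), dim = c(h, w, 3))
}

# Paint an axis-aligned ellipse of a given color; returns image + mask.
paintEllipse <- function(img, cx, cy, a, b, rgb) {
  h <- dim(img)[1]; w <- dim(img)[2]
  x <- matrix(rep(seq_len(w), each = h), nrow = h)
  y <- matrix(rep(seq_len(h), times = w), nrow = h)
  m <- ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1
  for (k in 1:3) img[, , k][m] <- rgb[k]
  list(image = img, mask = m)
}

# The default three-cultivar synthetic benchmark feature set.
benchmarkFeatures <- function(seed = 1L, n_times = 17L, reps = 3L) {
  samples <- generateDataset(cultivarPresets(seed = seed),
                             n_times = n_times, reps_per_time = reps)
  list(samples = samples, ise = buildFeatureTable(samples))
}
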