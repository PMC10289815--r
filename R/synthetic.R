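#' Trajectory parameters for one synthetic cultivar
#'
#' Describes the seasonal development of one cultivar on the
#' days-after-pit-hardening (DAPH) axis: a logistic rise of fruit oil
#' concentration (%FW), a truncated downward-parabolic trajectory of total
#' phenols (mg GAE per g DW), and quasi-parabolic mean R/G/B pixel-value
#' trajectories with per-channel peak, timing and curvature. Additive
#' Gaussian noise is applied per trait and per channel.
#'
#' @param cultivar_id cultivar label (unique within a dataset).
#' @param t_range DAPH interval \code{c(t_min, t_max)} covered by sampling.
#' @param oil_base,oil_max early-season and asymptotic oil concentration, %FW.
#' @param oil_midpoint,oil_rate logistic midpoint (DAPH) and rate (1/day).
#' @param phenol_peak,phenol_peak_time,phenol_curvature peak phenol
#'   concentration (mg GAE/g DW), its timing (DAPH) and the parabola
#'   curvature (mg/day^2).
#' @param channel_peak,channel_peak_time,channel_curvature length-3 vectors
#'   (R, G, B): peak mean pixel value (0-255), peak timing (DAPH) and
#'   parabola curvature.
#' @param noise_sd_trait named SDs \code{c(oil = , phenols = )}.
#' @param noise_sd_channel additive SD of the channel means.
#' @param seed RNG seed making the generated record set reproducible.
#' @return an object of class \code{TrajectoryParams}.
#' @seealso [generateTrajectory()], [cultivarPresets()]
#' @export
trajectoryParams <- function(cultivar_id,
                             t_range = c(0, 120),
                             oil_base = 5.5, oil_max = 22,
                             oil_midpoint = 60, oil_rate = 0.08,
                             phenol_peak = 41, phenol_peak_time = 45,
                             phenol_curvature = 0.0028,
                             channel_peak = c(140, 130, 65),
                             channel_peak_time = c(40, 45, 70),
                             channel_curvature = c(0.009, 0.009, 0.005),
                             noise_sd_trait = c(oil = 0.8, phenols = 2.0),
                             noise_sd_channel = 2.5,
                             seed = 1L) {
  stopIfNot(is.character(cultivar_id) && length(cultivar_id) == 1L,
            "`cultivar_id` must be a single label")
  stopIfNot(length(t_range) == 2L && t_range[1] < t_range[2],
            "`t_range` must be an increasing interval")
  stopIfNot(oil_base < oil_max, "`oil_base` must be below `oil_max`")
  stopIfNot(phenol_peak > 0, "`phenol_peak` must be positive")
  stopIfNot(length(channel_peak) == 3L && length(channel_peak_time) == 3L &&
              length(channel_curvature) == 3L,
            "channel parameters must be length-3 (R, G, B)")
  stopIfNot(all(noise_sd_trait >= 0) && all(noise_sd_channel >= 0),
            "noise SDs must be non-negative")
  structure(list(
    cultivar_id = cultivar_id, t_range = as.numeric(t_range),
    oil_base = oil_base, oil_max = oil_max,
    oil_midpoint = oil_midpoint, oil_rate = oil_rate,
    phenol_peak = phenol_peak, phenol_peak_time = phenol_peak_time,
    phenol_curvature = phenol_curvature,
    channel_peak = as.numeric(channel_peak),
    channel_peak_time = as.numeric(channel_peak_time),
    channel_curvature = as.numeric(channel_curvature),
    noise_sd_trait = noise_sd_trait, noise_sd_channel = noise_sd_channel,
    seed = as.integer(seed)
  ), class = "TrajectoryParams")
}

#' Default cultivar presets for the synthetic benchmark
#'
#' Three cultivars spanning the early/middle/late ripening groups. Ripening
#' timing is encoded as a shift of the channel peak times (-10 / 0 / +10
#' days for early / middle / late); the late cultivar carries the highest
#' phenol peak and the early one the lowest R and G peak values, mirroring
#' the qualitative cultivar differences seen in field data.
#'
#' @param seed base seed; each cultivar derives its own stream from it.
#' @return named list of [trajectoryParams()] objects.
#' @export
cultivarPresets <- function(seed = 1L) {
  list(
    cultivarA_late = trajectoryParams(
      "cultivarA_late",
      oil_max = 22, phenol_peak = 41,
      channel_peak = c(140, 130, 65),
      channel_peak_time = c(40, 45, 70) + 10,
      seed = deriveSeed(seed, 11L)
    ),
    cultivarB_middle = trajectoryParams(
      "cultivarB_middle",
      oil_max = 20, phenol_peak = 30,
      channel_peak = c(145, 135, 66),
      channel_peak_time = c(40, 45, 70),
      seed = deriveSeed(seed, 22L)
    ),
    cultivarC_early = trajectoryParams(
      "cultivarC_early",
      oil_max = 18, phenol_peak = 28,
      channel_peak = c(125, 115, 62),
      channel_peak_time = c(40, 45, 70) - 10,
      seed = deriveSeed(seed, 33L)
    )
  )
}

.oilCurve <- function(p, t) {
  p$oil_base + (p$oil_max - p$oil_base) /
    (1 + exp(-p$oil_rate * (t - p$oil_midpoint)))
}

.phenolCurve <- function(p, t) {
  pmax(0, p$phenol_peak - p$phenol_curvature * (t - p$phenol_peak_time)^2)
}

.channelCurve <- function(p, t, ch) {
  clamp(p$channel_peak[ch] - p$channel_curvature[ch] *
          (t - p$channel_peak_time[ch])^2, 0, 255)
}

#' Generate synthetic sample records along one cultivar's trajectory
#'
#' Evaluates the oil, phenol and channel trajectories at \code{n_times}
#' equally spaced DAPH values (with \code{reps_per_time} replicate samples
#' each), adds the configured Gaussian noise, and clamps to the physical
#' ranges (channels to 0-255, traits to >= 0).
#'
#' @param params a [trajectoryParams()] object.
#' @param n_times number of sampling times (>= 2).
#' @param reps_per_time replicate samples per time (>= 1).
#' @return a data.frame with columns \code{sample_id, cultivar, t, r_mean,
#'   g_mean, b_mean, oil, phenols}, sorted by \code{t}.
#' @examples
#' p <- trajectoryParams("demo", noise_sd_trait = c(oil = 0, phenols = 0),
#'                       noise_sd_channel = 0)
#' head(generateTrajectory(p, n_times = 5, reps_per_time = 1))
#' @export
generateTrajectory <- function(params, n_times, reps_per_time = 1L) {
  stopIfNot(inherits(params, "TrajectoryParams"), "`params` must be trajectoryParams()")
  stopIfNot(is.numeric(n_times) && n_times >= 2, "`n_times` must be >= 2")
  stopIfNot(is.numeric(reps_per_time) && reps_per_time >= 1,
            "`reps_per_time` must be >= 1")
  n_times <- as.integer(n_times); reps_per_time <- as.integer(reps_per_time)
  times <- seq(params$t_range[1], params$t_range[2], length.out = n_times)
  t <- rep(times, each = reps_per_time)
  n <- length(t)
  withLocalSeed(params$seed, {
    oil <- pmax(0, .oilCurve(params, t) +
                  rnorm(n, 0, params$noise_sd_trait[["oil"]]))
    phen <- pmax(0, .phenolCurve(params, t) +
                   rnorm(n, 0, params$noise_sd_trait[["phenols"]]))
    ch <- vapply(1:3, function(k)
      clamp(.channelCurve(params, t, k) + rnorm(n, 0, params$noise_sd_channel),
            0, 255), numeric(n))
    data.frame(
      sample_id = sprintf("%s_%03d", params$cultivar_id, seq_len(n)),
      cultivar = params$cultivar_id, t = t,
      r_mean = ch[, 1], g_mean = ch[, 2], b_mean = ch[, 3],
      oil = oil, phenols = phen,
      stringsAsFactors = FALSE
    )
  })
}

#' Rendering specification for synthetic fruit images
#'
#' @param width,height frame size in pixels.
#' @param background_rgb background color (8-bit triple); default a saturated
#'   blue so the CIELAB b* channel separates fruit from background.
#' @param n_fruits number of elliptical fruit to draw.
#' @param fruit_axes_range range of ellipse semi-axes in pixels.
#' @param fruit_jitter_sd per-fruit additive color jitter SD (per channel).
#' @param white_patch optional white reference patch,
#'   \code{list(x =, y =, w =, h =, rgb = c(255, 255, 255))} (0-based,
#'   origin top-left, half-open).
#' @param seed RNG seed for fruit placement and jitter.
#' @export
renderSpec <- function(width = 160L, height = 120L,
                       background_rgb = c(30, 60, 160),
                       n_fruits = 8L, fruit_axes_range = c(8, 16),
                       fruit_jitter_sd = 0,
                       white_patch = NULL, seed = 1L) {
  stopIfNot(width >= 8 && height >= 8, "frame too small")
  stopIfNot(n_fruits >= 0, "`n_fruits` must be >= 0")
  stopIfNot(length(fruit_axes_range) == 2L &&
              fruit_axes_range[1] <= fruit_axes_range[2] &&
              fruit_axes_range[1] >= 1,
            "`fruit_axes_range` must be an increasing pixel range >= 1")
  if (!is.null(white_patch)) {
    stopIfNot(all(c("x", "y", "w", "h") %in% names(white_patch)),
              "`white_patch` needs x, y, w, h")
    white_patch$rgb <- white_patch$rgb %||% c(255, 255, 255)
  }
  structure(list(
    width = as.integer(width), height = as.integer(height),
    background_rgb = as.numeric(background_rgb),
    n_fruits = as.integer(n_fruits),
    fruit_axes_range = as.numeric(fruit_axes_range),
    fruit_jitter_sd = fruit_jitter_sd,
    white_patch = white_patch, seed = as.integer(seed)
  ), class = "RenderSpec")
}

.ellipseMask <- function(h, w, cx, cy, a, b) {
  x <- matrix(rep(seq_len(w), each = h), nrow = h)
  y <- matrix(rep(seq_len(h), times = w), nrow = h)
  ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1
}

.patchMask <- function(h, w, patch) {
  m <- matrix(FALSE, h, w)
  if (is.null(patch)) return(m)
  # 0-based half-open pixel rectangle
  rows <- seq.int(patch$y + 1L, min(h, patch$y + patch$h))
  cols <- seq.int(patch$x + 1L, min(w, patch$x + patch$w))
  m[rows, cols] <- TRUE
  m
}

#' Render one sample as an 8-bit RGB image plus ground-truth fruit mask
#'
#' Fruit are drawn as ellipses filled with the record's channel means plus a
#' per-fruit Gaussian color jitter, on a uniform background with an optional
#' white reference patch. Ellipses are placed fully inside the frame and away
#' from the patch. The returned mask marks exactly the fruit pixels.
#'
#' @param record one row of [generateTrajectory()] output (or any list with
#'   \code{r_mean}, \code{g_mean}, \code{b_mean}).
#' @param spec a [renderSpec()].
#' @return \code{list(image = height x width x 3 array in 0..255,
#'   mask = logical height x width matrix, fruits = data.frame of the drawn
#'   ellipses and their jittered colors — the renderer's ground truth)}.
#' @export
renderSample <- function(record, spec) {
  stopIfNot(inherits(spec, "RenderSpec"), "`spec` must be renderSpec()")
  h <- spec$height; w <- spec$width
  base <- c(record$r_mean, record$g_mean, record$b_mean)
  img <- array(rep(spec$background_rgb, each = h * w), dim = c(h, w, 3))
  patch <- .patchMask(h, w, spec$white_patch)
  if (!is.null(spec$white_patch))
    for (k in 1:3) img[, , k][patch] <- spec$white_patch$rgb[k]
  mask <- matrix(FALSE, h, w)
  fruits <- NULL
  if (spec$n_fruits > 0) {
    fruits <- withLocalSeed(spec$seed, {
      rows <- vector("list", spec$n_fruits)
      for (f in seq_len(spec$n_fruits)) {
        placed <- FALSE
        for (try in 1:200) {
          a <- runif(1, spec$fruit_axes_range[1], spec$fruit_axes_range[2])
          b <- runif(1, spec$fruit_axes_range[1], spec$fruit_axes_range[2])
          if (2 * ceiling(a) + 2 >= w || 2 * ceiling(b) + 2 >= h) next
          cx <- runif(1, a + 1, w - a)
          cy <- runif(1, b + 1, h - b)
          em <- .ellipseMask(h, w, cx, cy, a, b)
          if (any(em & patch)) next
          col <- clamp(base + rnorm(3, 0, spec$fruit_jitter_sd), 0, 255)
          for (k in 1:3) img[, , k][em] <- col[k]
          mask <- mask | em
          rows[[f]] <- data.frame(cx = cx, cy = cy, a = a, b = b,
                                  col_r = col[1], col_g = col[2],
                                  col_b = col[3])
          placed <- TRUE
          break
        }
        if (!placed)
          stop("could not place fruit ", f, " inside the frame", call. = FALSE)
      }
      do.call(rbind, rows)
    })
  }
  img <- roundHalfUp(clamp(img, 0, 255))
  list(image = img, mask = mask, fruits = fruits)
}

#' Generate a full synthetic dataset over several cultivars
#'
#' Concatenates [generateTrajectory()] records for each cultivar parameter
#' set; sample ids are unique across cultivars. Optionally renders each
#' sample to a PNG image with its ground-truth mask and writes a manifest.
#'
#' @param param_sets list of [trajectoryParams()] (distinct cultivar ids).
#' @param n_times,reps_per_time passed to [generateTrajectory()].
#' @param render optional [renderSpec()]; if supplied together with
#'   \code{dir}, images and masks are written under \code{dir}.
#' @param dir output directory for rendered images and the manifest CSV.
#' @return the combined sample data.frame. When rendering, the manifest path
#'   is attached as attribute \code{"manifest"}.
#' @export
generateDataset <- function(param_sets, n_times, reps_per_time = 1L,
                            render = NULL, dir = NULL) {
  stopIfNot(length(param_sets) >= 1L, "need at least one cultivar")
  ids <- vapply(param_sets, function(p) p$cultivar_id, character(1))
  stopIfNot(!anyDuplicated(ids), "duplicate cultivar_id in `param_sets`")
  recs <- do.call(rbind, lapply(param_sets, generateTrajectory,
                                n_times = n_times,
                                reps_per_time = reps_per_time))
  rownames(recs) <- NULL
  if (!is.null(render) && !is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(nrow(recs)); mpaths <- character(nrow(recs))
    for (i in seq_len(nrow(recs))) {
      sp <- render
      sp$seed <- deriveSeed(render$seed, i)
      out <- renderSample(recs[i, ], sp)
      paths[i] <- file.path(dir, paste0(recs$sample_id[i], ".png"))
      mpaths[i] <- file.path(dir, paste0(recs$sample_id[i], "_mask.png"))
      writeImageRGB(out$image, paths[i])
      png::writePNG(out$mask * 1.0, mpaths[i])
    }
    manifest <- data.frame(sample_id = recs$sample_id,
                           image = paths, mask = mpaths,
                           stringsAsFactors = FALSE)
    mf <- file.path(dir, "manifest.csv")
    write.csv(manifest, mf, row.names = FALSE)
    attr(recs, "manifest") <- mf
  }
  recs
}
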