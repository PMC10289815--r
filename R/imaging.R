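#' Read / write an 8-bit RGB image
#'
#' Images are handled as \code{height x width x 3} numeric arrays on the
#' 0..255 scale (origin top-left).
#'
#' @param path PNG (or JPEG for reading is not supported here; fixtures are
#'   PNG so results are bit-stable).
#' @return the image array.
#' @export
readImageRGB <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img[, , 1:3, drop = FALSE] * 255
}

#' @rdname readImageRGB
#' @param image a height x width x 3 array on the 0..255 scale.
#' @export
writeImageRGB <- function(image, path) {
  png::writePNG(clamp(image, 0, 255) / 255, path)
  invisible(path)
}

.checkRGB <- function(image) {
  stopIfNot(is.array(image) && length(dim(image)) == 3L && dim(image)[3] >= 3,
            "`image` must be a height x width x 3 array")
}

.patchIndices <- function(image, patch_region) {
  d <- dim(image)
  x <- patch_region[["x"]]; y <- patch_region[["y"]]
  w <- patch_region[["w"]]; h <- patch_region[["h"]]
  stopIfNot(w >= 1 && h >= 1, "patch region is empty")
  stopIfNot(x >= 0 && y >= 0 && x + w <= d[2] && y + h <= d[1],
            "patch region must lie inside the frame")
  list(rows = seq.int(y + 1L, y + h), cols = seq.int(x + 1L, x + w))
}

#' White-balance gains from a white reference patch
#'
#' Per-channel gain is 255 divided by the channel mean over the patch, so
#' that the corrected patch mean hits white (255, 255, 255) before clipping.
#'
#' @param image height x width x 3 array, 0..255.
#' @param patch_region \code{list(x =, y =, w =, h =)} in pixel coordinates,
#'   0-based, origin top-left, half-open.
#' @return named gains \code{c(gain_r, gain_g, gain_b)} of class
#'   \code{WhiteBalanceGains}.
#' @export
computeWhiteBalance <- function(image, patch_region) {
  .checkRGB(image)
  idx <- .patchIndices(image, patch_region)
  mu <- vapply(1:3, function(k) mean(image[idx$rows, idx$cols, k]), numeric(1))
  if (any(mu == 0))
    stop("degenerate patch: zero mean in at least one channel", call. = FALSE)
  structure(setNames(255 / mu, c("gain_r", "gain_g", "gain_b")),
            class = "WhiteBalanceGains")
}

#' Apply white-balance gains to an image
#'
#' Multiplies each channel by its gain in real arithmetic, clips to 0..255,
#' and rounds half-up to integer pixel values.
#'
#' @inheritParams computeWhiteBalance
#' @param gains a [computeWhiteBalance()] result (or numeric length 3).
#' @export
applyWhiteBalance <- function(image, gains) {
  .checkRGB(image)
  out <- image
  for (k in 1:3) out[, , k] <- image[, , k] * gains[[k]]
  roundHalfUp(clamp(out, 0, 255))
}

# CIELAB b* plane of an sRGB image (D65, 2 degree observer, sRGB gamma).
.bStar <- function(image) {
  d <- dim(image)
  flat <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
                as.vector(image[, , 3])) / 255
  lab <- grDevices::convertColor(flat, from = "sRGB", to = "Lab")
  matrix(lab[, 3], nrow = d[1], ncol = d[2])
}

.otsuThreshold <- function(v) {
  # Otsu on a 256-bin histogram of a continuous signal
  r <- range(v)
  if (diff(r) == 0) return(r[1])
  br <- seq(r[1], r[2], length.out = 257)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins = 256)
  w <- cumsum(h); m <- cumsum(h * seq_len(256))
  wb <- w[-256]; wf <- w[256] - wb
  ok <- wb > 0 & wf > 0
  mb <- m[-256] / wb; mf <- (m[256] - m[-256]) / wf
  between <- wb * wf * (mb - mf)^2
  between[!ok] <- -Inf
  i <- which.max(between)
  (br[i] + br[i + 1]) / 2
}

#' Segment fruit from the blue background via CIELAB b* thresholding
#'
#' Converts the image to CIELAB (D65, 2 degree observer); pixels with
#' b* below the threshold are background (the blue backdrop has strongly
#' negative b*, fruit tissue does not). The optional white patch is forced
#' to background, a morphological opening (disc radius 2) removes speckle,
#' and connected components smaller than \code{min_area_px} are dropped.
#'
#' @inheritParams computeWhiteBalance
#' @param b_star_threshold fixed b* cut (default -15); ignored when
#'   \code{method = "otsu"}, which picks the cut from the b* histogram.
#' @param min_area_px minimum connected-component area kept.
#' @param patch_region optional white-patch rectangle to exclude.
#' @param method \code{"fixed"} threshold or \code{"otsu"} on b*.
#' @return a \code{FruitMask}: \code{list(mask, n_components, area_px)}.
#' @export
segmentFruit <- function(image, b_star_threshold = -15, min_area_px = 50L,
                         patch_region = NULL,
                         method = c("fixed", "otsu")) {
  .checkRGB(image)
  method <- match.arg(method)
  b <- .bStar(image)
  thr <- if (method == "otsu") .otsuThreshold(as.vector(b)) else b_star_threshold
  fg <- b >= thr
  if (!is.null(patch_region)) {
    idx <- .patchIndices(image, patch_region)
    fg[idx$rows, idx$cols] <- FALSE
  }
  opened <- EBImage::opening(EBImage::Image(fg * 1),
                             EBImage::makeBrush(5, shape = "disc"))
  lab <- EBImage::bwlabel(opened)
  labm <- EBImage::imageData(lab)
  if (max(labm) >= 1) {
    areas <- tabulate(labm[labm > 0], nbins = max(labm))
    keep <- which(areas >= min_area_px)
    mask <- matrix(labm %in% keep & labm > 0, nrow = nrow(labm))
    n_comp <- length(keep)
  } else {
    mask <- matrix(FALSE, nrow(labm), ncol(labm))
    n_comp <- 0L
  }
  if (!any(mask))
    stop("no fruit detected: empty mask after filtering", call. = FALSE)
  structure(list(mask = mask, n_components = n_comp, area_px = sum(mask)),
            class = "FruitMask")
}

#' Mean R, G, B pixel values over the fruit mask
#'
#' @inheritParams computeWhiteBalance
#' @param mask a [segmentFruit()] result or a logical matrix.
#' @return named numeric \code{c(r_mean, g_mean, b_mean)}, unrounded.
#' @export
extractChannelMeans <- function(image, mask) {
  .checkRGB(image)
  m <- if (inherits(mask, "FruitMask")) mask$mask else mask
  stopIfNot(is.logical(m) || all(m %in% c(0, 1)), "`mask` must be binary")
  m <- m > 0
  stopIfNot(any(m), "empty mask")
  setNames(vapply(1:3, function(k) mean(image[, , k][m]), numeric(1)),
           c("r_mean", "g_mean", "b_mean"))
}
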