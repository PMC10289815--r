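#' Registry of the 35 RGB colorimetric indexes
#'
#' Fixed names in registry (reading) order. Each index is a scalar function
#' of the mean R, G, B pixel values of a segmented fruit sample.
#'
#' @return character vector of length 35.
#' @export
indexNames <- function() c(
  "R", "G", "B", "NR", "NG", "NB", "GB", "RB", "GR", "BI", "BIM", "SCI",
  "GLI", "HI", "NGRDI", "NDGBI", "NDRBI", "I", "S", "VARI", "HUE", "HUE2",
  "BGI", "L", "GRAY", "GLAI", "CI", "SHP", "RI", "RminB", "RplusB",
  "RplusG", "RminG", "GminB", "BplusG"
)

# Safe ratio: undefined (NA) on a zero denominator rather than Inf/NaN.
.ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Compute the 35 colorimetric indexes from channel means
#'
#' Indexes with a zero denominator are flagged undefined (\code{NA}) rather
#' than raising an error. Two formula dialects are provided:
#' \describe{
#'   \item{\code{interpreted} (default)}{the documented intent of each
#'     index: the \code{30.5} constant appearing in the hue formulas is read
#'     as \eqn{3^{0.5}} (the \eqn{\sqrt 3} of the standard hue definition)
#'     and \code{L = (R+G+B)/3}. \code{BIM}'s \code{(R*2+G*2+B*2)} and
#'     \code{HUE2}'s \code{(R-G-R)} terms have no obvious canonical form and
#'     are kept as printed in both dialects.}
#'   \item{\code{as_printed}}{every formula evaluated exactly as typeset,
#'     including \code{L = R+G+B/3} and a literal \code{/30.5*} (divide by
#'     30.5, then multiply) in the hue formulas.}
#' }
#'
#' @param means channel means: named \code{c(r_mean =, g_mean =, b_mean =)}
#'   or an unnamed numeric length-3 (R, G, B), each in 0..255.
#' @param dialect \code{"interpreted"} or \code{"as_printed"}.
#' @return named numeric vector of length 35 in registry order; undefined
#'   values are \code{NA}.
#' @examples
#' computeIndexes(c(150, 100, 50))[c("NGRDI", "HI", "S")]
#' @export
computeIndexes <- function(means, dialect = c("interpreted", "as_printed")) {
  dialect <- match.arg(dialect)
  v <- unname(unlist(means))[1:3]
  stopIfNot(all(is.finite(v)) && all(v >= 0) && all(v <= 255),
            "channel means must be finite and in [0, 255]")
  R <- v[1]; G <- v[2]; B <- v[3]
  s3 <- sqrt(3)
  out <- c(
    R = R, G = G, B = B,
    NR = .ratio(R, R + G + B),
    NG = .ratio(G, R + G + B),
    NB = .ratio(B, R + G + B),
    GB = .ratio(G, B),
    RB = .ratio(R, B),
    GR = .ratio(G, R),
    BI = sqrt((R^2 + G^2 + B^2) / 3),
    BIM = sqrt((R * 2 + G * 2 + B * 2) / 3),
    SCI = .ratio(R - G, R + G),
    GLI = .ratio(2 * G - R - B, 2 * G + R + B),
    HI = .ratio(2 * R - G - B, G - B),
    NGRDI = .ratio(G - R, G + R),
    NDGBI = .ratio(G - B, G + B),
    NDRBI = .ratio(R - B, R + B),
    I = R + G + B,
    S = .ratio((R + G + B) - 3 * B, R + G + B),
    VARI = .ratio(G - R, G + R - B),
    HUE = if (dialect == "interpreted") {
      d <- s3 * (G - R)
      if (d == 0) NA_real_ else atan(2 * (B - G - R) / d)
    } else atan(2 * (B - G - R) / 30.5 * (G - R)),
    HUE2 = if (dialect == "interpreted") {
      d <- s3 * (G - B)
      if (d == 0) NA_real_ else atan(2 * (R - G - R) / d)
    } else atan(2 * (R - G - R) / 30.5 * (G - B)),
    BGI = .ratio(B, G),
    L = if (dialect == "interpreted") (R + G + B) / 3 else R + G + B / 3,
    GRAY = 0.299 * R + 0.587 * G + 0.114 * B,
    GLAI = {
      d <- G + R - B
      if (d == 0) NA_real_ else 25 * (G - R) / d + 1.25
    },
    CI = .ratio(R - B, R),
    SHP = .ratio(2 * (R - G - B), G - B),
    RI = .ratio(R^2, B * G^3),
    RminB = R - B,
    RplusB = R + B,
    RplusG = R + G,
    RminG = R - G,
    GminB = G - B,
    BplusG = B + G
  )
  out[indexNames()]
}

#' Build the colorimetric feature set for a sample table
#'
#' Computes the 35 indexes for every sample and assembles an
#' \linkS4class{OliveIndexSet} (a SummarizedExperiment with the index matrix
#' as assay and the sample table as colData). Undefined values are counted
#' per index and recorded in the metadata; imputation is deferred to
#' modelling time, where the training-set column median is used.
#'
#' @param samples data.frame with columns \code{r_mean}, \code{g_mean},
#'   \code{b_mean} (plus any metadata such as \code{sample_id},
#'   \code{cultivar}, \code{t}, \code{oil}, \code{phenols}).
#' @param dialect passed to [computeIndexes()].
#' @return an [OliveIndexSet-class] with samples as columns.
#' @export
buildFeatureTable <- function(samples, dialect = c("interpreted", "as_printed")) {
  dialect <- match.arg(dialect)
  need <- c("r_mean", "g_mean", "b_mean")
  if (!all(need %in% colnames(samples)))
    stop("`samples` must have columns r_mean, g_mean, b_mean", call. = FALSE)
  n <- nrow(samples)
  mat <- vapply(seq_len(n), function(i)
    computeIndexes(c(samples$r_mean[i], samples$g_mean[i], samples$b_mean[i]),
                   dialect = dialect),
    numeric(35))
  mat <- matrix(mat, nrow = 35,
                dimnames = list(indexNames(),
                                samples$sample_id %||% as.character(seq_len(n))))
  ud <- rowSums(is.na(mat))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(indexes = mat),
    colData = S4Vectors::DataFrame(samples)
  )
  S4Vectors::metadata(se)$dialect <- dialect
  S4Vectors::metadata(se)$undefined_counts <- ud
  methods::as(se, "OliveIndexSet")
}

#' @rdname buildFeatureTable
#' @param x an \code{OliveIndexSet}
#' @return \code{indexMatrix}: samples x 35 feature matrix.
#' @export
indexMatrix <- function(x) {
  stopIfNot(is(x, "OliveIndexSet"), "`x` must be an OliveIndexSet")
  t(SummarizedExperiment::assay(x, "indexes"))
}

#' @rdname buildFeatureTable
#' @return \code{undefinedCounts}: named per-index count of undefined values.
#' @export
undefinedCounts <- function(x) {
  stopIfNot(is(x, "OliveIndexSet"), "`x` must be an OliveIndexSet")
  S4Vectors::metadata(x)$undefined_counts
}
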