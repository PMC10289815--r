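#' Reference tables from the olive field study
#'
#' Two small plain-text tables reported by the field study on three olive
#' cultivars that this package's pipeline mirrors: the PCA and sparse-PCA
#' loadings of the 35 colorimetric indexes, and the per-cultivar GPI values
#' and ranks of the three network variants. They serve as worked examples
#' for the variable-selection filter ([selectVariables()]) and the ranking
#' rule ([rankByGPI()]).
#'
#' @return \code{referenceLoadings()}: data.frame with columns \code{index},
#'   \code{PC1}, \code{PC2}, \code{SPC1}, \code{SPC2} (35 rows, registry
#'   order). \code{referenceGPI()}: data.frame with columns \code{cultivar},
#'   \code{trait}, \code{model}, \code{gpi}, \code{rank}.
#' @export
referenceLoadings <- function() {
  read.csv(system.file("extdata", "reference_loadings.csv",
                       package = "OlivePhen"),
           stringsAsFactors = FALSE)
}

#' @rdname referenceLoadings
#' @export
referenceGPI <- function() {
  read.csv(system.file("extdata", "reference_gpi.csv",
                       package = "OlivePhen"),
           stringsAsFactors = FALSE)
}
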