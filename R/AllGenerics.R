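#' @rdname associationMatrix
#' @export
setGeneric("associationMatrix", function(x) standardGeneric("associationMatrix"))

#' @rdname diseaseNames
#' @export
setGeneric("diseaseNames", function(x) standardGeneric("diseaseNames"))

#' @rdname diseaseNames
#' @export
setGeneric("microbeNames", function(x) standardGeneric("microbeNames"))

#' Per-vertex node weights
#'
#' For a [GipKernel-class], computes the node weight of each microbe as the
#' sum of its row of the similarity matrix (including the unit
#' self-similarity term). For a [WeightedHypergraph-class], returns the
#' stored weights.
#'
#' @param x a \code{GipKernel} or \code{WeightedHypergraph}.
#' @param ... further arguments; for \code{GipKernel},
#'   \code{includeSelf = TRUE} controls whether the diagonal term is kept
#'   in the row sum.
#' @return named numeric vector of positive weights, one per microbe.
#' @examples
#' A <- buildAdjacency(exampleCatalog())
#' nodeWeights(gipKernel(A))
#' @export
setGeneric("nodeWeights", function(x, ...) standardGeneric("nodeWeights"))

#' @rdname similarityMatrix
#' @export
setGeneric("similarityMatrix", function(x) standardGeneric("similarityMatrix"))

#' @rdname incidenceMatrix
#' @export
setGeneric("incidenceMatrix", function(x) standardGeneric("incidenceMatrix"))

#' @rdname transitionMatrix
#' @export
setGeneric("transitionMatrix", function(x) standardGeneric("transitionMatrix"))

#' @rdname stationaryScores
#' @export
setGeneric("stationaryScores", function(x) standardGeneric("stationaryScores"))

#' @rdname loocvAuc
#' @export
setGeneric("loocvAuc", function(x) standardGeneric("loocvAuc"))

#' @rdname loocvAuc
#' @export
setGeneric("loocvFolds", function(x) standardGeneric("loocvFolds"))
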