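#' Squared norms of microbe interaction profiles
#'
#' The interaction profile of microbe \code{j} is column \code{j} of the
#' binary adjacency matrix; for a binary profile the squared Euclidean norm
#' equals the number of diseases the microbe is associated with.
#'
#' @param x a [BipartiteAssociations-class].
#' @return named numeric vector of per-microbe association counts.
#' @export
profileNorms <- function(x) {
    stopifnot(is(x, "BipartiteAssociations"))
    colSums(x@adjacency)
}

#' Gaussian interaction profile kernel bandwidth
#'
#' The bandwidth is \eqn{r = r' / (\frac{1}{nm}\sum_j \|IP_j\|^2)}: the
#' normalisation constant divided by the mean squared profile norm (the
#' average number of known associations per microbe).
#'
#' @param x a [BipartiteAssociations-class].
#' @param rPrime positive normalisation constant, default 1.
#' @return numeric(1), the bandwidth \eqn{r}.
#' @export
gipBandwidth <- function(x, rPrime = 1) {
    stopifnot(is(x, "BipartiteAssociations"),
              is.numeric(rPrime), length(rPrime) == 1L, rPrime > 0)
    meanNorm <- mean(profileNorms(x))
    if (meanNorm == 0)
        stop("bandwidth undefined: adjacency matrix has no associations",
             call. = FALSE)
    rPrime / meanNorm
}

#' Gaussian interaction profile kernel similarity for microbes
#'
#' Computes \eqn{GM(i,j) = \exp(-r \|IP_i - IP_j\|^2)} over the binary
#' disease-association profiles of all microbes. Each unordered pair is
#' computed once, so the matrix is exactly symmetric; the diagonal is
#' exactly 1. Microbes with all-zero profiles are retained and handled by
#' the same formula. The matrix is kept dense and unthresholded.
#'
#' @param x a [BipartiteAssociations-class].
#' @param rPrime positive bandwidth normalisation constant, default 1.
#' @return a [GipKernel-class].
#' @examples
#' A <- bipartiteAssociations(matrix(c(1, 1, 0, 1), 2,
#'                            dimnames = list(c("d1", "d2"), c("m1", "m2"))))
#' similarityMatrix(gipKernel(A))  # off-diagonal exp(-2/3)
#' @export
gipKernel <- function(x, rPrime = 1) {
    stopifnot(is(x, "BipartiteAssociations"))
    r <- gipBandwidth(x, rPrime)
    A <- x@adjacency
    nm <- ncol(A)
    # squared distance between binary columns: ||a||^2 + ||b||^2 - 2 a.b
    norms <- colSums(A)
    cross <- crossprod(A)
    d2 <- outer(norms, norms, "+") - 2 * cross
    GM <- exp(-r * d2)
    GM[upper.tri(GM)] <- t(GM)[upper.tri(GM)]  # exact symmetry
    diag(GM) <- 1
    dimnames(GM) <- list(colnames(A), colnames(A))
    new("GipKernel", similarity = GM, rPrime = rPrime, bandwidth = r)
}

#' @describeIn similarityMatrix the microbe-by-microbe similarity matrix.
#' @export
setMethod("similarityMatrix", "GipKernel", function(x) x@similarity)

#' Similarity matrix accessor
#'
#' @param x a [GipKernel-class].
#' @return numeric symmetric matrix with unit diagonal.
#' @name similarityMatrix
NULL

#' @describeIn nodeWeights row sums of the similarity matrix;
#'   \code{includeSelf = FALSE} drops the diagonal term from each sum.
#' @param includeSelf logical(1), keep the self-similarity term (default
#'   \code{TRUE}).
#' @export
setMethod("nodeWeights", "GipKernel", function(x, includeSelf = TRUE) {
    w <- rowSums(x@similarity)
    if (!includeSelf)
        w <- w - diag(x@similarity)
    w
})

setMethod("show", "GipKernel", function(object) {
    cat("GipKernel over", nrow(object@similarity), "microbe(s)\n")
    cat(sprintf("  rPrime = %g, bandwidth r = %.6g\n",
                object@rPrime, object@bandwidth))
    off <- object@similarity[lower.tri(object@similarity)]
    if (length(off))
        cat(sprintf("  off-diagonal range: [%.4g, %.4g]\n",
                    min(off), max(off)))
})
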