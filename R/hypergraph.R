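#' Build the hypergraph incidence structure
#'
#' Vertices are microbes and hyperedges are diseases, so the incidence
#' matrix is the transpose of the disease-by-microbe adjacency:
#' \code{H[v, e] = A[e, v]}. Vertex degrees (incident hyperedges per
#' microbe) and hyperedge degrees (member microbes per disease) are the row
#' and column sums. Empty hyperedges (diseases with no associations, which
#' can arise in cross-validation folds) are kept here and flagged with a
#' warning; they are dropped at the weighting stage.
#'
#' @param x a [BipartiteAssociations-class].
#' @return a [HypergraphIncidence-class].
#' @export
buildIncidence <- function(x) {
    stopifnot(is(x, "BipartiteAssociations"))
    H <- t(x@adjacency)
    delta <- colSums(H)
    if (any(delta == 0))
        warning("hypergraph has ", sum(delta == 0), " empty hyperedge(s): ",
                paste(colnames(H)[delta == 0], collapse = ", "),
                call. = FALSE)
    new("HypergraphIncidence", incidence = H,
        vertexDegree = unname(rowSums(H)), edgeDegree = unname(delta))
}

#' Attach node weights and build the weighted incidence
#'
#' Each vertex carries one positive weight (the same value in every
#' incident hyperedge); the weighted incidence is
#' \code{W[v, e] = weight(v) * H[v, e]}, the weighted hyperedge degree is
#' the column sum of \code{W}, and hyperedge weights are uniform
#' \code{1/|E|}. Empty hyperedges are removed before weighting so every
#' retained hyperedge has a strictly positive weighted degree.
#'
#' @param incidence a [HypergraphIncidence-class].
#' @param weights numeric vector of strictly positive per-vertex weights
#'   (typically [nodeWeights()] of the GIP kernel).
#' @return a [WeightedHypergraph-class].
#' @export
buildWeightedIncidence <- function(incidence, weights) {
    stopifnot(is(incidence, "HypergraphIncidence"))
    H <- incidence@incidence
    weights <- unname(weights)
    if (length(weights) != nrow(H))
        stop("need one weight per vertex (", nrow(H), "), got ",
             length(weights), call. = FALSE)
    if (any(!is.finite(weights)) || any(weights <= 0))
        stop("node weights must be strictly positive and finite",
             call. = FALSE)
    keep <- incidence@edgeDegree > 0
    if (!all(keep)) {
        H <- H[, keep, drop = FALSE]
        incidence <- new("HypergraphIncidence", incidence = H,
                         vertexDegree = unname(rowSums(H)),
                         edgeDegree = unname(colSums(H)))
    }
    nE <- ncol(H)
    if (nE == 0L)
        stop("hypergraph has no nonempty hyperedges", call. = FALSE)
    W <- H * weights
    new("WeightedHypergraph", incidence = incidence, nodeWeight = weights,
        weightedIncidence = W, weightedEdgeDegree = unname(colSums(W)),
        edgeWeight = rep(1 / nE, nE))
}

#' Transition matrix of the two-step hypergraph walk
#'
#' From vertex \code{u} the walker (1) picks a hyperedge among those
#' incident to \code{u}, with probability proportional to the hyperedge
#' weight (uniform over incident hyperedges here, since all hyperedge
#' weights are equal), then (2) picks a destination vertex within that
#' hyperedge with probability proportional to its node weight, i.e.
#' \code{W[v, e] / delta'(e)}. Summing over hyperedges gives
#' \deqn{P(u,v) = \sum_{e} \frac{w(e)\,h(u,e)}{\sum_{\hat e} w(\hat e)\,
#'   h(u,\hat e)} \cdot \frac{W(v,e)}{\delta'(e)}.}
#'
#' Normalising the hyperedge choice over the hyperedges incident to
#' \code{u} makes every non-dangling row sum to exactly 1. The alternative
#' \code{normalization = "printed"} uses the plain product form
#' \eqn{D_v^{-1} H W_e D_{ve}^{-1} W^T}, whose hyperedge choice is
#' normalised over \emph{all} hyperedges; with uniform weights its rows sum
#' to \eqn{1/|E|}, so it is retained only for comparison and is not
#' row-stochastic.
#'
#' Dangling vertices (degree 0, e.g. microbes losing their only
#' association in a cross-validation fold) get a uniform row over all
#' vertices (\code{dangling = "uniform"}, default) or a self-loop
#' (\code{dangling = "self_loop"}).
#'
#' @param hg a [WeightedHypergraph-class].
#' @param dangling policy for zero-degree vertex rows.
#' @param normalization \code{"incident"} (default, row-stochastic) or
#'   \code{"printed"}.
#' @return a [TransitionMatrix-class].
#' @examples
#' ex <- exampleHypergraph()   # V = {a,b,c}, E = {{a,b},{b,c}}, w = (1,2,1)
#' transitionMatrix(buildTransition(ex))
#' @export
buildTransition <- function(hg, dangling = c("uniform", "self_loop"),
                            normalization = c("incident", "printed")) {
    stopifnot(is(hg, "WeightedHypergraph"))
    dangling <- match.arg(dangling)
    normalization <- match.arg(normalization)
    H <- hg@incidence@incidence
    nV <- nrow(H)
    if (nV == 0L)
        stop("hypergraph has no vertices", call. = FALSE)
    we <- hg@edgeWeight
    # member-vertex choice within each hyperedge: W[v,e] / delta'(e)
    inEdge <- sweep(hg@weightedIncidence, 2L, hg@weightedEdgeDegree, "/")
    # hyperedge-choice mass per row
    rowMass <- drop(H %*% we)
    danglingIdx <- which(rowMass == 0)
    num <- H %*% (we * t(inEdge))  # sum_e w(e) h(u,e) inEdge[v,e]
    P <- if (normalization == "incident") {
        safe <- ifelse(rowMass > 0, rowMass, 1)
        num / safe
    } else {
        # printed product form: divide by d(u) with full-sum edge weights
        d <- hg@incidence@vertexDegree
        num / ifelse(d > 0, d, 1)
    }
    P <- as.matrix(P)
    if (length(danglingIdx)) {
        fill <- if (dangling == "uniform") {
            matrix(1 / nV, length(danglingIdx), nV)
        } else {
            diag(nV)[danglingIdx, , drop = FALSE]
        }
        P[danglingIdx, ] <- fill
    }
    dimnames(P) <- list(rownames(H), rownames(H))
    new("TransitionMatrix", matrix = P, danglingPolicy = dangling,
        danglingVertices = as.integer(danglingIdx),
        normalization = normalization)
}

#' Worked three-vertex hypergraph
#'
#' The small instance used in documentation and tests: vertices a, b, c,
#' hyperedges \{a, b\} and \{b, c\}, node weights (1, 2, 1), uniform
#' hyperedge weights.
#'
#' @return a [WeightedHypergraph-class].
#' @export
exampleHypergraph <- function() {
    H <- matrix(c(1, 1, 0,
                  0, 1, 1), nrow = 3,
                dimnames = list(c("a", "b", "c"), c("e1", "e2")))
    inc <- new("HypergraphIncidence", incidence = H,
               vertexDegree = unname(rowSums(H)),
               edgeDegree = unname(colSums(H)))
    buildWeightedIncidence(inc, c(1, 2, 1))
}

#' @describeIn incidenceMatrix binary vertex-by-hyperedge incidence.
#' @export
setMethod("incidenceMatrix", "HypergraphIncidence",
          function(x) x@incidence)

#' @describeIn incidenceMatrix incidence of the underlying unweighted
#'   structure.
#' @export
setMethod("incidenceMatrix", "WeightedHypergraph",
          function(x) x@incidence@incidence)

#' Incidence matrix accessor
#'
#' @param x a [HypergraphIncidence-class] or [WeightedHypergraph-class].
#' @name incidenceMatrix
NULL

#' @describeIn nodeWeights stored per-vertex weights.
#' @export
setMethod("nodeWeights", "WeightedHypergraph", function(x) {
    stats::setNames(x@nodeWeight, rownames(x@incidence@incidence))
})

#' @describeIn transitionMatrix the row-stochastic matrix itself.
#' @export
setMethod("transitionMatrix", "TransitionMatrix", function(x) x@matrix)

#' Transition matrix accessor
#'
#' @param x a [TransitionMatrix-class].
#' @name transitionMatrix
NULL

setMethod("show", "HypergraphIncidence", function(object) {
    cat("HypergraphIncidence:", nrow(object@incidence), "vertex(es) x",
        ncol(object@incidence), "hyperedge(s)\n")
    cat("  vertex degree range:", min(object@vertexDegree), "-",
        max(object@vertexDegree), "\n")
})

setMethod("show", "WeightedHypergraph", function(object) {
    H <- object@incidence@incidence
    cat("WeightedHypergraph:", nrow(H), "vertex(es),", ncol(H),
        "hyperedge(s), uniform edge weight", format(object@edgeWeight[1]),
        "\n")
})

setMethod("show", "TransitionMatrix", function(object) {
    cat("TransitionMatrix over", nrow(object@matrix), "vertex(es)",
        sprintf("(%s normalization)\n", object@normalization))
    if (length(object@danglingVertices))
        cat("  dangling rows:", length(object@danglingVertices),
            sprintf("(policy '%s')\n", object@danglingPolicy))
})
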