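#' Random walk with restart control parameters
#'
#' @param alpha restart probability, in (0, 1]; default 0.2. The value 1
#'   is admitted as the degenerate restart-only limit (the stationary state
#'   is then the initial distribution itself).
#' @param tol L1 convergence threshold between successive iterates,
#'   default 1e-6.
#' @param maxIter iteration safeguard, default 1000; non-convergence within
#'   \code{maxIter} is flagged on the result, never silent.
#' @param emptySeedPolicy what to do when a disease has no seed microbes
#'   (possible after leaving out its only association): \code{"uniform"}
#'   (default) starts the walk from the uniform distribution and flags the
#'   result; \code{"error"} stops.
#' @return a validated list of class \code{walkControl}.
#' @export
walkControl <- function(alpha = 0.2, tol = 1e-6, maxIter = 1000L,
                        emptySeedPolicy = c("uniform", "error")) {
    emptySeedPolicy <- match.arg(emptySeedPolicy)
    stopifnot(is.numeric(alpha), length(alpha) == 1L,
              alpha > 0, alpha <= 1,
              is.numeric(tol), length(tol) == 1L, tol > 0,
              length(maxIter) == 1L, maxIter >= 1)
    structure(list(alpha = alpha, tol = tol,
                   maxIter = as.integer(maxIter),
                   emptySeedPolicy = emptySeedPolicy),
              class = "walkControl")
}

#' Initial probability distribution over vertices
#'
#' Uniform probability \code{1/|seeds|} on the seed vertices and zero
#' elsewhere. An empty seed set falls back to the control's empty-seed
#' policy (default: uniform over all vertices, with an attribute flagging
#' the fallback).
#'
#' @param seeds integer or logical index vector of seed vertices (may be
#'   empty).
#' @param nVertices total number of vertices, at least 1.
#' @param emptySeedPolicy \code{"uniform"} or \code{"error"}.
#' @return numeric probability vector of length \code{nVertices}; attribute
#'   \code{emptySeedFallback} is TRUE when the fallback was applied.
#' @export
initialDistribution <- function(seeds, nVertices,
                                emptySeedPolicy = c("uniform", "error")) {
    emptySeedPolicy <- match.arg(emptySeedPolicy)
    stopifnot(nVertices >= 1L)
    if (is.logical(seeds))
        seeds <- which(seeds)
    v0 <- numeric(nVertices)
    if (length(seeds) == 0L) {
        if (emptySeedPolicy == "error")
            stop("empty seed set", call. = FALSE)
        v0[] <- 1 / nVertices
        attr(v0, "emptySeedFallback") <- TRUE
    } else {
        v0[seeds] <- 1 / length(seeds)
        attr(v0, "emptySeedFallback") <- FALSE
    }
    v0
}

#' One restart-iteration step
#'
#' Computes \eqn{(1-\alpha) P^T v + \alpha v_0}.
#'
#' @param P a [TransitionMatrix-class] or a plain square matrix.
#' @param v,v0 probability vectors over vertices.
#' @param alpha restart probability.
#' @return the next probability vector.
#' @export
rwrStep <- function(P, v, v0, alpha) {
    Pm <- if (is(P, "TransitionMatrix")) P@matrix else P
    if (length(v) != nrow(Pm) || length(v0) != nrow(Pm))
        stop("dimension mismatch between P and the probability vectors",
             call. = FALSE)
    drop((1 - alpha) * crossprod(Pm, v)) + alpha * v0
}

#' Iterate the random walk with restart to its stationary state
#'
#' Repeats \eqn{v \leftarrow (1-\alpha) P^T v + \alpha v_0} until the L1
#' change between successive iterates falls below \code{control$tol}, or
#' \code{control$maxIter} is reached (flagged, not silent). The iteration
#' is a contraction with factor \eqn{1-\alpha} in L1, so convergence is
#' geometric.
#'
#' @param P a [TransitionMatrix-class].
#' @param v0 normalized initial distribution (see [initialDistribution()]).
#' @param control a [walkControl()] list.
#' @param disease optional disease label recorded on the result.
#' @param seeds optional character vector of seed labels recorded on the
#'   result.
#' @return a [StationaryScores-class].
#' @export
rwrIterate <- function(P, v0, control = walkControl(),
                       disease = NA_character_, seeds = character()) {
    stopifnot(is(P, "TransitionMatrix"))
    Pm <- P@matrix
    alpha <- control$alpha
    v <- v0 <- as.numeric(v0)
    tPm <- t(Pm)
    converged <- FALSE
    delta <- Inf
    iter <- 0L
    while (iter < control$maxIter) {
        vNew <- drop((1 - alpha) * (tPm %*% v)) + alpha * v0
        delta <- sum(abs(vNew - v))
        v <- vNew
        iter <- iter + 1L
        if (delta < control$tol) {
            converged <- TRUE
            break
        }
    }
    if (!converged)
        warning("random walk did not converge within ", control$maxIter,
                " iterations (last L1 change ", format(delta), ")",
                call. = FALSE)
    resid <- sum(abs(v - (drop((1 - alpha) * (tPm %*% v)) + alpha * v0)))
    new("StationaryScores",
        scores = stats::setNames(v / sum(v), rownames(Pm)),
        disease = disease, seeds = seeds, iterations = iter,
        converged = converged, l1Delta = delta, residual = resid)
}

#' Solve the restart fixed point directly
#'
#' The stationary state satisfies \eqn{(I - (1-\alpha) P^T) v = \alpha v_0},
#' a nonsingular linear system for \eqn{\alpha \in (0, 1]} and stochastic
#' \eqn{P}; this dense solve is the exact counterpart of [rwrIterate()] and
#' serves as its independent cross-check.
#'
#' @inheritParams rwrIterate
#' @param alpha restart probability in (0, 1].
#' @return a [StationaryScores-class] with \code{iterations = 0}.
#' @export
rwrSolveDirect <- function(P, v0, alpha = 0.2, disease = NA_character_,
                           seeds = character()) {
    stopifnot(is(P, "TransitionMatrix"), alpha > 0, alpha <= 1)
    Pm <- P@matrix
    n <- nrow(Pm)
    v <- solve(diag(n) - (1 - alpha) * t(Pm), alpha * as.numeric(v0))
    stopifnot(abs(sum(v) - 1) < 1e-10)
    new("StationaryScores",
        scores = stats::setNames(v / sum(v), rownames(Pm)),
        disease = disease, seeds = seeds, iterations = 0L,
        converged = TRUE, l1Delta = 0,
        residual = 0)
}

#' Score all microbes for one disease
#'
#' Runs the full pipeline for a single disease: GIP kernel on the
#' adjacency, node weights as kernel row sums, weighted hypergraph and
#' transition matrix, then the random walk with restart seeded uniformly on
#' the disease's known microbes. Returns the stationary probability of
#' every microbe.
#'
#' @param x a [BipartiteAssociations-class].
#' @param disease disease label present in \code{diseaseNames(x)}.
#' @param control a [walkControl()] list.
#' @param rPrime GIP bandwidth normalisation constant.
#' @param dangling dangling-vertex policy passed to [buildTransition()].
#' @return a [StationaryScores-class].
#' @examples
#' A <- buildAdjacency(exampleCatalog())
#' stationaryScores(scoreDisease(A, "d1"))
#' @export
scoreDisease <- function(x, disease, control = walkControl(), rPrime = 1,
                         dangling = "uniform") {
    stopifnot(is(x, "BipartiteAssociations"))
    if (!disease %in% diseaseNames(x))
        stop("unknown disease label: ", disease, call. = FALSE)
    P <- transitionFromAssociations(x, rPrime = rPrime, dangling = dangling)
    walkOneDisease(x, disease, P, control)
}

# kernel -> weights -> weighted hypergraph -> transition, shared by the
# per-disease scorer and the LOOCV loops (P does not depend on the disease).
transitionFromAssociations <- function(x, rPrime = 1, dangling = "uniform") {
    GM <- gipKernel(x, rPrime)
    inc <- withCallingHandlers(buildIncidence(x),
        warning = function(w) invokeRestart("muffleWarning"))
    hg <- buildWeightedIncidence(inc, nodeWeights(GM))
    buildTransition(hg, dangling = dangling)
}

walkOneDisease <- function(x, disease, P, control) {
    seedsIdx <- which(x@adjacency[disease, ] == 1)
    v0 <- initialDistribution(seedsIdx, ncol(x@adjacency),
                              control$emptySeedPolicy)
    res <- rwrIterate(P, as.numeric(v0), control, disease = disease,
                      seeds = microbeNames(x)[seedsIdx])
    attr(res, "emptySeedFallback") <- attr(v0, "emptySeedFallback")
    res
}

#' Rank candidate microbes by stationary score
#'
#' Candidates are the microbes outside the known (seed) set, sorted by
#' score in decreasing order. Tied scores share their midrank and are
#' flagged.
#'
#' @param scores a [StationaryScores-class].
#' @param known character vector or index of known (excluded) microbes;
#'   defaults to the seed set recorded on \code{scores}.
#' @return data.frame with columns \code{disease}, \code{microbe},
#'   \code{score}, \code{rank}, \code{tied}, ordered by increasing rank.
#' @export
rankCandidates <- function(scores, known = scores@seeds) {
    stopifnot(is(scores, "StationaryScores"))
    s <- scores@scores
    if (is.character(known)) {
        cand <- s[setdiff(names(s), known)]
    } else {
        cand <- if (length(known)) s[-known] else s
    }
    if (length(cand) == 0L)
        return(data.frame(disease = character(), microbe = character(),
                          score = numeric(), rank = numeric(),
                          tied = logical(), stringsAsFactors = FALSE))
    # midrank on descending scores; ties flagged
    rk <- rank(-cand, ties.method = "average")
    ord <- order(rk, names(cand), method = "radix")
    tied <- duplicated(cand) | duplicated(cand, fromLast = TRUE)
    data.frame(disease = scores@disease, microbe = names(cand)[ord],
               score = unname(cand[ord]), rank = unname(rk[ord]),
               tied = unname(tied[ord]), stringsAsFactors = FALSE,
               row.names = NULL)
}

#' @describeIn stationaryScores named stationary probability vector.
#' @export
setMethod("stationaryScores", "StationaryScores", function(x) x@scores)

#' Stationary score accessor
#'
#' @param x a [StationaryScores-class].
#' @name stationaryScores
NULL

setMethod("show", "StationaryScores", function(object) {
    cat("StationaryScores over", length(object@scores), "vertex(es)")
    if (!is.na(object@disease))
        cat(" for disease", sQuote(object@disease))
    cat("\n  ", if (object@converged) "converged" else "NOT converged",
        "after", object@iterations, "iteration(s), residual",
        format(object@residual, digits = 3), "\n")
})
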