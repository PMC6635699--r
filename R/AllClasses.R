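#' @import methods
NULL

#' Catalog of disease-microbe association records
#'
#' An ordered collection of (disease, microbe) association records as read
#' from a delimited text table, before or after deduplication. Records keep
#' their input order; labels are whitespace-trimmed on ingestion.
#'
#' @slot records data.frame with character columns \code{disease} and
#'   \code{microbe} and an optional \code{note} column.
#' @slot provenance character(1), free-text description of the data source.
#' @slot deduplicated logical(1), whether exact duplicate pairs were removed.
#'
#' @seealso [readAssociationCatalog()], [deduplicateCatalog()],
#'   [buildAdjacency()]
#' @export
setClass("AssociationCatalog",
    representation(
        records = "data.frame",
        provenance = "character",
        deduplicated = "logical"
    ),
    prototype(
        records = data.frame(disease = character(), microbe = character(),
                             stringsAsFactors = FALSE),
        provenance = "unspecified",
        deduplicated = FALSE
    )
)

setValidity("AssociationCatalog", function(object) {
    rec <- object@records
    msgs <- character()
    if (!all(c("disease", "microbe") %in% names(rec)))
        msgs <- c(msgs, "'records' must have columns 'disease' and 'microbe'")
    else {
        if (!is.character(rec$disease) || !is.character(rec$microbe))
            msgs <- c(msgs, "'disease' and 'microbe' columns must be character")
        else if (any(!nzchar(trimws(rec$disease))) ||
                 any(!nzchar(trimws(rec$microbe))))
            msgs <- c(msgs, "labels must be non-empty after trimming")
        if (isTRUE(object@deduplicated) &&
            anyDuplicated(rec[, c("disease", "microbe")]) > 0L)
            msgs <- c(msgs, "catalog flagged deduplicated but contains duplicates")
    }
    if (length(object@provenance) != 1L)
        msgs <- c(msgs, "'provenance' must be a single string")
    if (length(msgs)) msgs else TRUE
})

#' Binary disease-by-microbe association matrix
#'
#' The bipartite association structure as a binary adjacency matrix with
#' diseases as rows and microbes as columns. Row and column names carry the
#' disease and microbe labels; order is fixed by lexicographic sort so every
#' downstream matrix is reproducible.
#'
#' @slot adjacency numeric matrix of 0/1 entries, diseases x microbes,
#'   with dimnames.
#'
#' @seealso [buildAdjacency()], [gipKernel()], [buildIncidence()]
#' @export
setClass("BipartiteAssociations",
    representation(adjacency = "matrix")
)

setValidity("BipartiteAssociations", function(object) {
    A <- object@adjacency
    msgs <- character()
    if (!is.numeric(A))
        msgs <- c(msgs, "'adjacency' must be numeric")
    if (nrow(A) < 1L || ncol(A) < 1L)
        msgs <- c(msgs, "'adjacency' must have at least one row and column")
    if (is.numeric(A) && !all(A %in% c(0, 1)))
        msgs <- c(msgs, "'adjacency' entries must all be 0 or 1")
    if (is.null(rownames(A)) || is.null(colnames(A)))
        msgs <- c(msgs, "'adjacency' must carry disease rownames and microbe colnames")
    else {
        if (anyDuplicated(rownames(A)))
            msgs <- c(msgs, "disease labels must be unique")
        if (anyDuplicated(colnames(A)))
            msgs <- c(msgs, "microbe labels must be unique")
    }
    if (length(msgs)) msgs else TRUE
})

#' Gaussian interaction profile kernel for microbes
#'
#' Symmetric microbe-by-microbe similarity matrix
#' \eqn{GM(i,j) = \exp(-r \|IP_i - IP_j\|^2)} over binary disease-association
#' profiles, with unit diagonal. The bandwidth \eqn{r} is the normalisation
#' constant \eqn{r'} divided by the mean squared profile norm.
#'
#' @slot similarity numeric matrix, microbes x microbes, symmetric with
#'   unit diagonal.
#' @slot rPrime numeric(1), the bandwidth normalisation constant (default 1).
#' @slot bandwidth numeric(1), the realised bandwidth \eqn{r}.
#'
#' @seealso [gipKernel()], [gipBandwidth()], [nodeWeights()]
#' @export
setClass("GipKernel",
    representation(
        similarity = "matrix",
        rPrime = "numeric",
        bandwidth = "numeric"
    )
)

setValidity("GipKernel", function(object) {
    GM <- object@similarity
    msgs <- character()
    if (nrow(GM) != ncol(GM))
        msgs <- c(msgs, "'similarity' must be square")
    else {
        if (!isTRUE(all.equal(GM, t(GM), tolerance = 0)))
            msgs <- c(msgs, "'similarity' must be exactly symmetric")
        if (any(abs(diag(GM) - 1) > 0))
            msgs <- c(msgs, "diagonal of 'similarity' must be exactly 1")
        if (any(GM <= 0) || any(GM > 1))
            msgs <- c(msgs, "entries must lie in (0, 1]")
    }
    if (length(object@rPrime) != 1L || object@rPrime <= 0)
        msgs <- c(msgs, "'rPrime' must be a single positive number")
    if (length(object@bandwidth) != 1L || object@bandwidth <= 0)
        msgs <- c(msgs, "'bandwidth' must be a single positive number")
    if (length(msgs)) msgs else TRUE
})

#' Unweighted hypergraph incidence structure
#'
#' Incidence matrix of the hypergraph whose vertices are microbes and whose
#' hyperedges are diseases: \code{H[v, e] = 1} iff microbe \code{v} is
#' associated with disease \code{e}. Vertex degree \code{d(v)} counts
#' incident hyperedges; hyperedge degree \code{delta(e)} counts member
#' vertices. The diagonal hyperedge-degree matrix is retained for
#' completeness although the weighted transition formula does not use it.
#'
#' @slot incidence numeric 0/1 matrix, vertices (microbes) x hyperedges
#'   (diseases).
#' @slot vertexDegree numeric vector, row sums of \code{incidence}.
#' @slot edgeDegree numeric vector, column sums of \code{incidence}.
#'
#' @seealso [buildIncidence()], [buildWeightedIncidence()]
#' @export
setClass("HypergraphIncidence",
    representation(
        incidence = "matrix",
        vertexDegree = "numeric",
        edgeDegree = "numeric"
    )
)

setValidity("HypergraphIncidence", function(object) {
    H <- object@incidence
    msgs <- character()
    if (!all(H %in% c(0, 1)))
        msgs <- c(msgs, "'incidence' entries must all be 0 or 1")
    if (length(object@vertexDegree) != nrow(H) ||
        !isTRUE(all.equal(object@vertexDegree, unname(rowSums(H)))))
        msgs <- c(msgs, "'vertexDegree' must equal the row sums of 'incidence'")
    if (length(object@edgeDegree) != ncol(H) ||
        !isTRUE(all.equal(object@edgeDegree, unname(colSums(H)))))
        msgs <- c(msgs, "'edgeDegree' must equal the column sums of 'incidence'")
    if (length(msgs)) msgs else TRUE
})

#' Vertex-weighted hypergraph
#'
#' Hypergraph with positive per-vertex weights (a vertex carries the same
#' weight in every hyperedge it belongs to), the weighted incidence matrix
#' \code{W[v, e] = weight(v) * H[v, e]}, weighted hyperedge degrees
#' (column sums of \code{W}), and uniform hyperedge weights \code{1/|E|}.
#' Empty hyperedges are dropped before construction.
#'
#' @slot incidence a [HypergraphIncidence-class] (empty hyperedges removed).
#' @slot nodeWeight numeric vector of positive per-vertex weights.
#' @slot weightedIncidence numeric matrix \code{W}.
#' @slot weightedEdgeDegree numeric vector of column sums of \code{W}.
#' @slot edgeWeight numeric vector of hyperedge weights, uniform
#'   \code{1/|E|}.
#'
#' @seealso [buildWeightedIncidence()], [buildTransition()]
#' @export
setClass("WeightedHypergraph",
    representation(
        incidence = "HypergraphIncidence",
        nodeWeight = "numeric",
        weightedIncidence = "matrix",
        weightedEdgeDegree = "numeric",
        edgeWeight = "numeric"
    )
)

setValidity("WeightedHypergraph", function(object) {
    H <- object@incidence@incidence
    msgs <- character()
    if (length(object@nodeWeight) != nrow(H))
        msgs <- c(msgs, "'nodeWeight' must have one entry per vertex")
    else if (any(object@nodeWeight <= 0))
        msgs <- c(msgs, "'nodeWeight' entries must be strictly positive")
    W <- object@weightedIncidence
    if (!identical(dim(W), dim(H)))
        msgs <- c(msgs, "'weightedIncidence' must have the incidence dimensions")
    else if (!isTRUE(all.equal(W, H * object@nodeWeight, check.attributes = FALSE)))
        msgs <- c(msgs, "'weightedIncidence' must equal nodeWeight * incidence")
    nE <- ncol(H)
    if (nE > 0L) {
        if (any(object@edgeWeight != 1 / nE))
            msgs <- c(msgs, "'edgeWeight' must be uniform 1/|E|")
        if (any(colSums(H) == 0))
            msgs <- c(msgs, "empty hyperedges must be dropped before weighting")
        if (!isTRUE(all.equal(object@weightedEdgeDegree, unname(colSums(W)))))
            msgs <- c(msgs, "'weightedEdgeDegree' must equal the column sums of W")
    }
    if (length(msgs)) msgs else TRUE
})

#' Row-stochastic vertex transition matrix
#'
#' Transition matrix of the two-step hypergraph walk: from vertex \code{u},
#' pick a hyperedge incident to \code{u} (proportional to its hyperedge
#' weight), then pick a member vertex proportional to its node weight within
#' that hyperedge. Rows of vertices incident to no hyperedge (dangling
#' vertices) are filled according to a recorded policy.
#'
#' @slot matrix numeric square matrix; every row sums to 1.
#' @slot danglingPolicy character(1), \code{"uniform"} or \code{"self_loop"}.
#' @slot danglingVertices integer vector of dangling row indices.
#' @slot normalization character(1), \code{"incident"} (row-stochastic
#'   normalisation over incident hyperedges) or \code{"printed"} (the
#'   product form normalised over all hyperedges, not row-stochastic in
#'   general; retained for comparison).
#'
#' @seealso [buildTransition()], [rwrIterate()]
#' @export
setClass("TransitionMatrix",
    representation(
        matrix = "matrix",
        danglingPolicy = "character",
        danglingVertices = "integer",
        normalization = "character"
    )
)

setValidity("TransitionMatrix", function(object) {
    P <- object@matrix
    msgs <- character()
    if (nrow(P) != ncol(P))
        msgs <- c(msgs, "transition matrix must be square")
    if (any(P < 0))
        msgs <- c(msgs, "transition probabilities must be nonnegative")
    if (identical(object@normalization, "incident") &&
        any(abs(rowSums(P) - 1) > 1e-12))
        msgs <- c(msgs, "every row must sum to 1 within 1e-12")
    if (!object@danglingPolicy %in% c("uniform", "self_loop"))
        msgs <- c(msgs, "'danglingPolicy' must be 'uniform' or 'self_loop'")
    if (length(msgs)) msgs else TRUE
})

#' Stationary scores of the random walk with restart
#'
#' The stationary probability vector of the restart iteration
#' \eqn{v \leftarrow (1-\alpha) P^T v + \alpha v_0}, together with
#' convergence diagnostics. Scores sum to 1; seed vertices keep their
#' stationary mass but are excluded from candidate rankings.
#'
#' @slot scores named numeric vector of per-vertex stationary probabilities.
#' @slot disease character(1), label of the scored disease (or \code{NA}).
#' @slot seeds character vector of seed vertex labels used for \eqn{v_0}.
#' @slot iterations integer(1), iterations performed (0 for a direct solve).
#' @slot converged logical(1).
#' @slot l1Delta numeric(1), last L1 change between iterates.
#' @slot residual numeric(1), L1 fixed-point residual
#'   \eqn{\|v - ((1-\alpha)P^T v + \alpha v_0)\|_1}.
#'
#' @seealso [rwrIterate()], [rwrSolveDirect()], [rankCandidates()]
#' @export
setClass("StationaryScores",
    representation(
        scores = "numeric",
        disease = "character",
        seeds = "character",
        iterations = "integer",
        converged = "logical",
        l1Delta = "numeric",
        residual = "numeric"
    )
)

setValidity("StationaryScores", function(object) {
    msgs <- character()
    if (any(object@scores < 0))
        msgs <- c(msgs, "scores must be nonnegative")
    if (abs(sum(object@scores) - 1) > 1e-8)
        msgs <- c(msgs, "scores must sum to 1 within 1e-8")
    if (is.null(names(object@scores)))
        msgs <- c(msgs, "scores must be named by vertex label")
    if (length(msgs)) msgs else TRUE
})

#' Leave-one-out cross-validation report
#'
#' Per-fold results and the pooled ROC/AUC of a global or local LOOCV run.
#' One fold per known association: the association is removed, the kernel
#' and hypergraph are rebuilt from the masked matrix (by default), the walk
#' is run, and the held-out pair's score is ranked against candidate
#' (unknown) pairs.
#'
#' @slot mode character(1), \code{"global"} or \code{"local"}.
#' @slot folds data.frame with one row per evaluated association: columns
#'   \code{disease}, \code{microbe}, \code{testScore}, \code{nCandidates},
#'   \code{normalizedRank}, \code{flagged} (TRUE when the fold needed the
#'   empty-seed fallback).
#' @slot auc numeric(1), pooled Mann-Whitney AUC over all folds.
#' @slot roc data.frame of ordered (\code{fpr}, \code{tpr}) ROC points.
#' @slot config list, full configuration provenance (alpha, tol, maxIter,
#'   rPrime, kernelRefit, policies, aggregation).
#'
#' @seealso [globalLoocv()], [localLoocv()], [writeLoocvReport()]
#' @export
setClass("LoocvReport",
    representation(
        mode = "character",
        folds = "data.frame",
        auc = "numeric",
        roc = "data.frame",
        config = "list"
    )
)

setValidity("LoocvReport", function(object) {
    msgs <- character()
    if (!object@mode %in% c("global", "local"))
        msgs <- c(msgs, "'mode' must be 'global' or 'local'")
    if (length(object@auc) != 1L || object@auc < 0 || object@auc > 1)
        msgs <- c(msgs, "'auc' must be a single value in [0, 1]")
    need <- c("disease", "microbe", "testScore", "nCandidates",
              "normalizedRank", "flagged")
    if (!all(need %in% names(object@folds)))
        msgs <- c(msgs, paste("'folds' must have columns:",
                              paste(need, collapse = ", ")))
    if (length(msgs)) msgs else TRUE
})
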