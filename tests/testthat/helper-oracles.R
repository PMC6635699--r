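# Independent brute-force oracles used across tests. These deliberately use
# explicit loops over (hyperedge, member vertex) outcomes and explicit pair
# enumeration so they share no code path with the implementation.

# Exhaustive two-step enumeration of the hypergraph walk: from u, pick an
# incident hyperedge proportional to its edge weight, then a member vertex
# proportional to its node weight; sum the outcome probabilities.
oracleTransition <- function(H, weights, edgeWeight = NULL,
                             dangling = "uniform") {
    keep <- colSums(H) > 0
    H <- H[, keep, drop = FALSE]
    nV <- nrow(H)
    nE <- ncol(H)
    if (is.null(edgeWeight))
        edgeWeight <- rep(1 / nE, nE)
    P <- matrix(0, nV, nV)
    for (u in seq_len(nV)) {
        inc <- which(H[u, ] == 1)
        if (length(inc) == 0L) {
            P[u, ] <- if (dangling == "uniform") 1 / nV
                      else as.numeric(seq_len(nV) == u)
            next
        }
        pEdge <- edgeWeight[inc] / sum(edgeWeight[inc])
        for (k in seq_along(inc)) {
            members <- which(H[, inc[k]] == 1)
            pVert <- weights[members] / sum(weights[members])
            P[u, members] <- P[u, members] + pEdge[k] * pVert
        }
    }
    P
}

# AUC by explicit enumeration of every (positive, negative) pair.
oracleAuc <- function(pos, neg) {
    s <- 0
    for (p in pos)
        for (q in neg)
            s <- s + (p > q) + 0.5 * (p == q)
    s / (length(pos) * length(neg))
}

# Random incidence matrix with at least one nonempty hyperedge and the
# matching WeightedHypergraph object.
randomIncidence <- function(nV, nE) {
    repeat {
        H <- matrix(rbinom(nV * nE, 1, 0.5), nV, nE)
        if (any(colSums(H) > 0))
            break
    }
    dimnames(H) <- list(paste0("v", seq_len(nV)), paste0("e", seq_len(nE)))
    H
}

makeWeightedHypergraph <- function(H, weights) {
    inc <- new("HypergraphIncidence", incidence = H,
               vertexDegree = unname(rowSums(H)),
               edgeDegree = unname(colSums(H)))
    buildWeightedIncidence(inc, weights)
}

# small association fixture used in several files: A = [[1,1],[0,1]]
tinyAssociations <- function() {
    bipartiteAssociations(matrix(c(1, 0, 1, 1), 2, 2,
        dimnames = list(c("d1", "d2"), c("m1", "m2"))))
}
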