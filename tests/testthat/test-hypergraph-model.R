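test_that("incidence is the transposed adjacency with matching degrees", {
    A <- matrix(c(1, 0, 1, 1, 0, 1), 2, 3,
                dimnames = list(c("d1", "d2"), c("m1", "m2", "m3")))
    inc <- buildIncidence(bipartiteAssociations(A))
    expect_identical(incidenceMatrix(inc), t(A))
    expect_equal(inc@vertexDegree, c(1, 2, 1))
    expect_equal(inc@edgeDegree, c(2, 2))
    # empty hyperedge flagged
    A2 <- rbind(A, d3 = c(0, 0, 0))
    expect_warning(buildIncidence(bipartiteAssociations(A2)),
                   "empty hyperedge")
})

test_that("node weights are kernel row sums, with and without the self term", {
    K <- gipKernel(tinyAssociations())
    w <- nodeWeights(K)
    expect_equal(unname(w), rep(1 + exp(-2 / 3), 2), tolerance = 1e-15)
    expect_equal(unname(nodeWeights(K, includeSelf = FALSE)),
                 rep(exp(-2 / 3), 2), tolerance = 1e-15)
    # identical profiles -> all-ones kernel -> every weight = nm
    dup <- bipartiteAssociations(matrix(1, 2, 3))
    expect_equal(unname(nodeWeights(gipKernel(dup))), rep(3, 3))
})

test_that("weighted incidence applies weights, drops empty hyperedges, uniform edge weights", {
    H <- matrix(c(1, 1, 0, 0), 2, 2,
                dimnames = list(c("a", "b"), c("e1", "e2")))
    expect_warning(inc <- buildIncidence(bipartiteAssociations(t(H))),
                   "empty")
    hg <- buildWeightedIncidence(inc, c(1, 2))
    expect_equal(ncol(incidenceMatrix(hg)), 1L)  # e2 dropped
    expect_equal(unname(hg@weightedIncidence[, 1]), c(1, 2))
    expect_equal(hg@weightedEdgeDegree, 3)
    expect_equal(hg@edgeWeight, 1)
    hg4 <- makeWeightedHypergraph(
        matrix(1, 3, 4, dimnames = list(letters[1:3], paste0("e", 1:4))),
        c(1, 1, 1))
    expect_equal(hg4@edgeWeight, rep(0.25, 4))
    expect_error(buildWeightedIncidence(inc, c(1, -1)), "positive")
    expect_error(buildWeightedIncidence(inc, 1), "one weight per vertex")
})

test_that("worked three-vertex transition matrix matches hand enumeration", {
    P <- transitionMatrix(buildTransition(exampleHypergraph()))
    expect_equal(unname(P),
                 rbind(c(1 / 3, 2 / 3, 0),
                       c(1 / 6, 2 / 3, 1 / 6),
                       c(0, 2 / 3, 1 / 3)),
                 tolerance = 1e-15)
    # single hyperedge with equal weights -> symmetric doubly uniform rows
    hg1 <- makeWeightedHypergraph(matrix(1, 2, 1), c(1, 1))
    expect_equal(unname(transitionMatrix(buildTransition(hg1))),
                 matrix(0.5, 2, 2))
})

test_that("transition agrees with exhaustive enumeration on random hypergraphs", {
    set.seed(202)
    for (rep in 1:60) {
        H <- randomIncidence(sample(2:6, 1), sample(1:4, 1))
        w <- runif(nrow(H), 0.1, 3)
        hg <- makeWeightedHypergraph(H, w)
        P <- transitionMatrix(buildTransition(hg))
        expect_equal(unname(P), oracleTransition(H, w), tolerance = 1e-12)
        expect_equal(unname(rowSums(P)), rep(1, nrow(H)), tolerance = 1e-12)
    }
})

test_that("uniform node weights reduce to the classic unweighted walk", {
    set.seed(33)
    H <- randomIncidence(5, 3)
    hg <- makeWeightedHypergraph(H, rep(1, 5))
    P <- transitionMatrix(buildTransition(hg))
    keep <- colSums(H) > 0
    Hk <- H[, keep, drop = FALSE]
    d <- rowSums(Hk)
    delta <- colSums(Hk)
    classic <- (Hk %*% (t(Hk) / delta)) / ifelse(d > 0, d, 1)
    nonDangling <- d > 0
    expect_equal(unname(P[nonDangling, ]),
                 unname(as.matrix(classic)[nonDangling, ]),
                 tolerance = 1e-12)
})

test_that("dangling vertex rows follow the chosen policy", {
    H <- matrix(c(1, 1, 0), 3, 1,
                dimnames = list(c("a", "b", "c"), "e1"))
    hg <- makeWeightedHypergraph(H, c(1, 1, 1))
    Pu <- buildTransition(hg, dangling = "uniform")
    expect_equal(unname(transitionMatrix(Pu)[3, ]), rep(1 / 3, 3))
    expect_equal(Pu@danglingVertices, 3L)
    Ps <- buildTransition(hg, dangling = "self_loop")
    expect_equal(unname(transitionMatrix(Ps)[3, ]), c(0, 0, 1))
    expect_equal(unname(rowSums(transitionMatrix(Ps))), rep(1, 3))
})

test_that("printed product form differs by the constant 1/|E| row mass", {
    hg <- exampleHypergraph()           # no dangling vertices, |E| = 2
    Pinc <- transitionMatrix(buildTransition(hg))
    Pprt <- transitionMatrix(buildTransition(hg, normalization = "printed"))
    # with uniform edge weights the printed rows sum to 1/|E| ...
    expect_equal(unname(rowSums(Pprt)), rep(1 / 2, 3), tolerance = 1e-12)
    # ... and renormalizing rows recovers the stochastic form
    expect_equal(Pprt / rowSums(Pprt), Pinc, tolerance = 1e-12)
})
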