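test_that("initial distribution is uniform on seeds with policy fallback", {
    expect_equal(as.numeric(initialDistribution(c(2, 5), 6)),
                 c(0, 0.5, 0, 0, 0.5, 0))
    expect_equal(as.numeric(initialDistribution(3, 4)), c(0, 0, 1, 0))
    v0 <- initialDistribution(integer(), 4)
    expect_equal(as.numeric(v0), rep(0.25, 4))
    expect_true(attr(v0, "emptySeedFallback"))
    expect_error(initialDistribution(integer(), 4, "error"), "empty seed")
    expect_equal(as.numeric(initialDistribution(c(TRUE, FALSE, TRUE), 3)),
                 c(0.5, 0, 0.5))
})

test_that("a single step implements (1-alpha) P'v + alpha v0", {
    P <- buildTransition(exampleHypergraph())
    v0 <- c(1, 0, 0)
    expect_equal(unname(rwrStep(P, v0, v0, alpha = 1)), as.numeric(v0))
    expect_equal(unname(rwrStep(P, v0, v0, alpha = 0.2)),
                 c(0.2 + 0.8 / 3, 0.8 * 2 / 3, 0), tolerance = 1e-12)
    sym <- new("TransitionMatrix", matrix = matrix(0.5, 2, 2),
               danglingPolicy = "uniform", danglingVertices = integer(),
               normalization = "incident")
    expect_equal(rwrStep(sym, c(0.5, 0.5), c(0.5, 0.5), 0.3), c(0.5, 0.5))
    expect_error(rwrStep(P, c(1, 0), v0, 0.2), "dimension mismatch")
})

test_that("iteration reaches the stationary state of the worked instance", {
    P <- buildTransition(exampleHypergraph())
    v0 <- initialDistribution(1, 3)
    res <- rwrIterate(P, v0, walkControl(tol = 1e-10),
                      disease = "dA", seeds = "a")
    expect_true(res@converged)
    expect_equal(unname(stationaryScores(res)),
                 c(0.36970, 0.53333, 0.09697), tolerance = 1e-4)
    direct <- rwrSolveDirect(P, v0, 0.2)
    expect_equal(stationaryScores(res), stationaryScores(direct),
                 tolerance = 1e-8)
    expect_lt(res@residual, 1e-10)
})

test_that("iterative and direct solutions agree across random instances", {
    set.seed(77)
    for (rep in 1:50) {
        H <- randomIncidence(sample(3:7, 1), sample(2:4, 1))
        hg <- makeWeightedHypergraph(H, runif(nrow(H), 0.2, 2))
        P <- buildTransition(hg)
        n <- nrow(H)
        v0 <- initialDistribution(sample(n, sample(n, 1)), n)
        alpha <- runif(1, 0.1, 0.9)
        ctl <- walkControl(alpha = alpha, tol = 1e-9)
        it <- rwrIterate(P, v0, ctl)
        dir <- rwrSolveDirect(P, v0, alpha)
        expect_lt(sum(abs(stationaryScores(it) - stationaryScores(dir))),
                  10 * ctl$tol)
        # probability is conserved along the way
        expect_equal(sum(stationaryScores(it)), 1, tolerance = 1e-10)
    }
})

test_that("restart-dominated limits behave as closed forms predict", {
    P <- buildTransition(exampleHypergraph())
    v0 <- initialDistribution(2, 3)
    # alpha = 1: the restart term alone; iteration returns v0 exactly
    res1 <- rwrIterate(P, v0, walkControl(alpha = 1))
    expect_identical(unname(stationaryScores(res1)), as.numeric(v0))
    expect_equal(res1@iterations, 1L)
    # alpha near 1 converges almost immediately to nearly v0
    res99 <- rwrIterate(P, v0, walkControl(alpha = 0.999))
    expect_lte(res99@iterations, 2L)
    expect_lt(sum(abs(stationaryScores(res99) - v0)), 0.01)
    # alpha near 0 on a connected hypergraph: nearly seed-independent
    ctl <- walkControl(alpha = 1e-4, tol = 1e-12, maxIter = 1e5)
    sA <- stationaryScores(rwrIterate(P, initialDistribution(1, 3), ctl))
    sC <- stationaryScores(rwrIterate(P, initialDistribution(3, 3), ctl))
    expect_lt(sum(abs(sA - sC)), 1e-2)
})

test_that("the iteration respects the (1-alpha)^t contraction bound", {
    set.seed(99)
    for (rep in 1:20) {
        H <- randomIncidence(5, 3)
        hg <- makeWeightedHypergraph(H, runif(5, 0.5, 2))
        P <- buildTransition(hg)
        v0 <- initialDistribution(sample(5, 2), 5)
        alpha <- 0.2
        it <- rwrIterate(P, v0, walkControl(alpha = alpha, tol = 1e-8))
        vInf <- stationaryScores(rwrSolveDirect(P, v0, alpha))
        bound <- (1 - alpha)^it@iterations * sum(abs(v0 - vInf))
        expect_lte(sum(abs(stationaryScores(it) - vInf)), bound + 1e-12)
    }
})

test_that("non-convergence is flagged, never silent", {
    P <- buildTransition(exampleHypergraph())
    v0 <- initialDistribution(1, 3)
    expect_warning(res <- rwrIterate(P, v0, walkControl(tol = 1e-14,
                                                        maxIter = 3)),
                   "did not converge")
    expect_false(res@converged)
    expect_equal(res@iterations, 3L)
})

test_that("scoreDisease runs the full per-disease pipeline", {
    x <- namedFixture("blocks-sep")
    res <- scoreDisease(x, "d01")
    expect_true(res@converged)
    expect_equal(sum(stationaryScores(res)), 1, tolerance = 1e-8)
    expect_setequal(res@seeds,
                    microbeNames(x)[associationMatrix(x)["d01", ] == 1])
    expect_error(scoreDisease(x, "nope"), "unknown disease")
    # seed set = every microbe: all scores positive, sums to 1
    full <- bipartiteAssociations(matrix(1, 2, 4))
    resF <- scoreDisease(full, "d1")
    expect_true(all(stationaryScores(resF) > 0))
    # single-association disease converges from a single-vertex seed
    one <- tinyAssociations()
    expect_true(scoreDisease(one, "d2")@converged)
})

test_that("candidate ranking excludes seeds and applies midranks to ties", {
    s <- new("StationaryScores",
             scores = c(mA = 0.5, mB = 0.3, mC = 0.2),
             disease = "d", seeds = "mA", iterations = 1L,
             converged = TRUE, l1Delta = 0, residual = 0)
    rk <- rankCandidates(s)
    expect_equal(rk$microbe, c("mB", "mC"))
    expect_equal(rk$rank, c(1, 2))
    tied <- new("StationaryScores",
                scores = c(mA = 0.4, mB = 0.2, mC = 0.2, mD = 0.2),
                disease = "d", seeds = "mA", iterations = 1L,
                converged = TRUE, l1Delta = 0, residual = 0)
    rkT <- rankCandidates(tied)
    expect_equal(rkT$rank, rep(2, 3))
    expect_true(all(rkT$tied))
    # disease linked to every microbe -> empty candidate list
    allSeed <- rankCandidates(s, known = c("mA", "mB", "mC"))
    expect_equal(nrow(allSeed), 0L)
})
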