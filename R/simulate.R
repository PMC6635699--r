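#' Planted-block synthetic association matrix
#'
#' Generates a binary disease-by-microbe matrix with block structure:
#' diseases and microbes are partitioned into \code{nBlocks} groups as
#' evenly as possible (in label order), and \code{A[i, j] ~
#' Bernoulli(pIn)} when disease \code{i} and microbe \code{j} share a
#' block, \code{Bernoulli(pOut)} otherwise. The draw is deterministic
#' given \code{seed} (Mersenne-Twister, fixed stream order over the matrix
#' in column-major order). All-zero rows and columns are retained and
#' reported as attributes.
#'
#' The defaults emulate the sparse regime of curated microbe-disease
#' catalogs (hundreds of 1s in a matrix of a few thousand cells) at a
#' size small enough for exhaustive cross-validation.
#'
#' @param nd,nm numbers of diseases and microbes.
#' @param nBlocks number of planted blocks.
#' @param pIn,pOut within-block and background association probabilities,
#'   \code{0 <= pOut <= pIn <= 1}.
#' @param seed integer RNG seed.
#' @return a [BipartiteAssociations-class]; attributes
#'   \code{diseaseBlock} and \code{microbeBlock} hold the ground-truth
#'   block labels, \code{emptyDiseases}/\code{emptyMicrobes} the counts of
#'   all-zero rows/columns.
#' @examples
#' simulatePlanted(10, 40, nBlocks = 2, pIn = 1, pOut = 0, seed = 7)
#' @export
simulatePlanted <- function(nd = 10, nm = 40, nBlocks = 2, pIn = 1,
                            pOut = 0, seed = 7) {
    stopifnot(nd >= 1, nm >= 1, nBlocks >= 1,
              pOut >= 0, pIn <= 1, pOut <= pIn)
    dBlock <- blockLabels(nd, nBlocks)
    mBlock <- blockLabels(nm, nBlocks)
    p <- matrix(pOut, nd, nm)
    p[outer(dBlock, mBlock, "==")] <- pIn
    A <- withSeed(seed, matrix(as.numeric(stats::runif(nd * nm) < p),
                               nd, nm))
    dimnames(A) <- list(paddedLabels("d", nd), paddedLabels("m", nm))
    x <- new("BipartiteAssociations", adjacency = A)
    attr(x, "diseaseBlock") <- dBlock
    attr(x, "microbeBlock") <- mBlock
    attr(x, "emptyDiseases") <- sum(rowSums(A) == 0)
    attr(x, "emptyMicrobes") <- sum(colSums(A) == 0)
    x
}

blockLabels <- function(n, nBlocks) {
    sort(rep_len(seq_len(nBlocks), n))
}

withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv())
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
    on.exit({
        if (is.null(old))
            rm(".Random.seed", envir = globalenv())
        else assign(".Random.seed", old, globalenv())
    })
    expr
}

#' Unstructured random association matrix
#'
#' I.i.d. Bernoulli(\code{density}) entries, deterministic given
#' \code{seed}.
#'
#' @param nd,nm numbers of diseases and microbes.
#' @param density association probability in [0, 1].
#' @param seed integer RNG seed.
#' @return a [BipartiteAssociations-class].
#' @export
simulateRandom <- function(nd, nm, density, seed) {
    stopifnot(nd >= 1, nm >= 1, density >= 0, density <= 1)
    A <- withSeed(seed, matrix(as.numeric(stats::runif(nd * nm) < density),
                               nd, nm))
    dimnames(A) <- list(paddedLabels("d", nd), paddedLabels("m", nm))
    new("BipartiteAssociations", adjacency = A)
}

#' Named fixture catalog
#'
#' Three fixed synthetic fixtures used throughout tests and the worked
#' examples; each is fully determined by its parameters and seed, so the
#' fixture can be regenerated anywhere byte-identically.
#'
#' \describe{
#'   \item{\code{blocks-sep}}{10 x 40, 2 blocks, pIn = 1, pOut = 0,
#'     seed 7: perfectly separated block-diagonal structure.}
#'   \item{\code{blocks-noisy}}{10 x 40, 2 blocks, pIn = 0.5,
#'     pOut = 0.02, seed 7: noisy planted structure.}
#'   \item{\code{hmdad-like}}{39 x 292 at density 0.04, seed 11: the
#'     sparsity regime of a curated association catalog, without block
#'     structure.}
#' }
#'
#' @param name fixture name, one of the above.
#' @return a [BipartiteAssociations-class].
#' @export
namedFixture <- function(name = c("blocks-sep", "blocks-noisy",
                                  "hmdad-like")) {
    switch(match.arg(name),
        "blocks-sep" = simulatePlanted(10, 40, nBlocks = 2, pIn = 1,
                                       pOut = 0, seed = 7),
        "blocks-noisy" = simulatePlanted(10, 40, nBlocks = 2, pIn = 0.5,
                                         pOut = 0.02, seed = 7),
        "hmdad-like" = simulateRandom(39, 292, density = 0.04, seed = 11))
}
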