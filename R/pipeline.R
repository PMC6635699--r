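#' Rank candidate microbes for every disease
#'
#' Builds the transition matrix once (it does not depend on the queried
#' disease), runs the restart walk for each disease seeded on its known
#' microbes, and collects the ranked candidate lists. This is the
#' prediction pipeline behind the command-line \code{predict} subcommand.
#'
#' @param x a [BipartiteAssociations-class].
#' @param control a [walkControl()] list.
#' @param rPrime GIP bandwidth normalisation constant.
#' @param dangling dangling-vertex policy, see [buildTransition()].
#' @return data.frame with columns \code{disease}, \code{microbe},
#'   \code{score}, \code{rank}, \code{tied}: one ranked candidate list per
#'   disease, ordered by disease label then rank.
#' @examples
#' preds <- predictAllDiseases(buildAdjacency(exampleCatalog()))
#' head(preds)
#' @export
predictAllDiseases <- function(x, control = walkControl(), rPrime = 1,
                               dangling = "uniform") {
    stopifnot(is(x, "BipartiteAssociations"))
    P <- transitionFromAssociations(x, rPrime, dangling)
    out <- lapply(diseaseNames(x), function(d) {
        rankCandidates(walkOneDisease(x, d, P, control))
    })
    res <- do.call(rbind, out)
    ord <- order(method = "radix", res$disease, res$rank, res$microbe)
    res <- res[ord, , drop = FALSE]
    row.names(res) <- NULL
    res
}

#' hyperMDA: hypergraph random-walk prediction of microbe-disease
#' associations
#'
#' Models a bipartite microbe-disease association table as a hypergraph
#' (diseases are hyperedges, microbes are vertices), weights vertices by
#' Gaussian interaction profile kernel similarity, and ranks candidate
#' microbes per disease by the stationary distribution of a two-step
#' random walk with restart. Ships global/local leave-one-out
#' cross-validation and a planted-block synthetic data generator.
#'
#' Typical flow: [readAssociationCatalog()] \eqn{\to}
#' [deduplicateCatalog()] \eqn{\to} [buildAdjacency()] \eqn{\to}
#' [predictAllDiseases()] or [globalLoocv()]/[localLoocv()].
#'
#' @name hyperMDA-package
#' @aliases hyperMDA
#' @import methods
#' @importFrom stats setNames runif
#' @importFrom utils head tail read.table write.table packageVersion
"_PACKAGE"
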