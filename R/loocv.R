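#' Mann-Whitney AUC
#'
#' The probability that a randomly chosen positive score exceeds a randomly
#' chosen negative score, with ties counted one half:
#' \deqn{AUC = \frac{\#(pos > neg) + 0.5\,\#(pos = neg)}{|pos|\,|neg|}.}
#' Computed through midranks (the Wilcoxon identity), which is exact.
#'
#' @param positive,negative numeric score vectors, both non-empty.
#' @return numeric(1) in [0, 1].
#' @examples
#' mannWhitneyAUC(c(10, 8), c(9, 1))  # 0.75
#' @export
mannWhitneyAUC <- function(positive, negative) {
    nPos <- length(positive)
    nNeg <- length(negative)
    if (nPos == 0L || nNeg == 0L)
        stop("both score sets must be non-empty", call. = FALSE)
    r <- rank(c(positive, negative), ties.method = "average")
    (sum(r[seq_len(nPos)]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' ROC curve by threshold sweep
#'
#' Sweeps a threshold down the distinct score values; at each threshold
#' \eqn{t}, TPR is the fraction of positives \eqn{\ge t} and FPR the
#' fraction of negatives \eqn{\ge t}. The curve starts at (0, 0) and ends
#' at (1, 1); its trapezoidal area equals [mannWhitneyAUC()] to floating
#' point accuracy.
#'
#' @inheritParams mannWhitneyAUC
#' @return data.frame with columns \code{fpr} and \code{tpr}, both
#'   nondecreasing, plus attribute \code{auc} (trapezoidal area).
#' @export
rocPoints <- function(positive, negative) {
    if (length(positive) == 0L || length(negative) == 0L)
        stop("both score sets must be non-empty", call. = FALSE)
    thr <- sort(unique(c(positive, negative)), decreasing = TRUE)
    tpr <- vapply(thr, function(t) mean(positive >= t), numeric(1))
    fpr <- vapply(thr, function(t) mean(negative >= t), numeric(1))
    curve <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
    auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                  utils::tail(curve$tpr, -1)) / 2)
    attr(curve, "auc") <- auc
    curve
}

#' Leave-one-out cross-validation of the hypergraph walk
#'
#' Every known association is left out in turn: the pair is removed from
#' the adjacency, the GIP kernel, hypergraph and transition matrix are
#' rebuilt from the masked matrix (default \code{kernelRefit = "per_fold"};
#' \code{"once"} reuses the full-data transition matrix, which is cheaper
#' but lets the held-out pair leak into the kernel), the walk is run, and
#' the held-out pair's score is compared with candidate scores.
#'
#' In \code{global} mode the walk is run for every disease and the test
#' pair competes against all disease-microbe pairs unknown in the original
#' data, pooled across diseases (every disease's stationary vector sums to
#' 1, so scores are on a comparable scale). In \code{local} mode it
#' competes only against the unknown microbes of its own disease. Folds
#' are pooled into one Mann-Whitney AUC (\code{aggregation = "pooled"});
#' \code{"macro"} instead averages one AUC per disease.
#'
#' Diseases left with no seed after the removal fall back to the
#' empty-seed policy of \code{control} and their folds are flagged, never
#' dropped.
#'
#' @param x a [BipartiteAssociations-class] with at least 2 associations.
#' @param mode \code{"global"} or \code{"local"}.
#' @param control a [walkControl()] list.
#' @param rPrime GIP bandwidth normalisation constant.
#' @param kernelRefit \code{"per_fold"} (default, leakage-free) or
#'   \code{"once"}.
#' @param dangling dangling-vertex policy, see [buildTransition()].
#' @param aggregation \code{"pooled"} (default) or \code{"macro"}.
#' @return a [LoocvReport-class].
#' @seealso [globalLoocv()], [localLoocv()]
#' @export
runLoocv <- function(x, mode = c("global", "local"),
                     control = walkControl(), rPrime = 1,
                     kernelRefit = c("per_fold", "once"),
                     dangling = "uniform",
                     aggregation = c("pooled", "macro")) {
    mode <- match.arg(mode)
    kernelRefit <- match.arg(kernelRefit)
    aggregation <- match.arg(aggregation)
    stopifnot(is(x, "BipartiteAssociations"))
    A <- x@adjacency
    ones <- which(A == 1, arr.ind = TRUE)
    ones <- ones[order(ones[, 1L], ones[, 2L]), , drop = FALSE]
    if (nrow(ones) < 2L)
        stop("LOOCV needs at least 2 known associations", call. = FALSE)
    unknownMask <- A == 0
    P0 <- if (kernelRefit == "once")
        transitionFromAssociations(x, rPrime, dangling)
    nFold <- nrow(ones)
    testScore <- numeric(nFold)
    nCand <- integer(nFold)
    normRank <- numeric(nFold)
    flagged <- logical(nFold)
    negPool <- vector("list", nFold)
    for (k in seq_len(nFold)) {
        di <- ones[k, 1L]
        mi <- ones[k, 2L]
        Atr <- A
        Atr[di, mi] <- 0
        xtr <- new("BipartiteAssociations", adjacency = Atr)
        P <- if (kernelRefit == "per_fold")
            transitionFromAssociations(xtr, rPrime, dangling)
        else P0
        if (mode == "global") {
            S <- matrix(NA_real_, nrow(A), ncol(A), dimnames = dimnames(A))
            for (d in rownames(A)) {
                res <- walkOneDisease(xtr, d, P, control)
                S[d, ] <- res@scores
                if (d == rownames(A)[di])
                    flagged[k] <- isTRUE(attr(res, "emptySeedFallback"))
            }
            testScore[k] <- S[di, mi]
            neg <- S[unknownMask]
        } else {
            res <- walkOneDisease(xtr, rownames(A)[di], P, control)
            flagged[k] <- isTRUE(attr(res, "emptySeedFallback"))
            testScore[k] <- res@scores[mi]
            neg <- res@scores[unknownMask[di, ]]
        }
        nCand[k] <- length(neg)
        normRank[k] <- (sum(neg > testScore[k]) +
                        0.5 * sum(neg == testScore[k]) + 1) / (length(neg) + 1)
        negPool[[k]] <- unname(neg)
    }
    folds <- data.frame(disease = rownames(A)[ones[, 1L]],
                        microbe = colnames(A)[ones[, 2L]],
                        testScore = testScore, nCandidates = nCand,
                        normalizedRank = normRank, flagged = flagged,
                        stringsAsFactors = FALSE)
    negAll <- unlist(negPool, use.names = FALSE)
    auc <- if (aggregation == "pooled") {
        mannWhitneyAUC(testScore, negAll)
    } else {
        perDisease <- vapply(split(seq_len(nFold), folds$disease),
            function(idx) mannWhitneyAUC(
                testScore[idx], unlist(negPool[idx], use.names = FALSE)),
            numeric(1))
        mean(perDisease)
    }
    roc <- rocPoints(testScore, negAll)
    attr(roc, "auc") <- NULL
    new("LoocvReport", mode = mode, folds = folds, auc = auc, roc = roc,
        config = list(alpha = control$alpha, tol = control$tol,
                      maxIter = control$maxIter,
                      emptySeedPolicy = control$emptySeedPolicy,
                      rPrime = rPrime, kernelRefit = kernelRefit,
                      dangling = dangling, aggregation = aggregation,
                      tiePolicy = "midrank"))
}

#' @rdname runLoocv
#' @param ... passed to [runLoocv()].
#' @export
globalLoocv <- function(x, ...) runLoocv(x, mode = "global", ...)

#' @rdname runLoocv
#' @export
localLoocv <- function(x, ...) runLoocv(x, mode = "local", ...)

#' Write a LOOCV report to disk
#'
#' Emits a JSON summary (\code{<prefix>_summary.json}: mode, AUC, fold and
#' flag counts, full configuration), a per-fold TSV
#' (\code{<prefix>_folds.tsv}) and optionally the ROC points
#' (\code{<prefix>_roc.tsv}). Output is deterministic: identical inputs and
#' configuration give byte-identical files.
#'
#' @param report a [LoocvReport-class].
#' @param prefix output path prefix.
#' @param roc logical(1), also write the ROC point table.
#' @return invisibly, character vector of files written.
#' @export
writeLoocvReport <- function(report, prefix, roc = TRUE) {
    stopifnot(is(report, "LoocvReport"))
    summaryPath <- paste0(prefix, "_summary.json")
    foldsPath <- paste0(prefix, "_folds.tsv")
    summary <- list(mode = report@mode, auc = report@auc,
                    nFolds = nrow(report@folds),
                    nFlagged = sum(report@folds$flagged),
                    config = report@config)
    jsonlite::write_json(summary, summaryPath, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    utils::write.table(report@folds, foldsPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written <- c(summaryPath, foldsPath)
    if (roc) {
        rocPath <- paste0(prefix, "_roc.tsv")
        utils::write.table(report@roc, rocPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        written <- c(written, rocPath)
    }
    invisible(written)
}

#' @describeIn loocvAuc pooled (or macro-averaged) AUC of the report.
#' @export
setMethod("loocvAuc", "LoocvReport", function(x) x@auc)

#' @describeIn loocvAuc per-fold results data.frame.
#' @export
setMethod("loocvFolds", "LoocvReport", function(x) x@folds)

#' LOOCV report accessors
#'
#' @param x a [LoocvReport-class].
#' @name loocvAuc
NULL

setMethod("show", "LoocvReport", function(object) {
    cat(sprintf("LoocvReport (%s): AUC = %.4f over %d fold(s)\n",
                object@mode, object@auc, nrow(object@folds)))
    if (any(object@folds$flagged))
        cat("  flagged folds (empty-seed fallback):",
            sum(object@folds$flagged), "\n")
    cat("  config: alpha =", object@config$alpha,
        ", kernelRefit =", object@config$kernelRefit,
        ", aggregation =", object@config$aggregation, "\n")
})
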