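#' Read a disease-microbe association table
#'
#' Reads a delimited text table with (at least) a \code{disease} and a
#' \code{microbe} column into an [AssociationCatalog-class]. Labels are
#' trimmed of leading/trailing whitespace; row order is preserved; extra
#' columns are ignored. Lines starting with \code{#} are treated as
#' comments (provenance headers written by this package are skipped
#' transparently).
#'
#' @param path path to an existing file.
#' @param delim field delimiter, \code{"tab"} (default) or \code{"comma"}.
#' @param diseaseCol,microbeCol names of the required columns.
#' @return an \code{AssociationCatalog} (not deduplicated).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("disease\tmicrobe", "asthma\tPseudomonas",
#'              "asthma\tStreptococcus"), tf)
#' readAssociationCatalog(tf)
#' @export
readAssociationCatalog <- function(path, delim = c("tab", "comma"),
                                   diseaseCol = "disease",
                                   microbeCol = "microbe") {
    delim <- match.arg(delim)
    if (!file.exists(path))
        stop("association file not found: ", path, call. = FALSE)
    sep <- if (delim == "tab") "\t" else ","
    tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                             comment.char = "#", stringsAsFactors = FALSE,
                             colClasses = "character", check.names = FALSE)
    missing <- setdiff(c(diseaseCol, microbeCol), names(tab))
    if (length(missing))
        stop("missing required column(s): ", paste(missing, collapse = ", "),
             call. = FALSE)
    if (nrow(tab) == 0L)
        stop("association file has no data rows after the header: ", path,
             call. = FALSE)
    rec <- data.frame(disease = trimws(tab[[diseaseCol]]),
                      microbe = trimws(tab[[microbeCol]]),
                      stringsAsFactors = FALSE)
    new("AssociationCatalog", records = rec,
        provenance = paste0("file:", path))
}

#' Remove duplicate association records
#'
#' Keeps the first occurrence of every exact (disease, microbe) pair.
#' Matching is exact string equality after the whitespace trimming applied
#' on ingestion; case is preserved. The number of removed records is
#' reported via \code{message()}.
#'
#' @param catalog an [AssociationCatalog-class].
#' @return a deduplicated \code{AssociationCatalog}.
#' @export
deduplicateCatalog <- function(catalog) {
    stopifnot(is(catalog, "AssociationCatalog"))
    rec <- catalog@records
    dup <- duplicated(rec[, c("disease", "microbe")])
    if (any(dup))
        message("deduplicateCatalog: removed ", sum(dup),
                " duplicate record(s), ", sum(!dup), " remain")
    new("AssociationCatalog", records = rec[!dup, , drop = FALSE],
        provenance = catalog@provenance, deduplicated = TRUE)
}

#' Build the binary adjacency matrix from a catalog
#'
#' Constructs a [BipartiteAssociations-class] whose rows are the sorted
#' unique disease labels and whose columns are the sorted unique microbe
#' labels (lexicographic sort in the C locale, fixing the ordering
#' deterministically across runs); \code{A[i, j] = 1} iff the pair occurs
#' in the catalog.
#'
#' @param catalog an [AssociationCatalog-class]; deduplicated catalogs are
#'   used as-is, others are deduplicated first.
#' @return a \code{BipartiteAssociations}.
#' @examples
#' cat3 <- exampleCatalog()
#' associationMatrix(buildAdjacency(cat3))
#' @export
buildAdjacency <- function(catalog) {
    stopifnot(is(catalog, "AssociationCatalog"))
    if (!isTRUE(catalog@deduplicated))
        catalog <- suppressMessages(deduplicateCatalog(catalog))
    rec <- catalog@records
    if (nrow(rec) == 0L)
        stop("cannot build an adjacency matrix from an empty catalog",
             call. = FALSE)
    dLev <- sortLabels(unique(rec$disease))
    mLev <- sortLabels(unique(rec$microbe))
    A <- matrix(0, nrow = length(dLev), ncol = length(mLev),
                dimnames = list(dLev, mLev))
    A[cbind(match(rec$disease, dLev), match(rec$microbe, mLev))] <- 1
    new("BipartiteAssociations", adjacency = A)
}

# Locale-independent lexicographic sort so row/column order is identical on
# every platform.
sortLabels <- function(x) {
    x[order(method = "radix", x)]
}

#' Construct a BipartiteAssociations from a matrix
#'
#' Low-level constructor used by the synthetic-data generator and tests.
#'
#' @param A numeric 0/1 matrix (diseases x microbes). Missing dimnames are
#'   filled with zero-padded \code{d}/\code{m} labels.
#' @return a [BipartiteAssociations-class].
#' @export
bipartiteAssociations <- function(A) {
    A <- as.matrix(A)
    if (is.null(rownames(A)))
        rownames(A) <- paddedLabels("d", nrow(A))
    if (is.null(colnames(A)))
        colnames(A) <- paddedLabels("m", ncol(A))
    new("BipartiteAssociations", adjacency = A)
}

paddedLabels <- function(prefix, n) {
    sprintf("%s%0*d", prefix, nchar(as.character(n)), seq_len(n))
}

#' Convert an adjacency matrix back to a catalog
#'
#' Inverse of [buildAdjacency()]: emits one record per 1-entry, ordered by
#' disease then microbe label, flagged deduplicated.
#'
#' @param x a [BipartiteAssociations-class].
#' @return an [AssociationCatalog-class].
#' @export
asCatalog <- function(x) {
    stopifnot(is(x, "BipartiteAssociations"))
    idx <- which(x@adjacency == 1, arr.ind = TRUE)
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    rec <- data.frame(disease = rownames(x@adjacency)[idx[, 1L]],
                      microbe = colnames(x@adjacency)[idx[, 2L]],
                      stringsAsFactors = FALSE)
    new("AssociationCatalog", records = rec, provenance = "adjacency",
        deduplicated = TRUE)
}

#' Tiny worked example catalog
#'
#' Three associations over two diseases and two microbes, used throughout
#' the documentation examples.
#'
#' @return an [AssociationCatalog-class] with records (d1, m1), (d1, m2),
#'   (d2, m2).
#' @export
exampleCatalog <- function() {
    new("AssociationCatalog",
        records = data.frame(disease = c("d1", "d1", "d2"),
                             microbe = c("m1", "m2", "m2"),
                             stringsAsFactors = FALSE),
        provenance = "example", deduplicated = TRUE)
}

#' Write an association table to delimited text
#'
#' Writes the 1-entries of the adjacency (or a catalog's records) as a TSV
#' with columns \code{disease} and \code{microbe}, preceded by \code{#}
#' provenance comment lines readable back by [readAssociationCatalog()].
#'
#' @param x a [BipartiteAssociations-class] or [AssociationCatalog-class].
#' @param path output file path.
#' @param provenance character vector of extra provenance lines (written as
#'   \code{# } comments).
#' @return invisibly, the path.
#' @export
writeAssociationTable <- function(x, path, provenance = character()) {
    if (is(x, "BipartiteAssociations"))
        x <- asCatalog(x)
    stopifnot(is(x, "AssociationCatalog"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(provenanceHeader(provenance), con)
    writeLines("disease\tmicrobe", con)
    rec <- x@records
    if (nrow(rec))
        writeLines(paste(rec$disease, rec$microbe, sep = "\t"), con)
    invisible(path)
}

provenanceHeader <- function(extra = character()) {
    c(sprintf("# hyperMDA %s",
              as.character(utils::packageVersion("hyperMDA"))),
      if (length(extra)) paste0("# ", extra))
}

#' Write ranked per-disease predictions
#'
#' Writes a TSV with columns \code{disease}, \code{microbe}, \code{score},
#' \code{rank} and \code{tied}, ordered by disease label then rank. Rank 1
#' is the highest score; tied scores share their midrank and are flagged in
#' the \code{tied} column.
#'
#' @param predictions data.frame with columns \code{disease},
#'   \code{microbe}, \code{score}, \code{rank} and \code{tied}, as produced
#'   by [predictAllDiseases()] / [rankCandidates()]. An empty data.frame
#'   yields a header-only file.
#' @param path output file path.
#' @param provenance character vector of extra \code{#} header lines.
#' @return invisibly, the path.
#' @export
writeRankedPredictions <- function(predictions, path,
                                   provenance = character()) {
    need <- c("disease", "microbe", "score", "rank", "tied")
    stopifnot(is.data.frame(predictions), all(need %in% names(predictions)))
    if (nrow(predictions) && !all(is.finite(predictions$score)))
        stop("prediction scores must be finite", call. = FALSE)
    ord <- order(method = "radix", predictions$disease, predictions$rank)
    predictions <- predictions[ord, need, drop = FALSE]
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(provenanceHeader(provenance), con)
    writeLines(paste(need, collapse = "\t"), con)
    if (nrow(predictions))
        writeLines(sprintf("%s\t%s\t%.12g\t%g\t%s",
                           predictions$disease, predictions$microbe,
                           predictions$score, predictions$rank,
                           ifelse(predictions$tied, "yes", "no")), con)
    invisible(path)
}

#' @describeIn associationMatrix the adjacency matrix of a
#'   \code{BipartiteAssociations}.
#' @export
setMethod("associationMatrix", "BipartiteAssociations",
          function(x) x@adjacency)

#' Accessors for bipartite association objects
#'
#' @param x a [BipartiteAssociations-class].
#' @return \code{associationMatrix}: the numeric 0/1 matrix;
#'   \code{diseaseNames}/\code{microbeNames}: character label vectors.
#' @name associationMatrix
NULL

#' @describeIn diseaseNames disease labels (row names).
#' @export
setMethod("diseaseNames", "BipartiteAssociations",
          function(x) rownames(x@adjacency))

#' @describeIn diseaseNames microbe labels (column names).
#' @export
setMethod("microbeNames", "BipartiteAssociations",
          function(x) colnames(x@adjacency))

#' Disease and microbe label accessors
#'
#' @param x a [BipartiteAssociations-class].
#' @name diseaseNames
NULL

setMethod("show", "AssociationCatalog", function(object) {
    cat("AssociationCatalog with", nrow(object@records), "record(s)",
        if (object@deduplicated) "(deduplicated)" else "(raw)", "\n")
    cat("  diseases:", length(unique(object@records$disease)),
        " microbes:", length(unique(object@records$microbe)), "\n")
    cat("  provenance:", object@provenance, "\n")
})

setMethod("show", "BipartiteAssociations", function(object) {
    A <- object@adjacency
    cat("BipartiteAssociations:", nrow(A), "disease(s) x", ncol(A),
        "microbe(s),", sum(A), "association(s)",
        sprintf("(density %.3f)\n", mean(A)))
})
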