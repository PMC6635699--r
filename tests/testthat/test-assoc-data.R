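test_that("catalog reading parses, trims, and preserves row order", {
    tf <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("disease\tmicrobe\tnote",
                 "  asthma \t Pseudomonas \tx",
                 "ibd\tBacteroides\ty",
                 "asthma\tStreptococcus\tz"), tf)
    cat <- readAssociationCatalog(tf)
    expect_s4_class(cat, "AssociationCatalog")
    expect_equal(nrow(cat@records), 3L)
    expect_equal(cat@records$disease[1], "asthma")
    expect_equal(cat@records$microbe[1], "Pseudomonas")
    expect_equal(cat@records$microbe,
                 c("Pseudomonas", "Bacteroides", "Streptococcus"))

    csv <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("disease,microbe", "a,b"), csv)
    expect_equal(nrow(readAssociationCatalog(csv, delim = "comma")@records), 1L)
})

test_that("reader raises distinct errors for missing file, column, and data", {
    expect_error(readAssociationCatalog(tempfile()), "not found")
    tf <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("illness\tmicrobe", "a\tb"), tf)
    expect_error(readAssociationCatalog(tf), "missing required column")
    tf2 <- withr::local_tempfile(fileext = ".tsv")
    writeLines("disease\tmicrobe", tf2)
    expect_error(readAssociationCatalog(tf2), "no data rows")
})

test_that("deduplication keeps first occurrences and is an identity without duplicates", {
    rec <- data.frame(disease = c("d1", "d2", "d1", "d1", "d3"),
                      microbe = c("m1", "m1", "m2", "m1", "m9"),
                      stringsAsFactors = FALSE)
    cat <- new("AssociationCatalog", records = rec)
    expect_message(ded <- deduplicateCatalog(cat), "removed 1")
    expect_equal(nrow(ded@records), 4L)
    expect_true(ded@deduplicated)
    # first occurrence kept, order preserved
    expect_equal(ded@records$disease, c("d1", "d2", "d1", "d3"))
    again <- suppressMessages(deduplicateCatalog(ded))
    expect_equal(again@records, ded@records, ignore_attr = TRUE)
})

test_that("adjacency construction is deterministic with sorted labels", {
    A <- buildAdjacency(exampleCatalog())
    expect_identical(associationMatrix(A),
                     matrix(c(1, 0, 1, 1), 2, 2,
                            dimnames = list(c("d1", "d2"), c("m1", "m2"))))
    # single record -> 1x1 matrix of 1
    one <- new("AssociationCatalog",
               records = data.frame(disease = "d", microbe = "m",
                                    stringsAsFactors = FALSE),
               deduplicated = TRUE)
    expect_identical(unname(associationMatrix(buildAdjacency(one))),
                     matrix(1, 1, 1))
    empty <- new("AssociationCatalog", deduplicated = TRUE)
    expect_error(buildAdjacency(empty), "empty catalog")
    # label order is independent of record order
    shuffled <- new("AssociationCatalog",
        records = exampleCatalog()@records[c(3, 1, 2), ],
        deduplicated = TRUE)
    expect_identical(associationMatrix(buildAdjacency(shuffled)),
                     associationMatrix(A))
})

test_that("adjacency round-trips through a catalog and through disk", {
    set.seed(101)
    x <- simulateRandom(6, 15, 0.3, seed = 3)
    back <- buildAdjacency(asCatalog(x))
    expect_identical(associationMatrix(back), associationMatrix(x))
    tf <- withr::local_tempfile(fileext = ".tsv")
    writeAssociationTable(x, tf, provenance = "round trip")
    reread <- buildAdjacency(readAssociationCatalog(tf))
    expect_identical(associationMatrix(reread), associationMatrix(x))
})

test_that("ranked prediction output orders by disease then rank and flags ties", {
    preds <- data.frame(
        disease = c("d2", "d1", "d1", "d1"),
        microbe = c("mX", "mA", "mB", "mC"),
        score = c(0.4, 0.1, 0.25, 0.25),
        rank = c(1, 3, 1.5, 1.5),
        tied = c(FALSE, FALSE, TRUE, TRUE),
        stringsAsFactors = FALSE)
    tf <- withr::local_tempfile(fileext = ".tsv")
    writeRankedPredictions(preds, tf)
    lines <- readLines(tf)
    body <- lines[!startsWith(lines, "#")]
    expect_equal(body[1], "disease\tmicrobe\tscore\trank\ttied")
    expect_match(body[2], "^d1\tmB\t0.25\t1.5\tyes$")
    expect_match(body[5], "^d2\tmX")
    # empty set -> header-only file
    tf2 <- withr::local_tempfile(fileext = ".tsv")
    writeRankedPredictions(preds[0, ], tf2)
    lines2 <- readLines(tf2)
    expect_equal(sum(!startsWith(lines2, "#")), 1L)
    expect_error(writeRankedPredictions(transform(preds, score = NaN), tf),
                 "finite")
})
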