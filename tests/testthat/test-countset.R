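test_that("CountSet validity catches malformed input", {
    m <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("a", "b")))
    d <- data.frame(subject = c("s1", "s2"), group = c("a", "b"))
    expect_s4_class(CountSet(m, d), "CountSet")
    expect_error(CountSet(m, d[1, , drop = FALSE]), "1 rows")
    expect_error(CountSet(matrix(c(-1L, 1L, 1L, 1L), 2,
                                 dimnames = dimnames(m)), d),
                 "non-negative")
    m2 <- m; rownames(m2) <- c("g1", "g1")
    expect_error(CountSet(m2, d), "duplicate gene")
    expect_error(CountSet(m, data.frame(subject = c("s1", "s2"))), "group")
})

test_that("count TSV round trip preserves content and order", {
    m <- matrix(0:11, nrow = 3,
                dimnames = list(c("gB", "gA", "gC"), paste0("s", 1:4)))
    storage.mode(m) <- "integer"
    path <- withr::local_tempfile(fileext = ".tsv")
    writeCounts(m, path, comments = "round trip fixture")
    expect_identical(readCounts(path), m)
})

test_that("readCounts validates cells and structure", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("gene_id\ts1\ts2", "g1\t3\t-1", "g2\t0\t2"), path)
    expect_error(readCounts(path), "g1.*s2")
    writeLines(c("gene_id\ts1\ts2", "g1\t3", "g2\t0\t2"), path)
    expect_error(readCounts(path), "[Rr]agged")
    writeLines(character(0), path)
    expect_error(readCounts(path), "no header")
    writeLines(c("gene_id\ts1\ts2", "g1\t3\t1.5"), path)
    expect_error(readCounts(path), "non-integer")
})

test_that("design table IO requires the key columns", {
    d <- studyDesignReplica()
    path <- withr::local_tempfile(fileext = ".tsv")
    writeDesignTable(d, path)
    back <- readDesignTable(path)
    expect_equal(back$subject, d$subject)
    expect_equal(back$status, d$status)
    writeLines(c("subject\tfoo", "s1\t1"), path)
    expect_error(readDesignTable(path), "group")
})

test_that("sumLanePairs adds the two lanes and books exclusions", {
    m <- matrix(c(3L, 4L, 10L, 20L,
                  0L, 0L, 5L, 5L), nrow = 2, byrow = TRUE,
                dimnames = list(c("g1", "g2"),
                                c("s1_L1", "s1_L2", "s2_L1", "s2_L2")))
    d <- data.frame(subject = rep(c("s1", "s2"), each = 2),
                    group = rep(c("a", "b"), each = 2),
                    status = "retained", tech_rep = rep(1:2, 2))
    cs <- CountSet(m, d, level = "lane")
    subj <- sumLanePairs(cs)
    expect_equal(unname(counts(subj)["g1", ]), c(7, 30))
    expect_equal(unname(counts(subj)["g2", ]), c(0, 10))   # all-zero stays
    expect_equal(colSums(counts(subj)), colSums(
        vapply(c("s1", "s2"), function(s)
            rowSums(m[, d$subject == s]), numeric(2))))
    ## one failed lane: strict errors, lenient drops with a warning
    d2 <- d; d2$status[2] <- "failed_sequencing"
    cs2 <- CountSet(m, d2, level = "lane")
    expect_error(sumLanePairs(cs2), "s1")
    expect_warning(out <- sumLanePairs(cs2, strict = FALSE), "s1")
    expect_equal(colnames(counts(out)), "s2")
})

test_that("filterExpressed keeps genes with any count and is idempotent", {
    cs <- tinyCountSet()
    f1 <- filterExpressed(cs)
    expect_equal(nrow(f1), 3L)              # g4 is all zero
    expect_equal(counts(filterExpressed(f1)), counts(f1))
    allzero <- tinyCountSet(matrix(0L, 2, 3,
        dimnames = list(c("g1", "g2"), c("s1", "s2", "s3"))))
    expect_warning(empty <- filterExpressed(allzero), "no expressed")
    expect_equal(nrow(empty), 0L)
})

test_that("scaledCounts keeps values on the count scale", {
    cs <- tinyCountSet()
    nf <- normFactors(cs, "total")
    sc <- scaledCounts(cs, nf)
    expect_equal(colMeans(sweep(sc, 2, mean(normConstants(nf)), "/")),
                 colMeans(sweep(counts(cs), 2, normConstants(nf), "/")))
    ## equal-depth samples are unchanged
    m <- matrix(c(1L, 2L, 3L, 2L, 1L, 3L), ncol = 2,
                dimnames = list(paste0("g", 1:3), c("a", "b")))
    cs2 <- tinyCountSet(m, groups = c("x", "y"))
    expect_equal(scaledCounts(cs2, "total"), m + 0)
})
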