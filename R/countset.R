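#' Construct a CountSet
#'
#' Bundle a genes-by-samples matrix of non-negative integer counts with a
#' per-sample annotation table into a \linkS4class{CountSet}.
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param design data.frame or \code{DataFrame} with one row per sample;
#'   must contain \code{subject} and \code{group}. Row order must match the
#'   columns of \code{counts}.
#' @param level \code{"lane"} for technical-replicate lanes, \code{"subject"}
#'   for lane-pair-summed counts.
#' @return a \linkS4class{CountSet}.
#' @examples
#' m <- matrix(0:5, nrow = 3, dimnames = list(paste0("g", 1:3), c("a", "b")))
#' d <- data.frame(subject = c("s1", "s2"), group = c("high", "low"))
#' cs <- CountSet(m, d)
#' counts(cs)
#' @export
CountSet <- function(counts, design, level = c("lane", "subject")) {
    level <- match.arg(level)
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    design <- S4Vectors::DataFrame(design, check.names = FALSE)
    if (nrow(design) != ncol(counts))
        stop("design has ", nrow(design), " rows but counts has ",
             ncol(counts), " samples")
    rownames(design) <- colnames(counts)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = design)
    obj <- new("CountSet", se)
    S4Vectors::metadata(obj)$level <- level
    validObject(obj)
    obj
}

#' @describeIn CountSet extract the counts matrix.
#' @param object,x a \code{CountSet}.
#' @export
setMethod("counts", "CountSet", function(object)
    SummarizedExperiment::assay(object, "counts"))

#' @describeIn CountSet per-sample annotation as a data.frame.
#' @export
setMethod("sampleDesign", "CountSet", function(object, ...)
    as.data.frame(SummarizedExperiment::colData(object)))

#' @describeIn CountSet whether samples are lanes or subjects.
#' @export
setMethod("countLevel", "CountSet", function(object) {
    lv <- S4Vectors::metadata(object)$level
    if (is.null(lv)) "lane" else lv
})

setMethod("show", "CountSet", function(object) {
    cat("CountSet (", countLevel(object), " level): ",
        nrow(object), " genes x ", ncol(object), " samples\n", sep = "")
    grp <- table(SummarizedExperiment::colData(object)$group)
    cat("  groups: ", paste(names(grp), grp, sep = "=", collapse = ", "),
        "\n", sep = "")
    tot <- colSums(counts(object))
    cat("  sample totals: ", format(min(tot), big.mark = ","), " - ",
        format(max(tot), big.mark = ","), "\n", sep = "")
})

## ---- tabular input/output ----------------------------------------------

.readTable <- function(path, what) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!startsWith(lines, "#")]
    if (!length(lines) || !nzchar(lines[[1L]]))
        stop("no header in ", what, " file: ", path)
    nfield <- lengths(strsplit(lines, "\t", fixed = TRUE))
    if (length(unique(nfield)) != 1L)
        stop("ragged rows in ", what, " file (fields per line vary): ", path)
    utils::read.delim(text = lines, check.names = FALSE,
                      stringsAsFactors = FALSE)
}

#' Read and write count matrices as tab-separated text
#'
#' The count format is a TSV whose header names the samples, whose first
#' column (\code{gene_id}) holds gene identifiers, and whose cells are
#' non-negative integers. Lines starting with \code{#} are treated as
#' comments. \code{writeCounts} followed by \code{readCounts} is an exact
#' round trip, preserving row and column order.
#'
#' @param path file path.
#' @return \code{readCounts}: an integer matrix with gene ids as rownames
#'   and sample ids as colnames.
#' @export
readCounts <- function(path) {
    df <- .readTable(path, "count")
    if (ncol(df) < 2L) stop("count file needs a gene_id column plus samples")
    genes <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (anyDuplicated(genes)) stop("duplicate gene identifiers in ", path)
    if (anyDuplicated(colnames(m))) stop("duplicate sample identifiers in ", path)
    if (!is.numeric(m) || anyNA(m))
        stop("non-numeric or missing cells in count file ", path)
    bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
    if (nrow(bad)) {
        stop("invalid count (negative or non-integer) for gene '",
             genes[bad[1L, 1L]], "', sample '", colnames(m)[bad[1L, 2L]], "'")
    }
    storage.mode(m) <- "integer"
    rownames(m) <- genes
    m
}

#' @rdname readCounts
#' @param matrix integer matrix (or \code{CountSet}) to write.
#' @param comments optional character vector written as leading
#'   \code{#}-prefixed provenance lines.
#' @export
writeCounts <- function(matrix, path, comments = NULL) {
    if (is(matrix, "CountSet")) matrix <- counts(matrix)
    con <- file(path, "w")
    on.exit(close(con))
    if (length(comments)) writeLines(paste0("# ", comments), con)
    writeLines(paste(c("gene_id", colnames(matrix)), collapse = "\t"), con)
    utils::write.table(data.frame(gene_id = rownames(matrix), matrix,
                                  check.names = FALSE),
                       con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read and write sample-annotation tables
#'
#' A design table is a TSV with one row per sample; it must contain
#' \code{subject} and \code{group} columns, and for lane-level tables the
#' full lane annotation (\code{flow_cell}, \code{lane_number},
#' \code{lane_pair}, \code{batch}, \code{software}, \code{tech_rep},
#' \code{status}).
#'
#' @param path file path.
#' @return \code{readDesignTable}: a data.frame.
#' @export
readDesignTable <- function(path) {
    df <- .readTable(path, "design")
    miss <- setdiff(c("subject", "group"), colnames(df))
    if (length(miss))
        stop("design table lacks column(s): ", paste(miss, collapse = ", "))
    df
}

#' @rdname readDesignTable
#' @param design data.frame to write.
#' @param comments optional \code{#}-prefixed provenance lines.
#' @export
writeDesignTable <- function(design, path, comments = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    if (length(comments)) writeLines(paste0("# ", comments), con)
    suppressWarnings(utils::write.table(as.data.frame(design), con, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = TRUE))
    invisible(path)
}

## ---- lane-pair collapse and expression filter --------------------------

#' Sum technical-replicate lanes to subject-level counts
#'
#' Technical variation between the two lanes carrying the same library is
#' Poisson, so the lanes are summed for all biological-variation analyses.
#' Lanes whose \code{status} is not \code{"retained"} are excluded first;
#' subjects left without exactly two lanes are then an error (strict mode,
#' the default) or are dropped with a warning.
#'
#' @param object a lane-level \linkS4class{CountSet}.
#' @param strict error (rather than drop) on subjects without exactly two
#'   retained lanes.
#' @return a subject-level \linkS4class{CountSet} whose columns are
#'   subjects; \code{colData} keeps the subject-constant lane annotation.
#' @export
sumLanePairs <- function(object, strict = TRUE) {
    stopifnot(is(object, "CountSet"))
    if (countLevel(object) != "lane")
        stop("sumLanePairs expects a lane-level CountSet")
    cd <- sampleDesign(object)
    keep <- if ("status" %in% colnames(cd)) cd$status == "retained"
            else rep(TRUE, nrow(cd))
    m <- counts(object)[, keep, drop = FALSE]
    cd <- cd[keep, , drop = FALSE]
    nlanes <- table(cd$subject)
    bad <- names(nlanes)[nlanes != 2L]
    if (length(bad)) {
        if (strict)
            stop("subject(s) without exactly 2 retained lanes: ",
                 paste(bad, collapse = ", "))
        warning("dropping subject(s) without exactly 2 retained lanes: ",
                paste(bad, collapse = ", "))
        keep2 <- !(cd$subject %in% bad)
        m <- m[, keep2, drop = FALSE]
        cd <- cd[keep2, , drop = FALSE]
    }
    subjects <- unique(cd$subject)
    out <- vapply(subjects, function(s)
        rowSums(m[, cd$subject == s, drop = FALSE]), numeric(nrow(m)))
    out <- matrix(out, nrow = nrow(m))
    dimnames(out) <- list(rownames(m), subjects)
    scd <- cd[match(subjects, cd$subject),
              intersect(c("subject", "group", "flow_cell", "lane_pair",
                          "batch", "software"), colnames(cd)),
              drop = FALSE]
    CountSet(out, scd, level = "subject")
}

#' Keep genes observed at least once
#'
#' Retains exactly the genes with a total count of at least one across all
#' samples. Idempotent; warns when nothing survives.
#'
#' @param object a \linkS4class{CountSet} or a counts matrix.
#' @return object of the same class with unexpressed genes removed.
#' @export
filterExpressed <- function(object) {
    m <- if (is(object, "CountSet")) counts(object) else object
    keep <- rowSums(m) >= 1L
    if (!any(keep)) warning("no expressed genes; returning an empty object")
    if (is(object, "CountSet")) object[keep, ] else m[keep, , drop = FALSE]
}

#' Depth-scaled counts
#'
#' Divides each sample's counts by its normalization constant and multiplies
#' by the mean constant, keeping values on the count scale. This is the
#' scaling used for the mean-variance characterization.
#'
#' @param object a \linkS4class{CountSet} or counts matrix.
#' @param norm a \linkS4class{NormFactors}, or a method name passed to
#'   \code{\link{normFactors}}.
#' @return numeric matrix of scaled counts.
#' @export
scaledCounts <- function(object, norm = "upper_quartile") {
    m <- if (is(object, "CountSet")) counts(object) else object
    if (is.character(norm)) norm <- normFactors(m, method = norm)
    cc <- normConstants(norm)
    stopifnot(length(cc) == ncol(m))
    sweep(m, 2L, cc, "/") * mean(cc)
}
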