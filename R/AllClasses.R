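#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom stats coef
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' CountSet: gene-level sequencing counts with experimental annotation
#'
#' \code{CountSet} extends
#' \linkS4class{SummarizedExperiment} and holds a genes-by-samples matrix of
#' non-negative integer counts in the \code{"counts"} assay, together with
#' per-sample experimental annotation in \code{colData}. Samples may be
#' individual sequencing lanes (technical replicates) or subjects after
#' technical-replicate lanes have been summed with \code{\link{sumLanePairs}};
#' the level is recorded in \code{metadata(x)$level}.
#'
#' @details
#' \code{colData} must contain at least \code{subject} and \code{group}
#' (the two-level response grouping). Lane-level objects additionally carry
#' \code{flow_cell}, \code{lane_number}, \code{lane_pair}, \code{batch},
#' \code{software}, \code{tech_rep} and a \code{status} column used for
#' exclusion bookkeeping (\code{"retained"} lanes enter the analysis;
#' any other value records why a lane was dropped).
#'
#' @slot .Data inherited \code{SummarizedExperiment} representation.
#' @seealso \code{\link{CountSet}} (constructor), \code{\link{sumLanePairs}},
#'   \code{\link{filterExpressed}}
#' @name CountSet-class
#' @aliases CountSet-class
#' @exportClass CountSet
setClass("CountSet", contains = "SummarizedExperiment")

.validCountSet <- function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object)) {
        msg <- c(msg, "assay 'counts' is required")
    } else {
        m <- SummarizedExperiment::assay(object, "counts")
        if (!is.numeric(m)) msg <- c(msg, "counts must be numeric")
        else {
            if (any(!is.finite(m))) msg <- c(msg, "counts must be finite")
            else {
                if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
                if (any(m != round(m))) msg <- c(msg, "counts must be integers")
            }
        }
    }
    if (is.null(rownames(object)) || is.null(colnames(object)))
        msg <- c(msg, "gene and sample identifiers are required as dimnames")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate gene identifiers")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample identifiers")
    cd <- SummarizedExperiment::colData(object)
    miss <- setdiff(c("subject", "group"), colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("colData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    if (length(msg)) msg else TRUE
}
setValidity("CountSet", .validCountSet)

#' Per-sample normalization constants and GLM offsets
#'
#' Produced by \code{\link{normFactors}}. Constants are strictly positive
#' scale factors (total count or nearest-rank 75th-percentile count);
#' offsets are centered log constants entering the GLM linear predictor
#' with coefficient fixed at 1.
#'
#' @slot method one of \code{"none"}, \code{"total"}, \code{"upper_quartile"}.
#' @slot constants named positive numeric, one per sample.
#' @slot offsets named numeric, \code{log(constants)} centered at zero.
#' @exportClass NormFactors
setClass("NormFactors",
    representation(method = "character", constants = "numeric",
                   offsets = "numeric"))

setValidity("NormFactors", function(object) {
    msg <- character()
    if (!object@method %in% c("none", "total", "upper_quartile"))
        msg <- c(msg, "unknown normalization method")
    if (any(object@constants <= 0)) msg <- c(msg, "constants must be positive")
    if (any(!is.finite(object@offsets))) msg <- c(msg, "offsets must be finite")
    if (length(object@constants) != length(object@offsets))
        msg <- c(msg, "constants/offsets length mismatch")
    if (object@method == "none" && any(object@offsets != 0))
        msg <- c(msg, "method 'none' implies zero offsets")
    if (length(msg)) msg else TRUE
})

#' Model design information for per-gene GLMs
#'
#' Produced by \code{\link{designForModel}}: an intercept column, a
#' treatment-coded group indicator and (optionally) treatment-coded blocking
#' contrasts, with unused levels pruned. The slot \code{p} counts the
#' non-intercept columns; this is the model-degrees-of-freedom accounting
#' used throughout (a group-only fit has \code{p = 1}).
#'
#' @slot matrix numeric design matrix (samples x coefficients), full rank.
#' @slot p integer, number of non-intercept columns.
#' @slot blocking which blocking factor the design encodes.
#' @exportClass DesignInfo
setClass("DesignInfo",
    representation(matrix = "matrix", p = "integer", blocking = "character"))

setValidity("DesignInfo", function(object) {
    msg <- character()
    if (qr(object@matrix)$rank < ncol(object@matrix))
        msg <- c(msg, "design matrix is rank deficient")
    if (object@p != ncol(object@matrix) - 1L)
        msg <- c(msg, "p must equal the non-intercept column count")
    if (length(msg)) msg else TRUE
})

#' Per-gene GLM fits under a common variance family
#'
#' Container returned by \code{\link{fitAllGenes}}: one log-link GLM per
#' gene, all sharing a design matrix, offsets and variance family
#' (\code{"poisson"}, \code{"od_poisson"} or \code{"nb"}). The Pearson
#' goodness-of-fit statistic uses the family-appropriate variance
#' (\eqn{\hat y}, \eqn{\hat k \hat y}, or \eqn{\hat y + \phi \hat y^2}).
#'
#' @slot geneIds gene identifiers.
#' @slot family variance family used for every gene.
#' @slot coefficients genes x coefficients matrix.
#' @slot fitted genes x samples matrix of fitted means.
#' @slot pearsonX2 per-gene Pearson statistic.
#' @slot dispersion per-gene dispersion used (phi for NB, k-hat for
#'   od_poisson, 0 for poisson).
#' @slot df reported chi-square reference degrees of freedom, \code{n - p}
#'   with \code{p} the non-intercept parameter count (intercept not counted).
#' @slot residDf residual degrees of freedom \code{n - p - 1}, used by the
#'   quasi-Poisson moment estimator.
#' @slot converged,degenerate per-gene flags; degenerate genes are all-zero.
#' @slot iterations IRLS iteration counts.
#' @slot design the shared \linkS4class{DesignInfo}.
#' @slot offsets the shared per-sample offsets.
#' @slot norm normalization method behind the offsets.
#' @slot meanCount per-gene mean raw count per sample.
#' @exportClass GeneFitSet
setClass("GeneFitSet",
    representation(geneIds = "character", family = "character",
                   coefficients = "matrix", fitted = "matrix",
                   pearsonX2 = "numeric", dispersion = "numeric",
                   df = "numeric", residDf = "numeric",
                   converged = "logical", degenerate = "logical",
                   iterations = "integer", design = "DesignInfo",
                   offsets = "numeric", norm = "character",
                   meanCount = "numeric"))

setValidity("GeneFitSet", function(object) {
    G <- length(object@geneIds)
    msg <- character()
    if (nrow(object@coefficients) != G || nrow(object@fitted) != G ||
        length(object@pearsonX2) != G || length(object@converged) != G)
        msg <- c(msg, "per-gene slots have inconsistent lengths")
    if (any(object@pearsonX2 < 0, na.rm = TRUE))
        msg <- c(msg, "Pearson statistics must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Over-dispersion parameter estimates
#'
#' Produced by \code{\link{estimateDispersions}}. Holds the quasi-Poisson
#' per-gene \code{k}, the per-gene NB dispersion \code{phi} (adjusted
#' profile likelihood), the common dispersion shared by all genes, and the
#' moderated per-gene dispersion shrunk towards the common value with prior
#' weight \code{priorN}.
#'
#' @slot geneIds gene identifiers.
#' @slot perGene per-gene phi estimates (NA for degenerate genes).
#' @slot moderated moderated phi estimates.
#' @slot common the common (global) phi estimate.
#' @slot k per-gene quasi-Poisson dispersion estimates.
#' @slot priorN prior weight used for moderation.
#' @exportClass DispersionSet
setClass("DispersionSet",
    representation(geneIds = "character", perGene = "numeric",
                   moderated = "numeric", common = "numeric",
                   k = "numeric", priorN = "numeric"))

setValidity("DispersionSet", function(object) {
    msg <- character()
    G <- length(object@geneIds)
    if (length(object@perGene) != G || length(object@moderated) != G)
        msg <- c(msg, "per-gene slots must match geneIds")
    if (any(object@perGene < 0, na.rm = TRUE) ||
        any(object@moderated < 0, na.rm = TRUE) ||
        (length(object@common) && object@common < 0))
        msg <- c(msg, "dispersions must be non-negative")
    if (length(msg)) msg else TRUE
})
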