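#' Build the per-gene model design
#'
#' Constructs the shared design matrix for the per-gene GLMs: an intercept,
#' a treatment-coded group indicator, and optionally treatment-coded
#' contrasts for one blocking factor (flow cell, lane-pair position, or
#' library-preparation batch). Factor levels are ordered by sorted label
#' (making the reference level deterministic) and unused levels are pruned
#' before coding. The model-degrees-of-freedom count \code{p} is the number
#' of non-intercept columns: 1 for a group-only design, and
#' \code{1 + (levels - 1)} with a blocking factor.
#'
#' @param design a subject-level \linkS4class{CountSet}, or a data.frame
#'   with one row per sample carrying \code{group} and any blocking column.
#' @param blocking \code{"none"}, \code{"flow_cell"}, \code{"lane_pair"} or
#'   \code{"batch"}.
#' @return a \linkS4class{DesignInfo}.
#' @examples
#' d <- subset(studyDesignReplica(), status == "retained" & tech_rep == 1)
#' modelDF(designForModel(d))                        # 1
#' modelDF(designForModel(d, "flow_cell"))           # 13
#' @export
designForModel <- function(design,
                           blocking = c("none", "flow_cell", "lane_pair",
                                        "batch")) {
    blocking <- match.arg(blocking)
    cd <- if (is(design, "CountSet")) sampleDesign(design)
          else as.data.frame(design)
    if (!"group" %in% colnames(cd)) stop("design lacks a 'group' column")
    grp <- factor(cd$group, levels = sort(unique(as.character(cd$group))))
    if (nlevels(grp) < 2L) stop("group must have two levels")
    if (blocking == "none") {
        X <- stats::model.matrix(~grp)
        colnames(X) <- c("(Intercept)", paste0("group", levels(grp)[2L]))
    } else {
        if (!blocking %in% colnames(cd))
            stop("design lacks a '", blocking, "' column")
        blk <- factor(cd[[blocking]],
                      levels = sort(unique(as.character(cd[[blocking]]))))
        blk <- droplevels(blk)
        X <- stats::model.matrix(~ grp + blk)
        colnames(X) <- c("(Intercept)", paste0("group", levels(grp)[2L]),
                         paste0(blocking, levels(blk)[-1L]))
    }
    q <- qr(X)
    if (q$rank < ncol(X)) {
        aliased <- colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]]
        stop("blocking factor is confounded with the design; aliased ",
             "column(s): ", paste(aliased, collapse = ", "))
    }
    rownames(X) <- rownames(cd)
    new("DesignInfo", matrix = X, p = ncol(X) - 1L, blocking = blocking)
}

#' @describeIn designForModel the design matrix.
#' @param object a \code{DesignInfo}.
#' @export
setMethod("designMatrix", "DesignInfo", function(object) object@matrix)

#' @describeIn designForModel the non-intercept parameter count \code{p}.
#' @export
setMethod("modelDF", "DesignInfo", function(object) object@p)

setMethod("show", "DesignInfo", function(object) {
    cat("DesignInfo: ", nrow(object@matrix), " samples, p = ", object@p,
        " (blocking: ", object@blocking, ")\n", sep = "")
})

## ---- single-gene fitting ------------------------------------------------

.familyFor <- function(family, phi) {
    if (family == "nb" && phi > 0) MASS::negative.binomial(theta = 1 / phi)
    else stats::poisson()
}

.pearsonX2 <- function(y, mu, family, phi = 0, k = 1) {
    v <- switch(family,
                poisson = mu,
                od_poisson = k * mu,
                nb = mu + phi * mu^2)
    num <- (y - mu)^2
    contrib <- ifelse(v <= 1e-10,
                      ifelse(num <= 1e-10, 0, Inf),
                      num / v)
    sum(contrib)
}

#' Fit one gene's log-link GLM
#'
#' Iteratively reweighted least squares (via \code{stats::glm.fit}) for a
#' single gene under the chosen variance family, with offsets entering the
#' linear predictor with coefficient fixed at 1. Convergence uses the
#' relative-deviance criterion (tolerance 1e-8, at most 50 iterations);
#' non-converged fits are flagged and still returned. The
#' \code{"od_poisson"} family fits the Poisson likelihood and estimates
#' \eqn{\hat k} from Pearson residuals post fit (its Pearson statistic,
#' computed with \eqn{\hat k \hat y} in the denominator, is by construction
#' not informative about fit, and equals the residual degrees of freedom).
#'
#' @param y non-negative integer counts, one per sample.
#' @param design a \linkS4class{DesignInfo}.
#' @param offsets per-sample offsets (default zero).
#' @param family \code{"poisson"}, \code{"od_poisson"} or \code{"nb"}.
#' @param phi NB dispersion (required finite and \code{>= 0} for
#'   \code{family = "nb"}; \code{phi = 0} reduces to Poisson).
#' @return list with \code{coefficients}, \code{fitted}, \code{family},
#'   \code{dispersion} (phi or k-hat), \code{converged}, \code{iterations},
#'   \code{pearsonX2}, \code{df} (reported \code{n - p}) and \code{residDf}
#'   (\code{n - p - 1}).
#' @examples
#' di <- designForModel(data.frame(group = c("a", "a", "b")), "none")
#' fitGene(c(2L, 4L, 6L), di)$fitted
#' @export
fitGene <- function(y, design, offsets = NULL,
                    family = c("poisson", "od_poisson", "nb"), phi = 0) {
    family <- match.arg(family)
    X <- designMatrix(design)
    n <- nrow(X)
    stopifnot(length(y) == n)
    if (is.null(offsets)) offsets <- rep(0, n)
    stopifnot(length(offsets) == n)
    if (family == "nb" && (!is.finite(phi) || phi < 0))
        stop("family 'nb' requires a resolvable dispersion phi >= 0")
    fam <- .familyFor(family, if (family == "nb") phi else 0)
    fit <- suppressWarnings(stats::glm.fit(
        x = X, y = y, offset = offsets, family = fam,
        control = stats::glm.control(epsilon = 1e-8, maxit = 50L)))
    mu <- fit$fitted.values
    residDf <- n - ncol(X)
    df <- n - (ncol(X) - 1L)       # reported reference df: intercept not counted
    x2p <- .pearsonX2(y, mu, "poisson")
    disp <- switch(family,
                   poisson = 0,
                   od_poisson = if (residDf > 0) x2p / residDf else NA_real_,
                   nb = phi)
    x2 <- switch(family,
                 poisson = x2p,
                 od_poisson = .pearsonX2(y, mu, "od_poisson", k = disp),
                 nb = .pearsonX2(y, mu, "nb", phi = phi))
    list(coefficients = stats::setNames(fit$coefficients, colnames(X)),
         fitted = mu, family = family, dispersion = disp,
         converged = fit$converged, iterations = fit$iter,
         pearsonX2 = x2, df = df, residDf = residDf,
         degenerate = all(y == 0))
}

#' Fit every gene under one model specification
#'
#' Applies \code{\link{fitGene}} gene by gene with a shared design,
#' normalization offsets and variance family. Per-gene failures are
#' recorded as non-converged degenerate fits rather than aborting the
#' batch; a summary of non-converged genes is reported via \code{message}.
#'
#' @param object a \linkS4class{CountSet} (typically subject level).
#' @param family variance family for all genes.
#' @param phi NB dispersion: a single value or one per gene (e.g. from
#'   \code{\link{geneDispersions}}). Ignored unless \code{family = "nb"}.
#' @param blocking blocking factor passed to \code{\link{designForModel}}.
#' @param norm normalization: a method name for \code{\link{normFactors}},
#'   a \linkS4class{NormFactors}, a numeric offset vector, or \code{NULL}.
#' @return a \linkS4class{GeneFitSet}.
#' @export
fitAllGenes <- function(object, family = c("poisson", "od_poisson", "nb"),
                        phi = NULL, blocking = "none",
                        norm = "upper_quartile") {
    family <- match.arg(family)
    stopifnot(is(object, "CountSet"))
    m <- counts(object)
    G <- nrow(m)
    di <- designForModel(object, blocking)
    no <- .resolveOffsets(norm, m)
    if (family == "nb") {
        if (is.null(phi)) stop("family 'nb' requires phi")
        phi <- rep_len(phi, G)
        if (any(!is.finite(phi) | phi < 0))
            stop("family 'nb' requires finite phi >= 0 for every gene")
    } else phi <- rep(0, G)
    nc <- ncol(designMatrix(di))
    coefs <- matrix(NA_real_, G, nc,
                    dimnames = list(rownames(m), colnames(designMatrix(di))))
    fitted <- matrix(NA_real_, G, ncol(m), dimnames = dimnames(m))
    x2 <- disp <- rep(NA_real_, G)
    conv <- deg <- rep(FALSE, G)
    iters <- rep(0L, G)
    for (g in seq_len(G)) {
        fg <- tryCatch(fitGene(m[g, ], di, no$off, family, phi[g]),
                       error = function(e) NULL)
        if (is.null(fg)) { deg[g] <- TRUE; next }
        coefs[g, ] <- fg$coefficients
        fitted[g, ] <- fg$fitted
        x2[g] <- fg$pearsonX2
        disp[g] <- fg$dispersion
        conv[g] <- fg$converged
        deg[g] <- fg$degenerate
        iters[g] <- fg$iterations
    }
    nbad <- sum(!conv & !deg)
    if (nbad) message(nbad, " gene(s) did not converge in 50 IRLS iterations")
    new("GeneFitSet", geneIds = rownames(m), family = family,
        coefficients = coefs, fitted = fitted, pearsonX2 = x2,
        dispersion = disp,
        df = nrow(designMatrix(di)) - modelDF(di),
        residDf = nrow(designMatrix(di)) - modelDF(di) - 1L,
        converged = conv, degenerate = deg, iterations = iters,
        design = di, offsets = as.numeric(no$off), norm = no$method,
        meanCount = rowMeans(m))
}

#' @describeIn fitAllGenes per-gene Pearson goodness-of-fit statistics.
#' @param object a \code{GeneFitSet}.
#' @export
setMethod("pearsonStats", "GeneFitSet", function(object)
    stats::setNames(object@pearsonX2, object@geneIds))

#' @describeIn fitAllGenes genes x samples matrix of fitted means.
#' @export
setMethod("fittedMeans", "GeneFitSet", function(object) object@fitted)

#' @describeIn fitAllGenes per-gene convergence flags.
#' @export
setMethod("isConverged", "GeneFitSet", function(object)
    stats::setNames(object@converged, object@geneIds))

#' @describeIn fitAllGenes genes x coefficients matrix.
#' @export
setMethod("coef", "GeneFitSet", function(object) object@coefficients)

#' @describeIn fitAllGenes reported chi-square reference degrees of freedom
#'   (\code{n - p}).
#' @export
setMethod("modelDF", "GeneFitSet", function(object) object@df)

setMethod("show", "GeneFitSet", function(object) {
    cat("GeneFitSet: ", length(object@geneIds), " genes, family=",
        object@family, ", blocking=", object@design@blocking,
        ", norm=", object@norm, "\n", sep = "")
    cat("  reference df (n - p): ", object@df, "; converged: ",
        sum(object@converged), "/", length(object@geneIds), "\n", sep = "")
    q <- stats::quantile(object@pearsonX2[is.finite(object@pearsonX2)],
                         c(0.5, 0.99, 1), na.rm = TRUE)
    cat("  Pearson X2 median/99%/max: ",
        paste(format(q, digits = 4L), collapse = " / "), "\n", sep = "")
})

#' Blocking-level contrast coefficients across genes
#'
#' For fits that included a blocking factor, extracts each non-reference
#' level's per-gene contrast coefficient (the difference of that level from
#' the reference level), with columns ordered by run order (sorted level
#' label). These are the distributions summarized in the flow-cell-effect
#' boxplots: without a depth offset their medians track the mid-study
#' sequencing-depth shift; with a total or upper-quartile offset the shift
#' disappears.
#'
#' @param object a \linkS4class{GeneFitSet} fitted with a blocking factor.
#' @return genes x levels matrix of contrast coefficients.
#' @export
setMethod("blockingEffects", "GeneFitSet", function(object, ...) {
    blk <- object@design@blocking
    if (blk == "none")
        stop("fits were made without a blocking factor")
    cols <- grep(paste0("^", blk), colnames(object@coefficients))
    object@coefficients[, cols, drop = FALSE]
})
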