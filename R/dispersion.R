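## Dispersion estimation: quasi-Poisson k per gene, NB phi per gene by
## profile likelihood, a common phi by Cox-Reid adjusted profile likelihood
## (APL), and moderated per-gene phi maximizing APL_g + priorN * mean APL.

.PHI_LO <- 1e-6
.PHI_HI <- 10

## Lean IRLS for the NB log-link GLM, used inside the profile-likelihood
## search where ~10^5 refits are routine. Matches stats::glm.fit with
## MASS::negative.binomial(1/phi) (relative-deviance tol 1e-8, maxit 50);
## equality is asserted in the test suite. phi = 0 gives the Poisson fit.
.nbFit <- function(y, X, off, phi, tol = 1e-8, maxit = 50L) {
    mu <- y + (y == 0) / 6
    eta <- log(mu) - off
    devf <- if (phi > 0)
        function(mu) -2 * sum(stats::dnbinom(y, size = 1 / phi, mu = mu,
                                             log = TRUE))
    else function(mu) -2 * sum(stats::dpois(y, lambda = mu, log = TRUE))
    mu <- exp(eta + off)
    dev <- devf(mu)
    conv <- FALSE
    beta <- rep(NA_real_, ncol(X))
    for (it in seq_len(maxit)) {
        w <- mu / (1 + phi * mu)
        z <- eta + (y - mu) / mu
        sw <- sqrt(w)
        ls <- .lm.fit(X * sw, z * sw)
        beta <- ls$coefficients
        eta <- pmin(pmax(drop(X %*% beta), -30), 300)  # clamp degenerate cells
        mu <- exp(eta + off)
        devnew <- devf(mu)
        if (abs(devnew - dev) < tol * (abs(devnew) + 0.1)) {
            dev <- devnew; conv <- TRUE; break
        }
        dev <- devnew
    }
    list(coefficients = beta, fitted = mu, converged = conv, iterations = it)
}

.nbLogLik <- function(y, mu, phi) {
    mu <- pmax(mu, 1e-10)
    if (phi > 0) sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
    else sum(stats::dpois(y, lambda = mu, log = TRUE))
}

## Cox-Reid adjustment: half log-determinant of the expected information
## for the mean parameters at the profiled beta.
.crAdjust <- function(X, mu, phi) {
    w <- pmax(mu, 1e-8) / (1 + phi * pmax(mu, 1e-8))
    d <- determinant(crossprod(X, X * w), logarithm = TRUE)
    0.5 * as.numeric(d$modulus)
}

## (Adjusted) profile log-likelihood of one gene at a given dispersion.
.aplGene <- function(y, X, off, phi, adjusted = TRUE) {
    fit <- .nbFit(y, X, off, phi)
    ll <- .nbLogLik(y, fit$fitted, phi)
    if (adjusted) ll - .crAdjust(X, fit$fitted, phi) else ll
}

## Maximize a profile objective over log phi in [.PHI_LO, .PHI_HI].
## Golden-section/parabolic search (stats::optimize), tolerance `tol` in
## log phi; 0 is returned when the objective is maximal at the lower
## boundary (likelihood monotone decreasing in phi).
.optimizePhi <- function(negObj, tol = 1e-5) {
    lo <- log(.PHI_LO); hi <- log(.PHI_HI)
    opt <- stats::optimize(negObj, c(lo, hi), tol = tol)
    if (negObj(lo) <= opt$objective + 1e-8) return(0)
    if (opt$minimum >= hi - 10 * tol && negObj(hi) < opt$objective)
        return(.PHI_HI)
    exp(opt$minimum)
}

.dispersionInputs <- function(object, blocking, norm) {
    stopifnot(is(object, "CountSet"))
    m <- counts(object)
    di <- designForModel(object, blocking)
    no <- .resolveOffsets(norm, m)
    list(m = m, X = designMatrix(di), off = no$off,
         informative = rowSums(m) > 0)
}

#' Quasi-Poisson dispersion per gene
#'
#' The moment estimator \eqn{\hat k_g = X^2_g / (n - p - 1)}: the Poisson
#' Pearson statistic divided by the residual degrees of freedom (sample
#' size minus all estimated mean parameters, intercept included). Under
#' Poisson variation \eqn{\hat k} averages 1; values above 1 measure
#' over-dispersion on the linear variance scale Var\eqn{(y) = k\mu}.
#'
#' @param object a \linkS4class{GeneFitSet} with \code{family "poisson"}
#'   (or \code{"od_poisson"}, whose dispersion slot already holds k-hat).
#' @return named per-gene k estimates.
#' @export
estimateK <- function(object) {
    stopifnot(is(object, "GeneFitSet"))
    if (object@residDf <= 0) stop("no residual degrees of freedom")
    k <- switch(object@family,
                poisson = object@pearsonX2 / object@residDf,
                od_poisson = object@dispersion,
                stop("estimateK needs Poisson-family fits"))
    stats::setNames(k, object@geneIds)
}

#' Per-gene NB dispersion by profile likelihood
#'
#' For each gene, maximizes the NB profile log-likelihood in \eqn{\phi}
#' (the regression coefficients are re-fit at every candidate \eqn{\phi}),
#' searching on \eqn{\log\phi} over \eqn{[10^{-6}, 10]} with tolerance
#' \code{1e-5}; the boundary value 0 is returned when the likelihood is
#' monotone decreasing in \eqn{\phi} (e.g. under-dispersed genes whose
#' sample variance is below the mean). With \code{adjusted = TRUE} the
#' Cox-Reid adjusted profile likelihood is maximized instead; this is the
#' flavour the moderated estimator shrinks, so \code{priorN = 0} moderation
#' reproduces it exactly.
#'
#' @param object a subject-level \linkS4class{CountSet}.
#' @param blocking,norm model specification, as in \code{\link{fitAllGenes}}.
#' @param adjusted use the Cox-Reid adjusted profile likelihood.
#' @return named per-gene dispersion estimates; \code{NA} for genes with
#'   no positive count (the dispersion is undefined there).
#' @export
estimatePhiPerGene <- function(object, blocking = "none",
                               norm = "upper_quartile", adjusted = FALSE) {
    inp <- .dispersionInputs(object, blocking, norm)
    G <- nrow(inp$m)
    phi <- rep(NA_real_, G)
    for (g in which(inp$informative)) {
        y <- inp$m[g, ]
        phi[g] <- .optimizePhi(function(l)
            -.aplGene(y, inp$X, inp$off, exp(l), adjusted = adjusted))
    }
    stats::setNames(phi, rownames(inp$m))
}

## Shared APL-vs-dispersion grid: coarse pass over the full range plus a
## refinement around the coarse optimum of the mean APL, giving an
## interpolator accurate where the common maximizer lives.
.aplBarGrid <- function(m, X, off, informative) {
    idx <- which(informative)
    evalBar <- function(l) {
        phi <- exp(l)
        mean(vapply(idx, function(g) .aplGene(m[g, ], X, off, phi), 0))
    }
    base <- seq(log(.PHI_LO), log(.PHI_HI), length.out = 25L)
    bar <- vapply(base, evalBar, 0)
    k <- which.max(bar)
    lo <- base[max(1L, k - 1L)]; hi <- base[min(length(base), k + 1L)]
    ref <- setdiff(seq(lo, hi, length.out = 21L), base)
    barR <- vapply(ref, evalBar, 0)
    ord <- order(c(base, ref))
    grid <- c(base, ref)[ord]
    vals <- c(bar, barR)[ord]
    list(fun = stats::splinefun(grid, vals, method = "fmm"),
         grid = grid, values = vals, evalBar = evalBar)
}

#' Common (global) NB dispersion
#'
#' Maximizes the summed Cox-Reid adjusted profile log-likelihood (APL)
#' across genes in the one-dimensional dispersion, giving the single
#' \eqn{\phi} shared by all genes. The mean APL is evaluated on an adaptive
#' \eqn{\log\phi} grid, interpolated by a cubic spline to locate the
#' optimum, and the estimate is polished by a direct search of the exact
#' mean APL around it. Genes with no positive count carry no dispersion
#' information and are excluded.
#'
#' @inheritParams estimatePhiPerGene
#' @return the common dispersion estimate (a single non-negative number).
#' @export
estimatePhiCommon <- function(object, blocking = "none",
                              norm = "upper_quartile") {
    inp <- .dispersionInputs(object, blocking, norm)
    if (!any(inp$informative)) stop("no informative genes")
    bar <- .aplBarGrid(inp$m, inp$X, inp$off, inp$informative)
    .commonFromBar(bar)
}

.commonFromBar <- function(bar) {
    lo <- log(.PHI_LO); hi <- log(.PHI_HI)
    opt <- stats::optimize(function(l) -bar$fun(l), c(lo, hi), tol = 1e-7)
    lstar <- opt$minimum
    ## polish against the exact mean APL in a neighbourhood of the spline
    ## optimum, then apply the boundary rule
    win <- c(max(lo, lstar - 0.6), min(hi, lstar + 0.6))
    ex <- stats::optimize(function(l) -bar$evalBar(l), win, tol = 1e-6)
    if (bar$evalBar(lo) >= -ex$objective - 1e-8) return(0)
    exp(ex$minimum)
}

#' Moderated per-gene NB dispersion
#'
#' Weighted-likelihood empirical-Bayes shrinkage: \eqn{\tilde\phi_g}
#' maximizes \eqn{APL_g(\phi) + priorN \cdot \overline{APL}(\phi)}, where
#' \eqn{\overline{APL}} is the average Cox-Reid adjusted profile
#' log-likelihood over all informative genes. \code{priorN} (prior weight,
#' in units of pseudo-genes) controls the shrinkage towards the common
#' value: \code{priorN = 0} reproduces the per-gene adjusted estimates and
#' \code{priorN -> Inf} reproduces the common estimate. The shared term is
#' evaluated on the same adaptive grid as \code{\link{estimatePhiCommon}}
#' and interpolated; each gene's own term is evaluated exactly.
#'
#' @inheritParams estimatePhiPerGene
#' @param priorN non-negative prior weight (default 3).
#' @return named per-gene moderated dispersions; \code{NA} for genes with
#'   no positive count.
#' @export
estimatePhiModerated <- function(object, blocking = "none",
                                 norm = "upper_quartile", priorN = 3) {
    stopifnot(priorN >= 0)
    inp <- .dispersionInputs(object, blocking, norm)
    bar <- if (priorN > 0)
        .aplBarGrid(inp$m, inp$X, inp$off, inp$informative) else NULL
    .moderatedFromBar(inp, bar, priorN)
}

.moderatedFromBar <- function(inp, bar, priorN) {
    G <- nrow(inp$m)
    phi <- rep(NA_real_, G)
    for (g in which(inp$informative)) {
        y <- inp$m[g, ]
        negObj <- if (priorN > 0)
            function(l) -(.aplGene(y, inp$X, inp$off, exp(l)) +
                          priorN * bar$fun(l))
        else function(l) -.aplGene(y, inp$X, inp$off, exp(l))
        phi[g] <- .optimizePhi(negObj)
    }
    stats::setNames(phi, rownames(inp$m))
}

#' Estimate all dispersion quantities at once
#'
#' Convenience wrapper computing the quasi-Poisson \eqn{\hat k_g}, the
#' per-gene adjusted-profile-likelihood \eqn{\hat\phi_g}, the common
#' \eqn{\hat\phi} and the moderated \eqn{\tilde\phi_g(priorN)}, sharing the
#' APL grid between the common and moderated estimators.
#'
#' @inheritParams estimatePhiModerated
#' @return a \linkS4class{DispersionSet}.
#' @export
estimateDispersions <- function(object, blocking = "none",
                                norm = "upper_quartile", priorN = 3) {
    inp <- .dispersionInputs(object, blocking, norm)
    pois <- fitAllGenes(object, "poisson", blocking = blocking, norm = norm)
    k <- estimateK(pois)
    bar <- .aplBarGrid(inp$m, inp$X, inp$off, inp$informative)
    common <- .commonFromBar(bar)
    perGene <- .moderatedFromBar(inp, NULL, 0)
    moderated <- if (priorN > 0) .moderatedFromBar(inp, bar, priorN)
                 else perGene
    new("DispersionSet", geneIds = rownames(inp$m), perGene = unname(perGene),
        moderated = unname(moderated), common = common, k = unname(k),
        priorN = priorN)
}

#' @describeIn estimateDispersions the common dispersion.
#' @param object a \code{DispersionSet}.
#' @export
setMethod("commonDispersion", "DispersionSet", function(object) object@common)

#' @describeIn estimateDispersions per-gene dispersions of the requested
#'   type (\code{"moderated"}, \code{"per_gene"} or quasi-Poisson
#'   \code{"k"}).
#' @param type which per-gene estimate to return.
#' @export
setMethod("geneDispersions", "DispersionSet",
    function(object, type = c("moderated", "per_gene", "k")) {
        type <- match.arg(type)
        v <- switch(type, moderated = object@moderated,
                    per_gene = object@perGene, k = object@k)
        stats::setNames(v, object@geneIds)
    })

setMethod("show", "DispersionSet", function(object) {
    cat("DispersionSet: ", length(object@geneIds), " genes\n", sep = "")
    cat("  common phi: ", format(object@common, digits = 4L),
        "  (implied subject CV ", round(100 * sqrt(object@common)), "%)\n",
        sep = "")
    ok <- !is.na(object@moderated)
    cat("  moderated phi (priorN=", object@priorN, "): median ",
        format(stats::median(object@moderated[ok]), digits = 4L),
        ", share < 0.15: ",
        round(100 * mean(object@moderated[ok] < 0.15)), "%\n", sep = "")
})
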