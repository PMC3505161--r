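## Diagnostic surfaces: Pearson GOF records and chi-square QQ data,
## technical-replicate pair QC (pair GOF, MVA, Spearman), and the
## mean-variance characterization with the three candidate variance laws.

#' Per-gene Pearson goodness-of-fit records
#'
#' Extracts the Pearson statistic
#' \eqn{X^2 = \sum_i (y_i - \hat y_i)^2 / Var(\hat y_i)} for every gene,
#' with the family-appropriate variance in the denominator, together with
#' the chi-square reference degrees of freedom (\code{n - p}) and a flag
#' marking low-count genes (mean count per sample below 5), whose
#' statistics the study design places throughout the GOF range.
#'
#' @param object a \linkS4class{GeneFitSet}.
#' @return data.frame with columns \code{gene}, \code{X2}, \code{df},
#'   \code{family}, \code{low_count}.
#' @export
pearsonGOF <- function(object) {
    stopifnot(is(object, "GeneFitSet"))
    data.frame(gene = object@geneIds, X2 = object@pearsonX2,
               df = object@df, family = object@family,
               low_count = object@meanCount < 5,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' QQ data against a chi-square reference
#'
#' Sorted observed statistics paired with theoretical chi-square quantiles
#' at plotting positions \eqn{(i - 0.5)/G}. The top 1\% of observed
#' statistics (\code{ceiling(0.01 G)} of them) are flagged
#' \code{"top1pct"} and the next 4\% \code{"next4pct"}, the coloring used
#' on the GOF QQ displays; observed deciles are attached as the
#' \code{"deciles"} attribute (the tick marks along the top of those
#' displays).
#'
#' @param x2 observed statistics (at least 10, finite values are ranked;
#'   non-finite values are ranked last).
#' @param df common chi-square reference degrees of freedom.
#' @return data.frame (\code{observed}, \code{theoretical}, \code{flag})
#'   sorted ascending, with attributes \code{deciles} and \code{df}.
#' @examples
#' qq <- qqChisq(rchisq(1000, 22), 22)
#' table(qq$flag)
#' @export
qqChisq <- function(x2, df) {
    if (length(x2) < 10L) stop("need at least 10 statistics")
    if (length(df) != 1L || df <= 0) stop("df must be a single positive value")
    G <- length(x2)
    ord <- order(x2)                      # non-finite sort last
    obs <- x2[ord]
    theo <- stats::qchisq((seq_len(G) - 0.5) / G, df = df)
    n1 <- ceiling(0.01 * G)
    n5 <- ceiling(0.05 * G)
    flag <- rep("none", G)
    flag[seq.int(G - n5 + 1L, G)] <- "next4pct"
    flag[seq.int(G - n1 + 1L, G)] <- "top1pct"
    out <- data.frame(observed = obs, theoretical = theo,
                      flag = factor(flag, c("none", "next4pct", "top1pct")),
                      row.names = NULL)
    attr(out, "deciles") <- stats::quantile(x2[is.finite(x2)],
                                            probs = seq(0.1, 0.9, 0.1))
    attr(out, "df") <- df
    out
}

#' Pearson statistics for a technical-replicate lane pair
#'
#' Under Poisson technical variation, a gene's two lane counts split its
#' lane-pair total in proportion to the lane totals. Per gene the expected
#' counts are \eqn{\hat y_l = N_l (y_1 + y_2)/(N_1 + N_2)} and
#' \eqn{X^2 = \sum_l (y_l - \hat y_l)^2/\hat y_l}, asymptotically
#' chi-square with 1 degree of freedom. Genes with a zero pair total are
#' excluded (0/0) and counted in the \code{"nExcluded"} attribute.
#'
#' @param y1,y2 the two lanes' counts for the same genes.
#' @param N1,N2 lane totals (default: sums of \code{y1}, \code{y2}).
#' @return data.frame (\code{gene}, \code{X2}) with attributes
#'   \code{df = 1} and \code{nExcluded}.
#' @export
technicalPairGOF <- function(y1, y2, N1 = sum(y1), N2 = sum(y2)) {
    stopifnot(length(y1) == length(y2), N1 > 0, N2 > 0)
    genes <- names(y1)
    if (is.null(genes)) genes <- paste0("g", seq_along(y1))
    s <- as.numeric(y1) + as.numeric(y2)
    keep <- s > 0
    N1 <- as.numeric(N1); N2 <- as.numeric(N2)
    e1 <- N1 * s[keep] / (N1 + N2)
    e2 <- N2 * s[keep] / (N1 + N2)
    x2 <- (y1[keep] - e1)^2 / e1 + (y2[keep] - e2)^2 / e2
    out <- data.frame(gene = genes[keep], X2 = unname(x2),
                      row.names = NULL, stringsAsFactors = FALSE)
    attr(out, "df") <- 1
    attr(out, "nExcluded") <- sum(!keep)
    out
}

#' MVA (minus-versus-average) coordinates for a lane pair
#'
#' Counts are scaled by total lane counts; restricted to genes positive in
#' both lanes, \eqn{A} is the average and \eqn{M} the difference of the two
#' log2 scaled counts. A centered moving-average smoother of \eqn{M} over
#' \eqn{A} (window 5\% of the points) summarizes the average bias; for
#' unbiased technical replicates it hugs the \eqn{y = 0} line.
#'
#' @inheritParams technicalPairGOF
#' @return data.frame (\code{gene}, \code{A}, \code{M}, \code{smooth})
#'   sorted by \code{A}.
#' @export
mvaPair <- function(y1, y2, N1 = sum(y1), N2 = sum(y2)) {
    stopifnot(length(y1) == length(y2), N1 > 0, N2 > 0)
    genes <- names(y1)
    if (is.null(genes)) genes <- paste0("g", seq_along(y1))
    keep <- y1 > 0 & y2 > 0
    if (sum(keep) < 10L) stop("fewer than 10 mutually positive genes")
    l1 <- log2(y1[keep] / N1)
    l2 <- log2(y2[keep] / N2)
    A <- (l1 + l2) / 2
    M <- l1 - l2
    ord <- order(A)
    A <- A[ord]; M <- M[ord]
    n <- length(A)
    w <- max(1L, round(0.05 * n))
    if (w %% 2L == 0L) w <- w + 1L
    half <- (w - 1L) %/% 2L
    cm <- cumsum(c(0, M))
    lo <- pmax(1L, seq_len(n) - half)
    hi <- pmin(n, seq_len(n) + half)
    smooth <- (cm[hi + 1L] - cm[lo]) / (hi - lo + 1L)
    data.frame(gene = genes[keep][ord], A = unname(A), M = unname(M),
               smooth = unname(smooth), row.names = NULL,
               stringsAsFactors = FALSE)
}

#' Spearman rank correlation of a technical pair
#'
#' Rank correlation (midranks for ties) between the two lanes' counts.
#'
#' @inheritParams technicalPairGOF
#' @return the correlation.
#' @export
spearmanPair <- function(y1, y2) {
    stopifnot(length(y1) == length(y2), length(y1) >= 3L)
    if (stats::sd(y1) == 0 || stats::sd(y2) == 0)
        stop("constant vector: rank correlation undefined")
    stats::cor(y1, y2, method = "spearman")
}

#' Within-group mean and variance of scaled counts
#'
#' For every gene and response group, the sample mean \eqn{\bar x} and
#' unbiased variance \eqn{S^2} of depth-scaled counts (counts divided by
#' the sample's normalization constant and multiplied by the mean constant,
#' staying on the count scale). Computing within groups isolates
#' subject-to-subject (biological) variation from the group contrast; each
#' gene contributes one point per group.
#'
#' @param object a subject-level \linkS4class{CountSet} with at least two
#'   subjects per group.
#' @param norm normalization constants: a \linkS4class{NormFactors} or a
#'   method name (default upper-quartile).
#' @return data.frame (\code{gene}, \code{group}, \code{mean}, \code{var}).
#' @export
groupMeanVariance <- function(object, norm = "upper_quartile") {
    stopifnot(is(object, "CountSet"))
    cd <- sampleDesign(object)
    sc <- scaledCounts(object, norm)
    groups <- sort(unique(as.character(cd$group)))
    pieces <- lapply(groups, function(g) {
        j <- cd$group == g
        if (sum(j) < 2L) stop("group '", g, "' has fewer than 2 subjects")
        sub <- sc[, j, drop = FALSE]
        mn <- rowMeans(sub)
        vr <- rowSums((sub - mn)^2) / (ncol(sub) - 1L)
        data.frame(gene = rownames(sc), group = g, mean = unname(mn),
                   var = unname(vr), row.names = NULL,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, pieces)
}

#' Fit the candidate variance laws to mean-variance points
#'
#' Least-squares fits of the two over-dispersion laws through the origin:
#' the linear law \eqn{S^2 = k\bar x} (over-dispersed Poisson; slope
#' \eqn{\hat k}) and the quadratic law \eqn{S^2 = \bar x + \phi\bar x^2}
#' (negative binomial; \eqn{S^2 - \bar x} regressed on \eqn{\bar x^2},
#' slope \eqn{\hat\phi}). Also returns the three reference curves on the
#' standard-deviation scale for plotting (Poisson identity, linear,
#' quadratic).
#'
#' @param points output of \code{\link{groupMeanVariance}} (or any
#'   data.frame with \code{mean} and \code{var} columns); at least 10
#'   points with positive mean.
#' @return list of class \code{"meanVarFit"} with \code{kLinear},
#'   \code{phiQuad}, and \code{curves(x)} returning a data.frame of SD-scale
#'   curve values.
#' @export
fitVarianceLaws <- function(points) {
    ok <- is.finite(points$mean) & is.finite(points$var) & points$mean > 0
    if (!any(ok)) stop("no points with positive mean")
    x <- points$mean[ok]; v <- points$var[ok]
    if (length(x) > 1L && length(x) < 10L)
        warning("fewer than 10 usable points; slopes will be unstable")
    k <- sum(v * x) / sum(x^2)
    phi <- sum((v - x) * x^2) / sum(x^4)
    curves <- function(xx) data.frame(
        mean = xx,
        sdPoisson = sqrt(xx),
        sdLinear = sqrt(pmax(k * xx, 0)),
        sdQuadratic = sqrt(pmax(xx + phi * xx^2, 0)))
    structure(list(kLinear = k, phiQuad = phi, curves = curves),
              class = "meanVarFit")
}

#' @export
print.meanVarFit <- function(x, ...) {
    cat("meanVarFit: k (linear) = ", format(x$kLinear, digits = 4),
        ";  phi (quadratic) = ", format(x$phiQuad, digits = 4), "\n", sep = "")
    invisible(x)
}

#' Dispersion versus mean summary
#'
#' Pairs each gene's (moderated) dispersion with its mean count on the
#' log10 scale, flags a supplied gene block (e.g. the genes zeroed in one
#' subject), and reports the least-squares slope of dispersion on log10
#' mean over the unflagged genes -- near zero when dispersion is not a
#' function of the mean.
#'
#' @param phi named per-gene dispersions (e.g.
#'   \code{geneDispersions(ds, "moderated")}).
#' @param meanCounts named per-gene mean counts (same genes).
#' @param flagGenes character vector of gene ids to flag (may be empty).
#' @return list with \code{points} (data.frame \code{gene},
#'   \code{log10mean}, \code{phi}, \code{flagged}) and \code{slope}.
#' @export
phiVsMean <- function(phi, meanCounts, flagGenes = character(0)) {
    genes <- names(phi)
    stopifnot(!is.null(genes), setequal(genes, names(meanCounts)))
    meanCounts <- meanCounts[genes]
    pts <- data.frame(gene = genes, log10mean = log10(pmax(meanCounts, 0.5)),
                      phi = unname(phi), flagged = genes %in% flagGenes,
                      row.names = NULL, stringsAsFactors = FALSE)
    ok <- !pts$flagged & is.finite(pts$phi)
    slope <- if (sum(ok) >= 3L)
        unname(stats::coef(stats::lm(phi ~ log10mean, data = pts[ok, ]))[2L])
    else NA_real_
    list(points = pts, slope = slope)
}
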