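#' QQ plot of Pearson GOF statistics
#'
#' Observed versus theoretical chi-square quantiles with the identity line,
#' decile tick marks along the top, the top 1\% of statistics in red and
#' the next 4\% in blue.
#'
#' @param qq output of \code{\link{qqChisq}}.
#' @param main plot title.
#' @param ... passed to \code{plot}.
#' @return invisibly, \code{qq}.
#' @export
plotQQ <- function(qq, main = "Pearson GOF QQ plot", ...) {
    cols <- c(none = "grey30", next4pct = "blue", top1pct = "red")
    plot(qq$theoretical, qq$observed, pch = 20, cex = 0.5,
         col = cols[as.character(qq$flag)],
         xlab = sprintf("Chi-square(%g) quantiles", attr(qq, "df")),
         ylab = "Observed Pearson statistics", main = main, ...)
    graphics::abline(0, 1, col = "grey60")
    graphics::axis(3, at = attr(qq, "deciles"), labels = FALSE,
                   tcl = -0.25)
    invisible(qq)
}

#' Mean-variance plot on the standard-deviation scale
#'
#' Within-group standard deviation against the mean scaled count (square
#' root axes), overlaid with the Poisson identity, the fitted linear
#' (over-dispersed Poisson) and the fitted quadratic (negative binomial)
#' variance laws.
#'
#' @param points output of \code{\link{groupMeanVariance}}.
#' @param fit output of \code{\link{fitVarianceLaws}} (computed from
#'   \code{points} when missing).
#' @param ... passed to \code{plot}.
#' @return invisibly, \code{fit}.
#' @export
plotMeanVariance <- function(points, fit = fitVarianceLaws(points), ...) {
    ok <- points$mean > 0
    plot(sqrt(points$mean[ok]), sqrt(points$var[ok]), pch = 20, cex = 0.4,
         col = "grey50", xlab = "Mean scaled count (square-root axis)",
         ylab = "Within-group SD of scaled counts", axes = FALSE, ...)
    px <- pretty(points$mean[ok])
    graphics::axis(1, at = sqrt(px), labels = px)
    py <- pretty(points$var[ok])
    graphics::axis(2, at = sqrt(sqrt(py)^2), labels = round(sqrt(py), 1))
    graphics::box()
    xx <- seq(0, max(points$mean[ok]), length.out = 400L)
    cv <- fit$curves(xx)
    graphics::lines(sqrt(cv$mean), cv$sdPoisson, col = "darkgreen")
    graphics::lines(sqrt(cv$mean), cv$sdLinear, col = "blue")
    graphics::lines(sqrt(cv$mean), cv$sdQuadratic, col = "red")
    graphics::legend("topleft", bty = "n", lty = 1,
                     col = c("darkgreen", "blue", "red"),
                     legend = c("Poisson", "linear (OD Poisson)",
                                "quadratic (NB)"))
    invisible(fit)
}
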