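#' Per-sample normalization constants and offsets
#'
#' Computes per-sample normalization constants and converts them to
#' log-scale offsets for the count GLMs. Two constants are supported:
#' the total count, and the nearest-rank 75th-percentile count
#' (upper-quartile normalization, robust to a few very high-count genes
#' dominating a sample). Offsets are \code{log(constant)} centered by the
#' mean log constant so that the intercept stays on the count scale;
#' centering does not change fitted-mean ratios or Pearson statistics
#' because the intercept absorbs any common shift.
#'
#' The 75th percentile is taken over the genes expressed somewhere in the
#' dataset (total count >= 1), by the nearest-rank rule: the
#' \code{ceiling(0.75 * n)}-th order statistic. Should that be zero for a
#' sample, the smallest positive count of that sample is used instead, with
#' a warning.
#'
#' @param object a \linkS4class{CountSet} or counts matrix.
#' @param method \code{"upper_quartile"} (default), \code{"total"}, or
#'   \code{"none"} (unit constants, zero offsets).
#' @return a \linkS4class{NormFactors}.
#' @examples
#' m <- matrix(c(1L, 2L, 3L, 4L, 2L, 4L, 6L, 8L), ncol = 2,
#'             dimnames = list(paste0("g", 1:4), c("a", "b")))
#' normConstants(normFactors(m, "total"))
#' normConstants(normFactors(m, "upper_quartile"))
#' @export
normFactors <- function(object,
                        method = c("upper_quartile", "total", "none")) {
    method <- match.arg(method)
    m <- if (is(object, "CountSet")) counts(object) else as.matrix(object)
    ids <- colnames(m)
    if (is.null(ids)) ids <- paste0("sample", seq_len(ncol(m)))
    const <- switch(method,
        none = rep(1, ncol(m)),
        total = {
            tot <- colSums(m)
            if (any(tot <= 0))
                stop("all-zero sample(s): ",
                     paste(ids[tot <= 0], collapse = ", "))
            tot
        },
        upper_quartile = {
            if (any(colSums(m > 0) < 1L))
                stop("each sample needs at least one positive count")
            expressed <- rowSums(m) >= 1L
            sub <- m[expressed, , drop = FALSE]
            r <- ceiling(0.75 * nrow(sub))
            q <- apply(sub, 2L, function(x) sort(x)[r])
            zero <- q <= 0
            if (any(zero)) {
                warning("zero 75th-percentile count for sample(s) ",
                        paste(ids[zero], collapse = ", "),
                        "; falling back to smallest positive count")
                q[zero] <- vapply(which(zero),
                                  function(j) min(sub[sub[, j] > 0, j]), 0)
            }
            q
        })
    names(const) <- ids
    off <- if (method == "none") rep(0, length(const))
           else log(const) - mean(log(const))
    names(off) <- ids
    new("NormFactors", method = method, constants = const, offsets = off)
}

#' @describeIn normFactors the normalization method.
#' @export
setMethod("normMethod", "NormFactors", function(object) object@method)

#' @describeIn normFactors the per-sample constants.
#' @export
setMethod("normConstants", "NormFactors", function(object) object@constants)

#' @describeIn normFactors the centered log-scale offsets (coefficient
#'   fixed at 1 in the GLM linear predictor).
#' @export
setMethod("normOffsets", "NormFactors", function(object) object@offsets)

setMethod("show", "NormFactors", function(object) {
    cat("NormFactors: method=", object@method, ", ",
        length(object@constants), " samples\n", sep = "")
    cat("  constants: ", paste(format(utils::head(object@constants, 4L),
                                      digits = 4L), collapse = ", "),
        if (length(object@constants) > 4L) ", ..." else "", "\n", sep = "")
})

#' Resolve offsets from several argument forms
#'
#' Internal convenience: accepts a \code{NormFactors}, a method name, a bare
#' numeric offset vector, or \code{NULL} (zero offsets).
#' @noRd
.resolveOffsets <- function(norm, m) {
    if (is.null(norm)) {
        list(off = rep(0, ncol(m)), method = "none")
    } else if (is(norm, "NormFactors")) {
        list(off = normOffsets(norm), method = normMethod(norm))
    } else if (is.character(norm)) {
        nf <- normFactors(m, method = norm)
        list(off = normOffsets(nf), method = normMethod(nf))
    } else if (is.numeric(norm)) {
        stopifnot(length(norm) == ncol(m))
        list(off = norm, method = "custom")
    } else stop("cannot interpret 'norm' argument")
}
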