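## Small in-code fixtures shared across test files.

# A tiny subject-level CountSet with two groups.
tinyCountSet <- function(m = NULL, groups = c("a", "a", "b"),
                         level = "subject") {
    if (is.null(m)) {
        m <- matrix(c(2L, 4L, 6L,
                      1L, 0L, 3L,
                      10L, 12L, 9L,
                      0L, 0L, 0L), nrow = 4, byrow = TRUE,
                    dimnames = list(paste0("g", 1:4),
                                    paste0("s", seq_along(groups))))
    }
    d <- data.frame(subject = colnames(m), group = groups)
    CountSet(m, d, level = level)
}

# Intercept-only design for n samples (used for closed-form checks).
interceptDesign <- function(n) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
    new("DesignInfo", matrix = X, p = 0L, blocking = "none")
}

# Subject-level CountSet simulated under the default study layout.
simSubjects <- function(nGenes, dispersion, seed, ...) {
    sim <- simulateExperiment(simConfig(nGenes = nGenes,
                                        dispersion = dispersion,
                                        seed = seed, ...))
    list(subj = filterExpressed(sumLanePairs(sim$counts)), sim = sim)
}

# Exact NB/Poisson log-likelihood maximization over beta (independent
# oracle for the IRLS fitter), with analytic gradient.
oracleFit <- function(y, X, off, phi) {
    nll <- function(b) {
        mu <- exp(pmin(drop(X %*% b) + off, 300))
        if (phi > 0) -sum(dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
        else -sum(dpois(y, lambda = mu, log = TRUE))
    }
    grd <- function(b) {
        mu <- exp(pmin(drop(X %*% b) + off, 300))
        -drop(crossprod(X, (y - mu) / (1 + phi * mu)))
    }
    b0 <- c(log(mean(y) + 0.5), rep(0, ncol(X) - 1L))
    opt <- optim(b0, nll, grd, method = "BFGS",
                 control = list(reltol = 1e-14, maxit = 500))
    opt$par
}
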