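## End-to-end orchestration: simulate -> collapse lanes -> normalize ->
## fit model specifications -> dispersions -> diagnostics, with every
## intermediate serialized as TSV for auditability.

#' A model specification for the comparison pipeline
#'
#' @param family variance family (\code{"poisson"}, \code{"od_poisson"},
#'   \code{"nb"}).
#' @param dispersionSource for NB fits: \code{"moderated"},
#'   \code{"per_gene"}, \code{"common"} or \code{"fixed"}.
#' @param fixedPhi dispersion value when \code{dispersionSource = "fixed"}.
#' @param blocking blocking factor (\code{"none"}, \code{"flow_cell"},
#'   \code{"lane_pair"}, \code{"batch"}).
#' @param norm normalization method (\code{"none"}, \code{"total"},
#'   \code{"upper_quartile"}).
#' @return list of class \code{"modelSpec"}.
#' @export
modelSpec <- function(family = c("nb", "poisson", "od_poisson"),
                      dispersionSource = c("moderated", "per_gene",
                                           "common", "fixed"),
                      fixedPhi = NA_real_,
                      blocking = c("none", "flow_cell", "lane_pair", "batch"),
                      norm = c("upper_quartile", "total", "none")) {
    spec <- list(family = match.arg(family),
                 dispersionSource = match.arg(dispersionSource),
                 fixedPhi = fixedPhi,
                 blocking = match.arg(blocking),
                 norm = match.arg(norm))
    if (spec$family == "nb" && spec$dispersionSource == "fixed" &&
        (!is.finite(fixedPhi) || fixedPhi < 0))
        stop("dispersionSource 'fixed' needs fixedPhi >= 0")
    class(spec) <- "modelSpec"
    spec
}

#' @export
print.modelSpec <- function(x, ...) {
    cat("modelSpec: ", x$family,
        if (x$family == "nb") paste0(" (phi: ", x$dispersionSource,
            if (x$dispersionSource == "fixed") paste0(" = ", x$fixedPhi), ")"),
        ", blocking=", x$blocking, ", norm=", x$norm, "\n", sep = "")
    invisible(x)
}

.specLabel <- function(s)
    paste(c(s$family,
            if (s$family == "nb") s$dispersionSource,
            if (s$blocking != "none") s$blocking,
            s$norm), collapse = "_")

#' Pipeline configuration
#'
#' @param sim a \code{\link{simConfig}} describing the synthetic
#'   experiment, or \code{NULL} to read counts/design from
#'   \code{countsPath}/\code{designPath}.
#' @param countsPath,designPath input TSVs used when \code{sim} is NULL.
#' @param specs list of \code{\link{modelSpec}}s to compare (at least one).
#' @param priorN prior weight for moderated dispersion.
#' @param seed integer seed recorded in every output header and used for
#'   every stochastic stage.
#' @return list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(sim = simConfig(),
                           countsPath = NULL, designPath = NULL,
                           specs = list(
                               modelSpec("poisson"),
                               modelSpec("nb", "moderated")),
                           priorN = 3, seed = 1L) {
    if (is.null(sim) && (is.null(countsPath) || is.null(designPath)))
        stop("either a simConfig or counts/design paths are required")
    if (!length(specs)) stop("at least one modelSpec is required")
    stopifnot(all(vapply(specs, inherits, TRUE, "modelSpec")))
    structure(list(sim = sim, countsPath = countsPath,
                   designPath = designPath, specs = specs,
                   priorN = priorN, seed = as.integer(seed)),
              class = "pipelineConfig")
}

.tsvOut <- function(df, dir, name, seed, stage) {
    path <- file.path(dir, name)
    writeDesignTable(df, path,
                     comments = c("countvar pipeline output",
                                  paste("stage:", stage),
                                  paste("seed:", seed)))
    path
}

#' Run the full variance-structure pipeline
#'
#' Executes the stages in order -- obtain lane counts (simulated or read
#' from disk), collapse technical-replicate lane pairs, filter to expressed
#' genes, compute normalization constants, estimate dispersions, fit every
#' requested model specification, and compute GOF, QQ and mean-variance
#' diagnostics -- writing each intermediate as a commented TSV under
#' \code{outDir}. Given the same configuration and seed the run is
#' reproducible file-for-file.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir output directory (created if missing).
#' @return a report bundle: list with \code{counts} (subject-level
#'   \linkS4class{CountSet}), \code{dispersions}, \code{fits} and
#'   \code{gof} (per model spec), \code{qq}, \code{meanVar},
#'   \code{meanVarFit}, \code{techQC}, \code{files}, \code{provenance}.
#' @export
runPipeline <- function(config, outDir = tempfile("countvar_run_")) {
    stopifnot(inherits(config, "pipelineConfig"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)
    seed <- config$seed
    if (!is.null(config$sim)) {
        cfg <- config$sim
        cfg$seed <- seed
        sim <- simulateExperiment(cfg)
        lanes <- sim$counts
        truthGenes <- data.frame(gene = rownames(counts(lanes)),
                                 mu = sim$truth$mu, phi = sim$truth$phi)
        files["truth_genes"] <- .tsvOut(truthGenes, outDir, "truth_genes.tsv",
                                        seed, "simulate")
    } else {
        m <- readCounts(config$countsPath)
        d <- readDesignTable(config$designPath)
        lanes <- CountSet(m, d, level = "lane")
        sim <- NULL
    }
    files["lane_counts"] <- file.path(outDir, "lane_counts.tsv")
    writeCounts(counts(lanes), files["lane_counts"],
                comments = c("stage: input", paste("seed:", seed)))
    files["lane_design"] <- .tsvOut(sampleDesign(lanes), outDir,
                                    "lane_design.tsv", seed, "input")

    ## technical QC on the first retained lane pair
    cd <- sampleDesign(lanes)
    firstSubj <- cd$subject[1L]
    pair <- counts(lanes)[, cd$subject == firstSubj, drop = FALSE]
    techGof <- technicalPairGOF(pair[, 1L], pair[, 2L])
    techQC <- list(subject = firstSubj,
                   gofMax = max(techGof$X2),
                   spearman = spearmanPair(pair[, 1L], pair[, 2L]))

    subj <- filterExpressed(sumLanePairs(lanes))
    files["subject_counts"] <- file.path(outDir, "subject_counts.tsv")
    writeCounts(counts(subj), files["subject_counts"],
                comments = c("stage: sum_lane_pairs", paste("seed:", seed)))
    nf <- normFactors(subj, "upper_quartile")
    files["norm"] <- .tsvOut(
        data.frame(sample = names(normConstants(nf)),
                   constant = unname(normConstants(nf)),
                   offset = unname(normOffsets(nf)),
                   subject = sampleDesign(subj)$subject,
                   group = sampleDesign(subj)$group),
        outDir, "norm_constants.tsv", seed, "normalize")

    needNB <- any(vapply(config$specs, function(s)
        s$family == "nb" && s$dispersionSource != "fixed", TRUE))
    ds <- if (needNB) estimateDispersions(subj, priorN = config$priorN)
          else NULL
    if (!is.null(ds)) {
        files["dispersions"] <- .tsvOut(
            data.frame(gene = ds@geneIds, phi_pergene = ds@perGene,
                       phi_moderated = ds@moderated, k = ds@k),
            outDir, "dispersions.tsv", seed,
            paste0("dispersion (common=", format(ds@common, digits = 6L),
                   ", priorN=", ds@priorN, ")"))
    }

    fits <- list(); gof <- list(); qq <- list()
    for (s in config$specs) {
        lab <- .specLabel(s)
        phi <- if (s$family != "nb") NULL
               else switch(s$dispersionSource,
                           fixed = s$fixedPhi,
                           common = commonDispersion(ds),
                           per_gene = {
                               pg <- geneDispersions(ds, "per_gene")
                               ifelse(is.na(pg), 0, pg)
                           },
                           moderated = {
                               md <- geneDispersions(ds, "moderated")
                               ifelse(is.na(md), 0, md)
                           })
        f <- fitAllGenes(subj, s$family, phi = phi, blocking = s$blocking,
                         norm = s$norm)
        rec <- pearsonGOF(f)
        fits[[lab]] <- f
        gof[[lab]] <- rec
        qq[[lab]] <- qqChisq(rec$X2[is.finite(rec$X2)], modelDF(f))
        files[paste0("gof_", lab)] <- .tsvOut(rec, outDir,
            paste0("gof_", lab, ".tsv"), seed, paste("gof", lab))
    }

    mv <- groupMeanVariance(subj, nf)
    mvFit <- fitVarianceLaws(mv)
    files["meanvar"] <- .tsvOut(mv, outDir, "meanvar_points.tsv", seed,
                                "mean_variance")
    gofSummary <- do.call(rbind, lapply(names(gof), function(lab) {
        x <- gof[[lab]]$X2[is.finite(gof[[lab]]$X2)]
        data.frame(spec = lab, max = max(x),
                   q99 = unname(stats::quantile(x, 0.99)),
                   median = stats::median(x))
    }))
    files["gof_summary"] <- .tsvOut(gofSummary, outDir, "gof_summary.tsv",
                                    seed, "summary")
    list(counts = subj, norm = nf, dispersions = ds, fits = fits, gof = gof,
         qq = qq, gofSummary = gofSummary, meanVar = mv, meanVarFit = mvFit,
         techQC = techQC, truth = if (is.null(sim)) NULL else sim$truth,
         files = files,
         provenance = list(seed = seed, priorN = config$priorN,
                           specs = vapply(config$specs, .specLabel, ""),
                           packageVersion = as.character(
                               utils::packageVersion("countvar"))))
}

#' Null-simulation check of the chi-square GOF reference
#'
#' Simulates null NB genes (no group effect), computes each gene's Pearson
#' statistic using the sample mean as the fitted value and the TRUE
#' dispersion in the variance, and returns QQ data against the chi-square
#' reference with \code{nSamples - 1} degrees of freedom. This verifies how
#' far the asymptotic chi-square approximation can be trusted at a given
#' sample size: most points sit on the identity line, while the extreme
#' right tail of the observed distribution falls slightly below it.
#'
#' @param nSamples subjects per gene (at least 3); the reference df is
#'   \code{nSamples - 1}.
#' @param nGenes number of simulated genes.
#' @param meanLog10Range log10 range of gene means; the default
#'   \code{c(1, 4)} covers the mid-to-high expression range where the
#'   large-sample question is of interest.
#' @param dispersion dispersion specification as in \code{\link{simConfig}}.
#' @param seed integer seed.
#' @return list with \code{qq} (see \code{\link{qqChisq}}), \code{x2},
#'   \code{df}, \code{meanX2}, and \code{ks} (Kolmogorov-Smirnov distance
#'   of the statistics to the reference).
#' @export
validateChisqAsymptotics <- function(nSamples = 23L, nGenes = 5000L,
                                     meanLog10Range = c(1, 4),
                                     dispersion = "study", seed = 1L) {
    if (nSamples < 3L) stop("need at least 3 samples")
    set.seed(seed)
    mu <- 10^stats::runif(nGenes, meanLog10Range[1L], meanLog10Range[2L])
    phi <- .drawDispersions(nGenes, dispersion)
    x2 <- numeric(nGenes)
    for (g in seq_len(nGenes)) {
        y <- if (phi[g] > 0)
            stats::rnbinom(nSamples, size = 1 / phi[g], mu = mu[g])
        else stats::rpois(nSamples, mu[g])
        yb <- mean(y)
        x2[g] <- if (yb > 0)
            sum((y - yb)^2) / (yb + phi[g] * yb^2) else NA_real_
    }
    x2 <- x2[is.finite(x2)]
    df <- nSamples - 1L
    ks <- suppressWarnings(stats::ks.test(x2, stats::pchisq, df = df))
    list(qq = qqChisq(x2, df), x2 = x2, df = df, meanX2 = mean(x2),
         ks = unname(ks$statistic))
}

#' Subject-to-subject coefficient of variation implied by a dispersion
#'
#' Under the Gamma-Poisson hierarchy behind the NB variance
#' \eqn{\mu + \phi\mu^2}, \eqn{\sqrt\phi} is the coefficient of variation
#' of the Gamma-distributed subject means; reported as a percentage rounded
#' to the nearest integer.
#'
#' @param phi non-negative dispersion.
#' @return CV percentage.
#' @examples
#' impliedCV(0.131)   # 36
#' @export
impliedCV <- function(phi) {
    if (any(phi < 0)) stop("phi must be non-negative")
    round(100 * sqrt(phi))
}
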