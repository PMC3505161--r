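#' Configuration for the synthetic lane-count generator
#'
#' Describes a two-group lane-level sequencing experiment of the kind used
#' to study variance structure in gene counts: subjects from a high and a
#' low response group allocated in pairs to flow cells, two
#' technical-replicate lanes per specimen, per-gene baseline means spanning
#' several orders of magnitude, Gamma-mixed (negative binomial) biological
#' variability, Poisson technical noise, and a mid-study sequencing-depth
#' shift attributable to a control-software upgrade.
#'
#' @param nGenes number of genes.
#' @param nSubjects subjects per group; a single count or a length-2 vector
#'   \code{c(high, low)}. The default \code{c(12, 11)} gives the 23-subject
#'   analysis set used throughout.
#' @param lanesPerSpecimen technical replicates per specimen (2).
#' @param meanLog10Range per-gene baseline means are drawn log10-uniformly
#'   over this interval (default \code{c(0, 5)}: five orders of magnitude
#'   of expression).
#' @param dispersion per-gene NB dispersion specification: a single
#'   non-negative number (point mass; 0 gives pure Poisson counts), a
#'   numeric vector of length \code{nGenes}, or \code{"study"} for a
#'   mixture with most mass below 0.15 and a heavy right tail above 0.25
#'   (82\% uniform on [0.01, 0.15], 13\% uniform on [0.15, 0.25], 5\%
#'   0.25 plus an exponential tail with mean 0.15).
#' @param depthRangeM per-lane total-count interval, in millions.
#' @param depthRegimes optional list \code{list(pre = c(lo, hi),
#'   post = c(lo, hi))} (in millions) overriding the default split of
#'   \code{depthRangeM} at its midpoint; lane depth targets are uniform
#'   within the regime set by the lane's flow cell.
#' @param upgradeAtFlowcell first flow cell processed with the upgraded
#'   software (deeper regime).
#' @param flowcellEffectSd,batchEffectSd log-scale SDs of multiplicative
#'   flow-cell and library-prep-batch effects (default 0).
#' @param deFraction,deLog2fc optional differential expression: fraction of
#'   genes given a group effect of \code{deLog2fc} log2 units (alternating
#'   sign).
#' @param zeroSubject inject one subject whose two lanes are zero for a
#'   random block of genes (see \code{\link{injectZeroSubject}}).
#' @param zeroGeneFraction fraction of genes in the injected zero block.
#' @param seed integer seed; the generator uses one RNG stream seeded once.
#' @return a validated list of class \code{"simConfig"}.
#' @export
simConfig <- function(nGenes = 5000L,
                      nSubjects = c(high = 12L, low = 11L),
                      lanesPerSpecimen = 2L,
                      meanLog10Range = c(0, 5),
                      dispersion = "study",
                      depthRangeM = c(3.7, 10.7),
                      depthRegimes = NULL,
                      upgradeAtFlowcell = 6L,
                      flowcellEffectSd = 0,
                      batchEffectSd = 0,
                      deFraction = 0,
                      deLog2fc = 0,
                      zeroSubject = FALSE,
                      zeroGeneFraction = 0.02,
                      seed = 1L) {
    if (length(nSubjects) == 1L) nSubjects <- c(high = nSubjects, low = nSubjects)
    nSubjects <- as.integer(nSubjects)
    if (is.null(names(nSubjects))) names(nSubjects) <- c("high", "low")
    if (nGenes < 1L) stop("nGenes must be positive")
    if (any(nSubjects < 1L)) stop("subject counts must be positive")
    if (lanesPerSpecimen != 2L)
        stop("only 2 technical-replicate lanes per specimen are supported")
    if (diff(meanLog10Range) < 0) stop("meanLog10Range is inverted")
    if (diff(depthRangeM) < 0 || depthRangeM[1L] <= 0)
        stop("depth interval inverted or non-positive")
    if (is.numeric(dispersion) && any(dispersion < 0))
        stop("dispersions must be non-negative")
    if (is.numeric(dispersion) &&
        !(length(dispersion) %in% c(1L, nGenes)))
        stop("dispersion vector must have length 1 or nGenes")
    if (is.character(dispersion) && dispersion != "study")
        stop("unknown dispersion specification")
    if (deFraction < 0 || deFraction > 1) stop("deFraction out of [0, 1]")
    if (zeroGeneFraction < 0 || zeroGeneFraction >= 1)
        stop("zeroGeneFraction out of [0, 1)")
    cfg <- list(nGenes = as.integer(nGenes), nSubjects = nSubjects,
                lanesPerSpecimen = 2L, meanLog10Range = meanLog10Range,
                dispersion = dispersion, depthRangeM = depthRangeM,
                depthRegimes = depthRegimes,
                upgradeAtFlowcell = as.integer(upgradeAtFlowcell),
                flowcellEffectSd = flowcellEffectSd,
                batchEffectSd = batchEffectSd,
                deFraction = deFraction, deLog2fc = deLog2fc,
                zeroSubject = isTRUE(zeroSubject),
                zeroGeneFraction = zeroGeneFraction,
                seed = as.integer(seed))
    class(cfg) <- "simConfig"
    cfg
}

#' @export
print.simConfig <- function(x, ...) {
    cat("simConfig: ", x$nGenes, " genes; ",
        paste(names(x$nSubjects), x$nSubjects, sep = "=", collapse = "+"),
        " subjects x 2 lanes; depth ", x$depthRangeM[1L], "-",
        x$depthRangeM[2L], "M; seed ", x$seed, "\n", sep = "")
    invisible(x)
}

.drawDispersions <- function(n, spec) {
    if (is.numeric(spec)) return(rep_len(spec, n))
    ## "study" mixture: mostly small dispersions, heavy right tail
    comp <- sample.int(3L, n, replace = TRUE, prob = c(0.82, 0.13, 0.05))
    phi <- numeric(n)
    phi[comp == 1L] <- stats::runif(sum(comp == 1L), 0.01, 0.15)
    phi[comp == 2L] <- stats::runif(sum(comp == 2L), 0.15, 0.25)
    phi[comp == 3L] <- 0.25 + stats::rexp(sum(comp == 3L), rate = 1 / 0.15)
    phi
}

## Balanced allocation: one high and one low subject per flow cell, leftover
## subjects on their own flow cell; within a flow cell the high subject goes
## to lanes 1-4 or 5-8 at random and the specimen pair to the first or
## second pair of its half.
.allocateLanes <- function(nHigh, nLow, upgradeAt) {
    nPair <- min(nHigh, nLow)
    nFC <- max(nHigh, nLow)
    subj <- c(sprintf("H%02d", seq_len(nHigh)), sprintf("L%02d", seq_len(nLow)))
    grp <- rep(c("high", "low"), c(nHigh, nLow))
    fc <- integer(nHigh + nLow)
    fc[seq_len(nPair)] <- seq_len(nPair)                     # paired highs
    fc[nHigh + seq_len(nPair)] <- seq_len(nPair)             # paired lows
    extra <- setdiff(seq_along(subj), c(seq_len(nPair), nHigh + seq_len(nPair)))
    fc[extra] <- nPair + seq_along(extra)
    lanes <- lapply(seq_along(subj), function(i) {
        paired <- fc[i] <= nPair
        highHalf <- stats::runif(1L) < 0.5                   # lanes 1-4?
        half <- if (grp[i] == "high") highHalf else !highHalf
        if (!paired) half <- stats::runif(1L) < 0.5
        slotInHalf <- stats::runif(1L) < 0.5                 # first two lanes?
        base <- if (half) 0L else 4L
        first <- base + (if (slotInHalf) 1L else 3L)
        pairSlot <- (base %/% 2L) + (if (slotInHalf) 1L else 2L)  # 1..4
        data.frame(subject = subj[i], group = grp[i],
                   flow_cell = sprintf("FC%02d", fc[i]),
                   lane_number = c(first, first + 1L),
                   lane_pair = sprintf("P%d", pairSlot),
                   tech_rep = 1:2, stringsAsFactors = FALSE)
    })
    des <- do.call(rbind, lanes)
    ## library batches of four subjects in processing (flow cell) order, so
    ## that batches mix the two response groups
    prepOrder <- subj[order(fc, grp)]
    batchOf <- ceiling(match(des$subject, prepOrder) / 4)
    des$batch <- sprintf("B%d", batchOf)
    fcNum <- as.integer(sub("FC", "", des$flow_cell))
    des$software <- ifelse(fcNum < upgradeAt, "SCS_2.01", "SCS_2.4")
    des$status <- "retained"
    des$sample <- paste0(des$subject, "_L", des$tech_rep)
    des[order(fcNum, des$lane_number), ]
}

#' Simulate a lane-level count experiment
#'
#' Draws counts under the Gamma-Poisson hierarchy: each gene has a baseline
#' mean \eqn{\mu_g} (log10-uniform over \code{meanLog10Range}); each
#' subject's expression rate is \eqn{\lambda_{gs} = \mu_g m_{gs}} with
#' \eqn{m_{gs} \sim} Gamma(shape \eqn{1/\phi_g}, scale \eqn{\phi_g}) so that
#' E\eqn{[m] = 1} and Var\eqn{[m] = \phi_g} (for \eqn{\phi_g = 0},
#' \eqn{m \equiv 1} and counts are Poisson); group, flow-cell and batch
#' effects act multiplicatively; and each lane's count is Poisson with mean
#' \eqn{\lambda_{gs} d_l}, where the lane depth factor \eqn{d_l} scales the
#' expected lane total to a target drawn uniformly within the lane's depth
#' regime. Marginally over subjects each gene is negative binomial with
#' variance \eqn{\mu + \phi \mu^2}.
#'
#' All randomness comes from one stream seeded once with \code{config$seed};
#' draws are ordered gene-major (means, dispersions, effect assignment,
#' lane allocation, depths, subject multipliers, effects, counts), so equal
#' configurations give byte-identical output.
#'
#' @param config a \code{\link{simConfig}}.
#' @return list with elements \code{counts} (a lane-level
#'   \linkS4class{CountSet}) and \code{truth} (list of generating values:
#'   \code{mu}, \code{phi}, \code{multipliers} (genes x subjects),
#'   \code{depthFactors}, \code{laneTargets}, \code{deGenes},
#'   \code{deLog2fc}, \code{flowcellEffects}, \code{batchEffects},
#'   \code{zero}).
#' @examples
#' sim <- simulateExperiment(simConfig(nGenes = 200, seed = 7))
#' sim$counts
#' @export
simulateExperiment <- function(config) {
    stopifnot(inherits(config, "simConfig"))
    set.seed(config$seed)
    G <- config$nGenes
    r <- config$meanLog10Range
    mu <- 10^stats::runif(G, r[1L], r[2L])
    phi <- .drawDispersions(G, config$dispersion)
    deGenes <- integer(0)
    deSign <- numeric(0)
    if (config$deFraction > 0 && config$deLog2fc != 0) {
        deGenes <- sample.int(G, max(1L, round(config$deFraction * G)))
        deSign <- rep_len(c(1, -1), length(deGenes))
    }
    des <- .allocateLanes(config$nSubjects[["high"]], config$nSubjects[["low"]],
                          config$upgradeAtFlowcell)
    L <- nrow(des)
    subjects <- unique(des$subject)
    S <- length(subjects)

    ## lane depth targets, uniform within the flow cell's regime
    regimes <- config$depthRegimes
    if (is.null(regimes)) {
        mid <- mean(config$depthRangeM)
        regimes <- list(pre = c(config$depthRangeM[1L], mid),
                        post = c(mid, config$depthRangeM[2L]))
    }
    pre <- des$software == "SCS_2.01"
    targets <- numeric(L)
    targets[pre] <- stats::runif(sum(pre), regimes$pre[1L], regimes$pre[2L])
    targets[!pre] <- stats::runif(sum(!pre), regimes$post[1L], regimes$post[2L])
    targets <- targets * 1e6
    d <- targets / sum(mu)

    ## subject-level Gamma rate multipliers, gene-major
    mult <- matrix(1, G, S, dimnames = list(NULL, subjects))
    pos <- phi > 0
    if (any(pos)) {
        sh <- rep(1 / phi[pos], S)
        mult[pos, ] <- stats::rgamma(sum(pos) * S, shape = sh, scale = 1 / sh)
    }

    fcs <- unique(des$flow_cell)
    fcEff <- stats::rnorm(length(fcs), 0, config$flowcellEffectSd)
    names(fcEff) <- fcs
    batches <- unique(des$batch)
    bEff <- stats::rnorm(length(batches), 0, config$batchEffectSd)
    names(bEff) <- batches

    subjIdx <- match(des$subject, subjects)
    rate <- mu * mult[, subjIdx, drop = FALSE]
    if (length(deGenes)) {
        fc2 <- 2^(deSign * config$deLog2fc)
        highLanes <- des$group == "high"
        rate[deGenes, highLanes] <- rate[deGenes, highLanes] * fc2
    }
    laneScale <- d * exp(fcEff[des$flow_cell] + bEff[des$batch])
    rate <- sweep(rate, 2L, laneScale, "*")
    y <- matrix(stats::rpois(G * L, rate), G, L)
    dimnames(y) <- list(sprintf("g%05d", seq_len(G)), des$sample)
    cs <- CountSet(y, des, level = "lane")
    truth <- list(mu = mu, phi = phi, multipliers = mult,
                  depthFactors = stats::setNames(d, des$sample),
                  laneTargets = stats::setNames(targets, des$sample),
                  deGenes = rownames(y)[deGenes],
                  deLog2fc = if (length(deGenes)) deSign * config$deLog2fc
                             else numeric(0),
                  flowcellEffects = fcEff, batchEffects = bEff,
                  zero = NULL)
    if (config$zeroSubject) {
        cs <- injectZeroSubject(cs, config$zeroGeneFraction)
        truth$zero <- S4Vectors::metadata(cs)$zeroInjection
    }
    list(counts = cs, truth = truth)
}

#' Zero out one subject's lanes for a block of genes
#'
#' Emulates the anomaly in which both technical replicates of one subject
#' have zero counts for a sizeable block of genes (the phenomenon behind the
#' spike of elevated moderated dispersion at mid-to-high means). All other
#' cells are untouched. The affected subject and gene block are recorded in
#' \code{metadata(x)$zeroInjection}.
#'
#' @param object a lane-level \linkS4class{CountSet}.
#' @param geneFraction fraction of genes zeroed (in \code{[0, 1)}); 0 is a
#'   no-op.
#' @param subject subject identifier; default picks one at random from the
#'   current RNG stream.
#' @return the modified \linkS4class{CountSet}.
#' @export
injectZeroSubject <- function(object, geneFraction, subject = NULL) {
    stopifnot(is(object, "CountSet"))
    if (geneFraction < 0 || geneFraction >= 1)
        stop("geneFraction out of [0, 1)")
    cd <- sampleDesign(object)
    if (is.null(subject)) subject <- sample(unique(cd$subject), 1L)
    lanes <- which(cd$subject == subject)
    if (!length(lanes)) stop("subject not present in design: ", subject)
    if (geneFraction == 0) return(object)
    nz <- round(geneFraction * nrow(object))
    genes <- sort(sample.int(nrow(object), nz))
    m <- counts(object)
    m[genes, lanes] <- 0L
    SummarizedExperiment::assay(object, "counts") <- m
    S4Vectors::metadata(object)$zeroInjection <-
        list(subject = subject, genes = rownames(m)[genes])
    validObject(object)
    object
}

#' A deterministic replica of the study's lane allocation
#'
#' Reconstructs the published experimental layout for design accounting:
#' 25 subjects (12 high and 13 low responders), flow cells carrying one
#' subject per group (the odd low responder fills a 13th flow cell), four
#' lane-pair positions per flow cell, seven library-preparation batches,
#' and the upgrade of the sequencer control software before flow cell 6.
#' Two subjects are excluded as in the study -- one low responder whose
#' unstimulated lanes failed sequencing (the sole member of its library
#' batch) and one high responder discarded after technical-replicate QC --
#' leaving 23 retained subjects that span 13 flow cells, 4 lane-pair
#' positions and 6 observed batches. This is a synthetic reconstruction of
#' the design, not the deposited annotation.
#'
#' @return a lane-level design data.frame (two rows per subject) with a
#'   \code{status} column (\code{"retained"}, \code{"failed_sequencing"},
#'   \code{"discarded_qc"}).
#' @examples
#' d <- studyDesignReplica()
#' table(d$status) / 2
#' @export
studyDesignReplica <- function() {
    nHigh <- 12L; nLow <- 13L
    subj <- c(sprintf("H%02d", seq_len(nHigh)), sprintf("L%02d", seq_len(nLow)))
    grp <- rep(c("high", "low"), c(nHigh, nLow))
    fc <- c(seq_len(nHigh), seq_len(nLow))            # L13 alone on FC13
    ## deterministic lane-pair slots cycling over the four positions;
    ## high subject of FC i gets half by parity, low the other half
    rows <- lapply(seq_along(subj), function(i) {
        half <- if (grp[i] == "high") fc[i] %% 2L == 1L else fc[i] %% 2L == 0L
        slotFirst <- (fc[i] %/% 2L) %% 2L == 0L
        base <- if (half) 0L else 4L
        first <- base + (if (slotFirst) 1L else 3L)
        pairSlot <- (base %/% 2L) + (if (slotFirst) 1L else 2L)
        data.frame(subject = subj[i], group = grp[i],
                   flow_cell = sprintf("FC%02d", fc[i]),
                   lane_number = c(first, first + 1L),
                   lane_pair = sprintf("P%d", pairSlot),
                   tech_rep = 1:2, stringsAsFactors = FALSE)
    })
    des <- do.call(rbind, rows)
    ## batches of four subjects in processing (flow cell) order, mixing the
    ## response groups; the failed subject L05 sits alone in batch 7, so
    ## retained lanes span six batches
    failedSubject <- "L05"; discardedSubject <- "H08"
    others <- setdiff(subj[order(fc, grp)], failedSubject)
    batchOf <- stats::setNames(sprintf("B%d", ceiling(seq_along(others) / 4)),
                               others)
    batchOf[failedSubject] <- "B7"
    des$batch <- unname(batchOf[des$subject])
    fcNum <- as.integer(sub("FC", "", des$flow_cell))
    des$software <- ifelse(fcNum < 6L, "SCS_2.01", "SCS_2.4")
    des$status <- "retained"
    des$status[des$subject == failedSubject] <- "failed_sequencing"
    des$status[des$subject == discardedSubject] <- "discarded_qc"
    des$sample <- paste0(des$subject, "_L", des$tech_rep)
    rownames(des) <- des$sample
    des[order(fcNum, des$lane_number), ]
}
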