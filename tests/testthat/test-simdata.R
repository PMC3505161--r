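test_that("simConfig validates its domain", {
    expect_error(simConfig(nGenes = 0), "nGenes")
    expect_error(simConfig(nSubjects = c(high = 0L, low = 3L)), "positive")
    expect_error(simConfig(depthRangeM = c(10.7, 3.7)), "inverted")
    expect_error(simConfig(dispersion = -0.1), "non-negative")
    expect_error(simConfig(dispersion = c(0.1, 0.2)), "length")
})

test_that("zero dispersion gives Poisson counts (variance equals mean)", {
    cfg <- simConfig(nGenes = 1000, dispersion = 0,
                     depthRegimes = list(pre = c(7, 7), post = c(7, 7)),
                     seed = 51)
    sim <- simulateExperiment(cfg)
    m <- counts(sim$counts)
    expect_equal(ncol(m), 46L)
    keep <- rowMeans(m) > 1
    ratio <- apply(m[keep, ], 1, stats::var) / rowMeans(m[keep, ])
    expect_gt(mean(ratio), 0.9)
    expect_lt(mean(ratio), 1.1)
})

test_that("same seed reproduces the experiment exactly", {
    cfg <- simConfig(nGenes = 150, seed = 99)
    a <- simulateExperiment(cfg)
    b <- simulateExperiment(cfg)
    expect_identical(counts(a$counts), counts(b$counts))
    expect_identical(a$truth, b$truth)
})

test_that("within-group mean-variance cloud tracks the quadratic law", {
    ## phi = 0.131 point mass; the quadratic regression on one seeded
    ## replicate recovers the generating dispersion
    res <- simSubjects(3000, 0.131, seed = 61)
    mv <- groupMeanVariance(res$subj)
    fit <- fitVarianceLaws(mv)
    expect_lt(abs(fit$phiQuad - 0.131) / 0.131, 0.15)
})

test_that("design balance: one subject per group per paired flow cell", {
    sim <- simulateExperiment(simConfig(nGenes = 20, seed = 5))
    d <- sampleDesign(sim$counts)
    subj <- unique(d[, c("subject", "group", "flow_cell")])
    ## every subject sits on exactly one flow cell
    expect_equal(nrow(subj), length(unique(subj$subject)))
    tab <- table(subj$flow_cell, subj$group)
    paired <- rowSums(tab) == 2L
    expect_true(all(tab[paired, ] == 1L))
    ## groups occupy opposite lane halves within a paired flow cell
    d$half <- ifelse(d$lane_number <= 4, "1-4", "5-8")
    for (fc in rownames(tab)[paired]) {
        sub <- d[d$flow_cell == fc, ]
        expect_equal(length(unique(paste(sub$group, sub$half))), 2L)
    }
    ## batches mix the groups (not confounded)
    expect_s4_class(designForModel(unique(d[, c("subject", "group", "batch")]),
                                   "batch"), "DesignInfo")
})

test_that("per-gene means of depth-scaled counts recover the truth", {
    cfg <- simConfig(nGenes = 600, dispersion = 0, seed = 52)
    sim <- simulateExperiment(cfg)
    sc <- sweep(counts(sim$counts), 2, sim$truth$depthFactors, "/")
    mn <- rowMeans(sc)
    se <- apply(sc, 1, stats::sd) / sqrt(ncol(sc))
    ok <- se > 0
    coverage <- mean(abs(mn[ok] - sim$truth$mu[ok]) <= 3 * se[ok])
    expect_gte(coverage, 0.95)
})

test_that("lane-pair sums follow the NB law at fixed dispersion", {
    phi <- 0.2
    cfg <- simConfig(nGenes = 200, dispersion = phi,
                     meanLog10Range = c(2, 3),
                     depthRegimes = list(pre = c(7, 7), post = c(7, 7)),
                     seed = 52)
    sim <- simulateExperiment(cfg)
    ps <- counts(sumLanePairs(sim$counts))
    pairD <- tapply(sim$truth$depthFactors,
                    sampleDesign(sim$counts)$subject, sum)[colnames(ps)]
    pass <- vapply(seq_len(nrow(ps)), function(g) {
        mu <- sim$truth$mu[g] * mean(pairD)
        y <- ps[g, ]
        cuts <- unique(stats::qnbinom(seq(0.2, 0.8, 0.2),
                                      size = 1 / phi, mu = mu))
        f <- cut(y, c(-1, cuts, Inf))
        p <- diff(c(0, stats::pnbinom(cuts, size = 1 / phi, mu = mu), 1))
        suppressWarnings(stats::chisq.test(
            tabulate(as.integer(f), nbins = nlevels(f)),
            p = p)$p.value) > 0.01
    }, TRUE)
    expect_gte(mean(pass), 0.95)
})

test_that("injectZeroSubject zeroes exactly the requested block", {
    sim <- simulateExperiment(simConfig(nGenes = 1000, seed = 7))
    cs <- sim$counts
    expect_identical(counts(injectZeroSubject(cs, 0, subject = "H01")),
                     counts(cs))
    set.seed(1)
    z <- injectZeroSubject(cs, 0.1, subject = "H01")
    info <- S4Vectors::metadata(z)$zeroInjection
    expect_equal(length(info$genes), 100L)
    lanes <- sampleDesign(cs)$subject == "H01"
    expect_equal(sum(lanes), 2L)
    expect_true(all(counts(z)[info$genes, lanes] == 0L))
    same <- counts(z)[setdiff(rownames(z), info$genes), ]
    expect_identical(same, counts(cs)[setdiff(rownames(cs), info$genes), ])
    expect_error(injectZeroSubject(cs, 0.1, subject = "nope"), "not present")
})

test_that("zeroed subject inflates moderated dispersion at matched means", {
    cfg <- simConfig(nGenes = 250, dispersion = 0.05,
                     meanLog10Range = c(2, 4), zeroSubject = TRUE,
                     zeroGeneFraction = 0.2, seed = 71)
    sim <- simulateExperiment(cfg)
    subj <- filterExpressed(sumLanePairs(sim$counts))
    md <- estimatePhiModerated(subj, priorN = 3)
    flagged <- rownames(subj) %in% sim$truth$zero$genes
    expect_gt(stats::median(md[flagged], na.rm = TRUE),
              stats::median(md[!flagged], na.rm = TRUE))
    pv <- phiVsMean(md, rowMeans(counts(subj)), sim$truth$zero$genes)
    expect_equal(sum(pv$points$flagged), sum(flagged))
})
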