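test_that("design accounting matches the study layout", {
    d <- subset(studyDesignReplica(), status == "retained" & tech_rep == 1)
    expect_equal(nrow(d), 23L)
    expect_equal(modelDF(designForModel(d, "none")), 1L)
    expect_equal(modelDF(designForModel(d, "lane_pair")), 4L)
    expect_equal(modelDF(designForModel(d, "flow_cell")), 13L)
    expect_equal(modelDF(designForModel(d, "batch")), 6L)
    ## empty levels are pruned: restricting to two flow cells drops the rest
    sub <- d[d$flow_cell %in% c("FC01", "FC02"), ]
    expect_equal(modelDF(designForModel(sub, "flow_cell")), 2L)
})

test_that("confounded blocking factors are reported by name", {
    d <- data.frame(subject = paste0("s", 1:6),
                    group = rep(c("a", "b"), each = 3),
                    batch = rep(c("b1", "b2"), each = 3))
    expect_error(designForModel(d, "batch"), "confounded.*batchb2")
})

test_that("intercept-only and group fits hit their closed forms", {
    di0 <- interceptDesign(3)
    f <- fitGene(c(2L, 4L, 6L), di0)
    expect_equal(unname(f$fitted), rep(4, 3), tolerance = 1e-7)
    ## NB with any fixed phi has the same intercept-only ML mean
    fnb <- fitGene(c(2L, 4L, 6L), di0, family = "nb", phi = 0.7)
    expect_equal(unname(fnb$fitted), rep(4, 3), tolerance = 1e-6)
    ## group model without offset fits the group means
    dg <- designForModel(data.frame(group = c("a", "a", "b", "b")))
    fg <- fitGene(c(2L, 4L, 9L, 11L), dg)
    expect_equal(unname(fg$fitted), c(3, 3, 10, 10), tolerance = 1e-7)
    ## reported df drops only non-intercept parameters; residual df all
    expect_equal(fg$df, 3)
    expect_equal(fg$residDf, 2)
})

test_that("quasi-Poisson dispersion follows the moment estimator", {
    f <- fitGene(c(0L, 4L), interceptDesign(2))
    expect_equal(f$pearsonX2, 4)            # (0-2)^2/2 + (4-2)^2/2
    expect_equal(f$residDf, 1)
    fo <- fitGene(c(0L, 4L), interceptDesign(2), family = "od_poisson")
    expect_equal(fo$dispersion, 4)          # k-hat = X2 / residual df
    expect_equal(fo$pearsonX2, fo$residDf)  # od_poisson X2 is df by design
    fz <- fitGene(c(3L, 3L), interceptDesign(2), family = "od_poisson")
    expect_equal(fz$dispersion, 0)          # y == fitted
})

test_that("Poisson and NB(phi = 0) fits coincide", {
    res <- simSubjects(40, 0.2, seed = 91)
    fp <- fitAllGenes(res$subj, "poisson")
    f0 <- fitAllGenes(res$subj, "nb", phi = 0)
    expect_equal(coef(fp), coef(f0), tolerance = 1e-9)
    expect_equal(pearsonStats(fp), pearsonStats(f0), tolerance = 1e-9)
})

test_that("IRLS matches direct likelihood maximization on random genes", {
    res <- simSubjects(20, 0.15, seed = 92, meanLog10Range = c(1, 3))
    m <- counts(res$subj)
    di <- designForModel(res$subj)
    X <- designMatrix(di)
    off <- normOffsets(normFactors(res$subj))
    for (g in seq_len(nrow(m))) {
        irls <- fitGene(m[g, ], di, off, "nb", phi = 0.15)
        direct <- oracleFit(m[g, ], X, off, 0.15)
        expect_lt(max(abs(unname(irls$coefficients) - direct)), 1e-6)
    }
})

test_that("internal IRLS agrees with glm.fit for the NB family", {
    set.seed(3)
    X <- cbind(1, rep(0:1, c(12, 11)))
    off <- rnorm(23, 0, 0.2)
    for (phi in c(0.05, 0.4)) {
        y <- rnbinom(23, size = 1 / phi, mu = 150)
        mine <- countvar:::.nbFit(y, X, off, phi)
        ref <- suppressWarnings(glm.fit(
            x = X, y = y, offset = off,
            family = MASS::negative.binomial(theta = 1 / phi),
            control = glm.control(epsilon = 1e-8, maxit = 50)))
        expect_equal(unname(mine$coefficients), unname(ref$coefficients),
                     tolerance = 1e-7)
    }
})

test_that("shifting every offset leaves Pearson statistics unchanged", {
    res <- simSubjects(60, 0.131, seed = 93)
    off <- normOffsets(normFactors(res$subj))
    f1 <- fitAllGenes(res$subj, "nb", phi = 0.131, norm = off)
    f2 <- fitAllGenes(res$subj, "nb", phi = 0.131, norm = off + 1)
    expect_equal(pearsonStats(f1), pearsonStats(f2), tolerance = 1e-8)
})

test_that("fitted means are invariant to blocking-level relabeling", {
    res <- simSubjects(30, 0.1, seed = 94)
    cs <- res$subj
    f1 <- fitAllGenes(cs, "poisson", blocking = "batch")
    cd <- sampleDesign(cs)
    relab <- c(B1 = "Bz", B2 = "By", B3 = "Bx", B4 = "Bw", B5 = "Bv",
               B6 = "Bu")
    cd$batch <- unname(relab[cd$batch])
    cs2 <- CountSet(counts(cs), cd, level = "subject")
    f2 <- fitAllGenes(cs2, "poisson", blocking = "batch")
    expect_equal(fittedMeans(f1), fittedMeans(f2), tolerance = 1e-7)
})

test_that("degenerate genes are flagged, not fatal", {
    m <- matrix(c(0L, 0L, 0L, 0L, 5L, 7L, 6L, 8L), nrow = 2, byrow = TRUE,
                dimnames = list(c("gz", "g1"), paste0("s", 1:4)))
    cs <- tinyCountSet(m, groups = c("a", "a", "b", "b"))
    f <- fitAllGenes(cs, "poisson", norm = NULL)
    expect_true(f@degenerate["gz" == f@geneIds])
    expect_equal(pearsonStats(f)[["gz"]], 0)  # 0/0 contributions defined as 0
    expect_true(is.finite(pearsonStats(f)[["g1"]]))
})

test_that("flow-cell contrasts track an un-normalized depth shift", {
    cfg <- simConfig(nGenes = 300, dispersion = 0.1,
                     depthRegimes = list(pre = c(5, 5), post = c(10, 10)),
                     upgradeAtFlowcell = 5, seed = 41)
    sim <- simulateExperiment(cfg)
    subj <- filterExpressed(sumLanePairs(sim$counts))
    raw <- fitAllGenes(subj, "nb", phi = 0.1, blocking = "flow_cell",
                       norm = NULL)
    med <- apply(blockingEffects(raw), 2, stats::median, na.rm = TRUE)
    pre <- paste0("flow_cellFC0", 2:4)
    post <- setdiff(names(med), pre)
    expect_lt(max(abs(med[pre])), 0.15)
    expect_equal(unname(med[post]), rep(log(2), length(post)),
                 tolerance = 0.12)
    ## the total-count offset removes the shift
    offd <- fitAllGenes(subj, "nb", phi = 0.1, blocking = "flow_cell",
                        norm = "total")
    medo <- apply(blockingEffects(offd), 2, stats::median, na.rm = TRUE)
    expect_lt(max(abs(medo)), 0.15)
    expect_error(blockingEffects(fitAllGenes(subj, "poisson")), "without")
})
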