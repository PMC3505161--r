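test_that("Pearson statistics use the family-specific variance", {
    ## poisson: (4-2)^2/2 + (0-2)^2/2 = 4
    expect_equal(countvar:::.pearsonX2(c(4, 0), c(2, 2), "poisson"), 4)
    ## NB: (10-2)^2 / (2 + 0.5 * 4) = 16
    expect_equal(countvar:::.pearsonX2(10, 2, "nb", phi = 0.5), 16)
    ## y == fitted gives 0; zero-denominator cells with y = 0 contribute 0
    expect_equal(countvar:::.pearsonX2(c(3, 3), c(3, 3), "poisson"), 0)
    expect_equal(countvar:::.pearsonX2(c(0, 2), c(0, 2), "poisson"), 0)
    expect_equal(countvar:::.pearsonX2(c(1, 2), c(0, 2), "poisson"), Inf)
})

test_that("pearsonGOF reports df and the low-count flag", {
    m <- matrix(c(1L, 0L, 2L, 1L, 200L, 300L, 250L, 260L), nrow = 2,
                byrow = TRUE, dimnames = list(c("lo", "hi"), paste0("s", 1:4)))
    cs <- tinyCountSet(m, groups = c("a", "a", "b", "b"))
    rec <- pearsonGOF(fitAllGenes(cs, "poisson", norm = NULL))
    expect_equal(rec$df, c(3, 3))            # n - p with p = 1
    expect_equal(rec$low_count, c(TRUE, FALSE))
})

test_that("qqChisq flags exactly the top 1% and next 4%", {
    set.seed(8)
    x <- rchisq(1000, 22)
    qq <- qqChisq(x, 22)
    expect_equal(sum(qq$flag == "top1pct"), 10L)
    expect_equal(sum(qq$flag == "next4pct"), 40L)
    expect_equal(qq$observed, sort(x))
    expect_equal(length(attr(qq, "deciles")), 9L)
    ## observed equal to the theoretical quantiles lies on the identity
    theo <- qchisq((seq_len(200) - 0.5) / 200, 22)
    qq2 <- qqChisq(theo, 22)
    expect_equal(qq2$observed, qq2$theoretical)
    expect_error(qqChisq(x[1:5], 22), "at least 10")
})

test_that("technical pair GOF splits the pair total by lane depth", {
    expect_equal(technicalPairGOF(c(4L, 2L), c(4L, 2L))$X2, c(0, 0))
    g <- technicalPairGOF(4L, 0L, N1 = 100, N2 = 100)
    expect_equal(g$X2, 4)                    # (4-2)^2/2 + (0-2)^2/2
    ## zero-total genes are excluded and counted
    g2 <- technicalPairGOF(c(4L, 0L), c(4L, 0L), 50, 50)
    expect_equal(nrow(g2), 1L)
    expect_equal(attr(g2, "nExcluded"), 1L)
    expect_equal(attr(g2, "df"), 1)
    ## Poisson pairs with unequal depth follow chi-square(1)
    set.seed(9)
    mu <- 10^runif(10000, log10(50), log10(500))
    y1 <- rpois(10000, mu); y2 <- rpois(10000, 1.4 * mu)
    gof <- technicalPairGOF(y1, y2)
    ks <- suppressWarnings(ks.test(gof$X2, pchisq, df = 1)$statistic)
    expect_lt(unname(ks), 0.02)
})

test_that("MVA coordinates vanish for proportional lanes", {
    set.seed(10)
    y1 <- rpois(500, 100) + 1L
    mv <- mvaPair(y1, y1, 1e6, 1e6)
    expect_true(all(mv$M == 0))
    expect_true(all(mv$smooth == 0))
    ## doubling counts and depth together changes nothing
    mv2 <- mvaPair(y1, 2L * y1, 1e6, 2e6)
    expect_equal(mv2$M, rep(0, nrow(mv2)))
    ## unbiased Poisson pair: smoother hugs zero
    mu <- 10^runif(5000, 1, 4)
    a <- rpois(5000, mu); b <- rpois(5000, mu)
    mv3 <- mvaPair(a, b, sum(a), sum(b))
    expect_lt(max(abs(mv3$smooth)), 0.2)
    expect_lt(abs(stats::median(mv3$smooth)), 0.05)
    expect_error(mvaPair(c(0L, 1L), c(1L, 0L), 10, 10), "fewer than 10")
})

test_that("Spearman pair correlation behaves at the extremes", {
    y <- c(5L, 9L, 1L, 14L)
    expect_equal(spearmanPair(y, y), 1)
    expect_equal(spearmanPair(y, max(y) - y), -1)
    expect_error(spearmanPair(y, rep(3L, 4)), "constant")
    ## simulated deep technical pair is nearly perfectly rank-correlated
    ## (genes in the well-measured range; rank noise is pure Poisson)
    sim <- simulateExperiment(simConfig(nGenes = 5000, dispersion = 0.131,
                                        meanLog10Range = c(1, 4),
                                        seed = 111))
    cd <- sampleDesign(sim$counts)
    pair <- counts(sim$counts)[, cd$subject == "H01"]
    expect_gt(spearmanPair(pair[, 1], pair[, 2]), 0.99)
})

test_that("group mean-variance points are per gene and group", {
    m <- matrix(c(5L, 5L, 5L, 2L, 4L, 9L), nrow = 1,
                dimnames = list("g1", paste0("s", 1:6)))
    cs <- tinyCountSet(m, groups = rep(c("a", "b"), each = 3))
    mv <- groupMeanVariance(cs, norm = "none")
    expect_equal(mv$mean, c(5, 5))
    expect_equal(mv$var, c(0, 13))
    ## a two-subject group: gene [2, 4] -> (3, 2)
    cs2 <- tinyCountSet(matrix(c(2L, 4L, 7L, 7L), 1,
                               dimnames = list("g1", paste0("s", 1:4))),
                        groups = c("a", "a", "b", "b"))
    mv2 <- groupMeanVariance(cs2, norm = "none")
    expect_equal(mv2$mean[mv2$group == "a"], 3)
    expect_equal(mv2$var[mv2$group == "a"], 2)
    expect_error(groupMeanVariance(tinyCountSet(), norm = "none"), "fewer")
})

test_that("variance-law regressions recover exact generating slopes", {
    expect_equal(fitVarianceLaws(data.frame(mean = 10, var = 110))$phiQuad, 1)
    x <- seq(2, 400, length.out = 50)
    fit <- fitVarianceLaws(data.frame(mean = x, var = 2 * x))
    expect_equal(fit$kLinear, 2, tolerance = 1e-12)
    fit2 <- fitVarianceLaws(data.frame(mean = x, var = x + 0.3 * x^2))
    expect_equal(fit2$phiQuad, 0.3, tolerance = 1e-12)
    cv <- fit2$curves(c(0, 4))
    expect_equal(cv$sdPoisson, c(0, 2))
    expect_equal(cv$sdQuadratic[2], sqrt(4 + 0.3 * 16))
})

test_that("dispersion shows no mean trend on homogeneous data", {
    res <- simSubjects(300, 0.131, seed = 112, meanLog10Range = c(1, 4))
    md <- estimatePhiModerated(res$subj, priorN = 3)
    pv <- phiVsMean(md, rowMeans(counts(res$subj)))
    expect_lt(abs(pv$slope), 0.01)
    expect_false(any(pv$points$flagged))
})

test_that("per-gene dispersion fits over-fit: GOF over-concentrates", {
    ## estimating phi from the same counts it is then judged on tunes each
    ## gene's denominator to its own noise, collapsing the spread of the
    ## statistics far below the chi-square reference spread
    res <- simSubjects(400, 0.131, seed = 113)
    pg <- estimatePhiPerGene(res$subj)
    pg[is.na(pg)] <- 0
    f <- fitAllGenes(res$subj, "nb", phi = pg)
    x2 <- pearsonStats(f)
    refIQR <- qchisq(0.75, modelDF(f)) - qchisq(0.25, modelDF(f))
    expect_lt(stats::IQR(x2), 0.6 * refIQR)
    expect_lt(abs(stats::median(x2) - modelDF(f)), 2)
})

test_that("flow-cell blocking over-fits a no-effect simulation", {
    res <- simSubjects(400, 0.131, seed = 113)
    f <- fitAllGenes(res$subj, "nb", phi = 0.131, blocking = "flow_cell")
    x2 <- pearsonStats(f)
    ## the GOF distribution sits stochastically below its reference
    expect_gt(mean(x2 < qchisq(0.5, modelDF(f))), 0.55)
})
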