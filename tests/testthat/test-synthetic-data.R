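test_that("generateDesign builds the complete balanced 2x2x2 layout", {
    d <- generateDesign(3)
    s <- designTable(d)
    expect_equal(nrow(s), 24L)
    expect_equal(length(unique(paste(s$M, s$R, s$T))), 8L)
    expect_equal(replicates(d), 3L)
    expect_false(anyDuplicated(s$sample) > 0)
    # labels encode genotype/tissue/stage
    expect_true(all(grepl("^[WY][RE](36|52)_[0-9]+$", s$sample)))
    expect_equal(generateDesign(2, seed = 7), generateDesign(2, seed = 7))
    expect_error(generateDesign(1), "replicates")
})

test_that("simulateExpression realises the indicator-coded cell means", {
    d <- generateDesign(3)
    null <- data.frame(gene = "g1", class = "insignificant", group = "none",
        mu = 5, T = 0, M = 0, R = 0, TM = 0, TR = 0, MR = 0, TMR = 0)
    ex <- simulateExpression(d, null, noiseSd = 1e-12, seed = 1)
    expect_equal(unname(SummarizedExperiment::assay(ex, "log2")[1, ]),
        rep(5, 24), tolerance = 1e-9)

    mOnly <- null; mOnly$M <- 2
    y <- SummarizedExperiment::assay(simulateExpression(d, mOnly,
        noiseSd = 1e-12, seed = 1), "log2")[1, ]
    s <- designTable(d)
    expect_equal(mean(y[s$M == "yng"]) - mean(y[s$M == "WT"]), 2,
        tolerance = 1e-9)

    thr <- null; thr$TMR <- 3
    y <- SummarizedExperiment::assay(simulateExpression(d, thr,
        noiseSd = 1e-12, seed = 1), "log2")[1, ]
    # three-way pattern: retinal interaction minus whole-embryo interaction
    ret <- cellMean(y, d, "YR52") - cellMean(y, d, "YR36") -
        cellMean(y, d, "WR52") + cellMean(y, d, "WR36")
    emb <- cellMean(y, d, "YE52") - cellMean(y, d, "YE36") -
        cellMean(y, d, "WE52") + cellMean(y, d, "WE36")
    expect_equal(ret - emb, 3, tolerance = 1e-9)

    expect_error(simulateExpression(d, null[0, ]), "empty")
    expect_equal(simulateExpression(d, mOnly, 0.3, seed = 4),
        simulateExpression(d, mOnly, 0.3, seed = 4))
})

test_that("saturated fit on near-noiseless simulation recovers every truth", {
    d <- generateDesign(3)
    tr <- makeGeneTruths(c("insignificant" = 5, "one-way" = 5,
        "two-way" = 5, "three-way" = 5), effect = 1.3, seed = 9)
    ex <- simulateExpression(d, tr, noiseSd = 1e-9, seed = 9)
    fit <- fitSaturated(ex)
    B <- coef(fit)
    truthB <- as.matrix(tr[, c("mu", "T", "M", "R", "TM", "TR", "MR",
        "TMR")])
    dimnames(truthB) <- dimnames(B)
    expect_equal(B, truthB, tolerance = 1e-8)
})

test_that("ISH scores are a thresholded sign with calibrated corruption", {
    con <- data.frame(gene = c("a", "b", "c"), comparison = "YR36/WR36",
        estimate = c(1.5, -0.3, -2))
    sc <- simulateIshScores(con, detectLog2 = 1, flipProb = 0, seed = 1)
    expect_equal(sc$score, c(1L, 0L, -1L))
    # flip fraction matches its binomial expectation
    n <- 10000
    big <- data.frame(gene = sprintf("g%05d", 1:n), comparison = "x",
        estimate = rep(2, n))
    sc2 <- simulateIshScores(big, flipProb = 0.2, seed = 42)
    flipped <- mean(sc2$score != 1L)
    expect_lt(abs(flipped - 0.2), 3 * sqrt(0.2 * 0.8 / n))
    # flips land uniformly on the two other values
    expect_gt(sum(sc2$score == 0L), 0)
    expect_gt(sum(sc2$score == -1L), 0)
    expect_error(simulateIshScores(big, flipProb = 0.5), "flipProb")
})

test_that("simulateDomainMatrix plants templates with bounded corruption", {
    tpl <- rbind(a = c(1, 1, 0, 0), b = c(0, 0, 1, 1))
    m <- simulateDomainMatrix(tpl, c(3, 2), flipProb = 0, seed = 1)
    expect_equal(unname(m), unname(tpl[c(1, 1, 1, 2, 2), ]),
        ignore_attr = TRUE)
    expect_equal(attr(m, "template"), c(1L, 1L, 1L, 2L, 2L))
    m3 <- simulateDomainMatrix(defaultDomainTemplates()$templates,
        c(8, 5, 12), flipProb = 0.1, seed = 3)
    expect_equal(nrow(m3), 25L)
    expect_true(all(rowSums(m3) > 0))
    expect_error(simulateDomainMatrix(rbind(c(0, 0)), 2, 0.1), "all-zero")
})

test_that("between-template distances dominate within-template distances", {
    # two templates at Hamming distance 9 of 18
    t1 <- c(rep(1, 9), rep(0, 9)); t2 <- c(rep(0, 4), rep(1, 9), rep(0, 5))
    hits <- 0; total <- 0
    for (seed in 1:20) {
        m <- simulateDomainMatrix(rbind(t1, t2), c(5, 5), flipProb = 0.05,
            seed = seed)
        D <- as.matrix(binaryDistMatrix(m))
        within <- c(D[1:5, 1:5][upper.tri(diag(5))],
            D[6:10, 6:10][upper.tri(diag(5))])
        between <- as.vector(D[1:5, 6:10])
        total <- total + length(between) * length(within)
        hits <- hits + sum(outer(between, within, ">"))
    }
    expect_gte(hits / total, 0.95)
})
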