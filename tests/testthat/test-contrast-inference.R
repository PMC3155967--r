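wOf <- function(w) names(w)[w != 0]

test_that("contrast weights reproduce the printed null hypotheses", {
    expect_setequal(wOf(contrastWeights("three-way", "YR36/WR36")),
        c("M", "MR"))
    expect_setequal(wOf(contrastWeights("two-way", "YR36/WR36")),
        c("M", "MR"))
    expect_setequal(wOf(contrastWeights("one-way", "YR36/WR36")), "M")
    expect_setequal(wOf(contrastWeights("three-way", "YR52/WR52")),
        c("M", "MR", "TM", "TMR"))
    expect_setequal(wOf(contrastWeights("two-way", "YR52/WR52")),
        c("M", "MR", "TM"))
    # model-implied default vs printed literal for the one-way 52 hpf case
    expect_setequal(wOf(contrastWeights("one-way", "YR52/WR52")), "M")
    expect_setequal(wOf(contrastWeights("one-way", "YR52/WR52",
        literalOneWay52 = TRUE)), c("M", "T"))
    # retina specificity and whole-embryo mutation contrasts
    expect_setequal(wOf(contrastWeights("three-way", "retina/whole@36")),
        "R")
    expect_setequal(wOf(contrastWeights("three-way", "retina/whole@52")),
        c("R", "TR"))
    expect_setequal(wOf(contrastWeights("three-way", "YE52/WE52")),
        c("M", "TM"))
    expect_error(contrastWeights("three-way", "nope"), "unknown")
    expect_error(contrastWeights("insignificant", "YR36/WR36"), "class")
})

test_that("testContrast matches exact arithmetic and cell means", {
    d <- generateDesign(3)
    s <- designTable(d)
    # noise-free gene with M = 1, MR = 0.5
    y <- 8 + 1 * (s$M == "yng") + 0.5 * (s$M == "yng") * (s$R == "retina")
    names(y) <- s$sample
    fit <- fitSaturated(matrix(y, 1, dimnames = list("g", names(y))), d)
    r <- testContrast(fit, contrastWeights("three-way", "YR36/WR36"))
    expect_equal(r$estimate, 1.5, tolerance = 1e-12)
    expect_equal(r$p, 0)  # zero residual variance, nonzero estimate

    # noisy gene: every contrast equals its direct cell-mean combination
    set.seed(12)
    y2 <- rnorm(24, 8, 1); names(y2) <- s$sample
    fit2 <- fitSaturated(matrix(y2, 1, dimnames = list("g", names(y2))), d)
    est <- testContrast(fit2,
        contrastWeights("three-way", "YR52/WR52"))$estimate
    expect_equal(est, cellMean(y2, d, "YR52") - cellMean(y2, d, "WR52"),
        tolerance = 1e-10)
    est36 <- testContrast(fit2,
        contrastWeights("three-way", "YR36/WR36"))$estimate
    expect_equal(est36, cellMean(y2, d, "YR36") - cellMean(y2, d, "WR36"),
        tolerance = 1e-10)

    # all-zero coefficients: estimate 0, fold change 1, p = 1
    y3 <- rep(8, 24); names(y3) <- s$sample
    fit3 <- fitSaturated(matrix(y3, 1, dimnames = list("g", names(y3))), d)
    r3 <- testContrast(fit3, contrastWeights("three-way", "YR36/WR36"))
    expect_equal(r3$estimate, 0)
    expect_equal(signedFoldChange(r3$estimate), 1)
    expect_equal(r3$p, 1)
})

test_that("signed fold change follows the field convention", {
    expect_equal(signedFoldChange(1), 2)
    expect_equal(signedFoldChange(0), 1)
    expect_equal(signedFoldChange(-1), -2)
    # a printed under-expression of -1.17 corresponds to log2(1/1.17)
    expect_equal(signedFoldChange(log2(1 / 1.17)), -1.17,
        tolerance = 1e-12)
    # filter equivalence: |FC| >= 2 iff |log2 estimate| >= 1
    grid <- seq(-3, 3, by = 0.01)
    expect_equal(abs(signedFoldChange(grid)) >= 2, abs(grid) >= 1)
    expect_true(all(abs(signedFoldChange(grid)) >= 1))
    expect_equal(sign(signedFoldChange(grid)), ifelse(grid >= 0, 1, -1))
})

test_that("adjustFDR is Benjamini-Hochberg step-up", {
    expect_equal(adjustFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(adjustFDR(0.2), 0.2)
    expect_equal(adjustFDR(rep(1, 5)), rep(1, 5))
    expect_error(adjustFDR(c(0.5, 1.2)), "0, 1")
    set.seed(77)
    for (i in 1:20) {
        p <- runif(sample(1:40, 1))
        expect_equal(adjustFDR(p), bhOracle(p), tolerance = 1e-12)
    }
})

test_that("functional groups follow the ordered decision rules", {
    mk <- function(gene, sig) data.frame(gene = gene,
        comparison = names(sig), q = ifelse(sig, 0.001, 0.5),
        fc = ifelse(sig, 4, 1.2), significant = unname(sig),
        stringsAsFactors = FALSE)
    cmps <- c("YR36/WR36", "YR52/WR52", "retina/whole@36",
        "retina/whole@52", "YE36/WE36", "YE52/WE52")
    flags <- function(...) setNames(c(...), cmps)
    # foxn4-like: retina-specific at both stages, mutation FCs below 2
    foxn4 <- mk("foxn4", flags(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE))
    # strong mutation response at 52 hpf
    gi <- mk("gi", flags(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
    # whole-embryo mutation response only
    giii <- mk("giii", flags(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
    # nothing significant
    gn <- mk("gn", flags(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
    # retina-specific at one stage only does not qualify for group ii
    ghalf <- mk("ghalf", flags(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
    out <- classifyFunctionalGroup(rbind(foxn4, gi, giii, gn, ghalf))
    expect_equal(setNames(out$group, out$gene),
        c(foxn4 = "ii", gi = "i", giii = "iii", gn = "none",
          ghalf = "none"))
    # exactly one group per gene, always
    expect_true(all(out$group %in% c("i", "ii", "iii", "none")))
    expect_error(classifyFunctionalGroup(rbind(foxn4)[
        rbind(foxn4)$comparison != "YE36/WE36", ]), "missing contrast")
})

test_that("group-(i) calls are precedence-ordered over group (ii)", {
    # a gene passing both mutation and retina-specificity rules is (i)
    cmps <- c("YR36/WR36", "YR52/WR52", "retina/whole@36",
        "retina/whole@52", "YE36/WE36", "YE52/WE52")
    df <- data.frame(gene = "g", comparison = cmps, q = 0.001, fc = 4,
        significant = TRUE, stringsAsFactors = FALSE)
    expect_equal(classifyFunctionalGroup(df)$group, "i")
})
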