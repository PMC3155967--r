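test_that("compareCall truth table is exhaustively correct", {
    # all 9 combinations of call state (sig+, sig-, insignificant) x score
    cases <- expand.grid(state = c("sig+", "sig-", "ns"),
        score = c(-1, 0, 1), stringsAsFactors = FALSE)
    sig <- cases$state != "ns"
    est <- ifelse(cases$state == "sig+", 2, ifelse(cases$state == "sig-",
        -2, 0.1))
    got <- compareCall(sig, est, cases$score)
    want <- ifelse(sig, cases$score == sign(est), cases$score == 0)
    expect_equal(got, want)
    # relaxed mode: any nonzero score agrees with a significant call
    got2 <- compareCall(sig, est, cases$score, signStrict = FALSE)
    want2 <- ifelse(sig, cases$score != 0, cases$score == 0)
    expect_equal(got2, want2)
    expect_error(compareCall(TRUE, 2, 2), "score")
    expect_error(compareCall(TRUE, 0, 1), "inconsistent")
})

test_that("identity matrix covers the key intersection and flags drops", {
    res <- data.frame(gene = c("a", "a", "b"),
        comparison = c("YR36/WR36", "YR52/WR52", "YR36/WR36"),
        significant = c(TRUE, FALSE, TRUE), estimate = c(2, 0.1, -1.5))
    sc <- data.frame(gene = c("a", "a", "b", "c"),
        comparison = c("YR36/WR36", "YR52/WR52", "YR36/WR36", "YR36/WR36"),
        score = c(1L, 0L, 1L, 1L))
    expect_message(id <- buildIdentityMatrix(res, sc), "dropped")
    expect_equal(nrow(id), 3L)
    expect_equal(id$identical, c(TRUE, TRUE, FALSE))  # b: sign mismatch
    expect_error(buildIdentityMatrix(res,
        data.frame(gene = "z", comparison = "YR36/WR36", score = 0L)),
        "shared")
})

test_that("concordance rates report exact counts and fractions", {
    grid <- concordanceFixture()
    id <- buildIdentityMatrix(
        grid[, c("gene", "comparison", "significant", "estimate")],
        grid[, c("gene", "comparison", "score")])
    all <- concordanceRate(id, "all")
    expect_equal(all$n, 116L)
    expect_equal(all$k, 97L)
    expect_equal(round(100 * all$rate, 1), 83.6)
    sig <- concordanceRate(id, "significant")
    expect_equal(sig$n, 31L)
    expect_equal(sig$k, 28L)
    expect_equal(round(100 * sig$rate, 1), 90.3)
    expect_error(concordanceRate(id[0, ], "all"), "empty")
    # permutation invariance
    perm <- sample(nrow(grid))
    id2 <- buildIdentityMatrix(
        grid[perm, c("gene", "comparison", "significant", "estimate")],
        grid[, c("gene", "comparison", "score")])
    expect_equal(concordanceRate(id2, "all")$rate, all$rate)
    expect_equal(concordanceRate(id2, "significant")$rate, sig$rate)
})

test_that("the TDR z test is the null-variance one-sample proportion test", {
    eq <- tdrZTest(19, 20, 0.95)
    expect_equal(eq$z, 0)
    expect_equal(eq$p, 1)
    zt <- tdrZTest(28, 31, 0.95)
    expect_equal(zt$z, (28 / 31 - 0.95) / sqrt(0.95 * 0.05 / 31),
        tolerance = 1e-12)
    expect_equal(zt$z, -1.1949, tolerance = 1e-4)
    expect_equal(zt$p, 0.2321, tolerance = 1e-3)
    expect_error(tdrZTest(5, 0), "n")
    expect_error(tdrZTest(-1, 10), "k")
    expect_error(tdrZTest(1, 10, 1), "p0")
})

test_that("significant-only concordance converges to 1 - flip rate", {
    n <- 5000
    con <- rbind(
        data.frame(gene = sprintf("g%04d", 1:n), comparison = "YR36/WR36",
            estimate = 2),
        data.frame(gene = sprintf("g%04d", 1:n), comparison = "YR52/WR52",
            estimate = -2))
    con$significant <- TRUE
    f <- 0.2
    sc <- simulateIshScores(con, detectLog2 = 1, flipProb = f, seed = 99)
    id <- buildIdentityMatrix(con, sc)
    rate <- concordanceRate(id, "significant")
    expect_equal(rate$n, 2L * n)
    # a flip always breaks sign agreement, so agreement ~ Binom(n, 1 - f)
    expect_lt(abs(rate$rate - (1 - f)), 3 * sqrt(f * (1 - f) / (2 * n)))
})
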