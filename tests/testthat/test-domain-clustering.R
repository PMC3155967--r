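test_that("binary distance matches its set definition", {
    expect_equal(binaryDistance(c(1, 1, 0), c(1, 1, 0)), 0)
    expect_equal(binaryDistance(c(1, 1, 0), c(0, 1, 1)), 2 / 3)
    expect_equal(binaryDistance(c(1, 0, 0), c(0, 1, 0)), 1)
    expect_error(binaryDistance(c(0, 0), c(0, 0)), "all-zero")
    expect_error(binaryDistance(c(1, 0), c(1, 0, 1)), "length")
    # semimetric properties on random admitted vectors
    set.seed(5)
    for (i in 1:50) {
        L <- sample(2:10, 1)
        a <- rbinom(L, 1, 0.5); b <- rbinom(L, 1, 0.5)
        if (sum(a) == 0 || sum(b) == 0) next
        expect_equal(binaryDistance(a, b), binaryDistance(b, a))
        expect_gte(binaryDistance(a, b), 0)
        expect_lte(binaryDistance(a, b), 1)
        expect_equal(binaryDistance(a, b) == 0, identical(a, b))
    }
    # agreement with stats::dist(method = "binary") on a matrix
    m <- matrix(rbinom(60, 1, 0.5), 10); m[rowSums(m) == 0, 1] <- 1
    D <- as.matrix(binaryDistMatrix(m))
    for (i in 1:9) for (j in (i + 1):10)
        expect_equal(D[i, j], binaryDistanceOracle(m[i, ], m[j, ]))
})

test_that("UPGMA reproduces simple merges and is height-monotone", {
    D <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0), 3,
        dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
    hc <- upgmaCluster(D)
    sets <- cladeLabelSets(hc, c("A", "B", "C"))
    expect_equal(sets[[1]], c("A", "B"))
    expect_equal(hc$height, c(0, 1))
    # two items merge at their distance
    D2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("x", "y"), NULL))
    expect_equal(upgmaCluster(D2)$height, 0.4)
    expect_error(upgmaCluster(matrix(c(0, 1, 2, 0), 2)), "symmetric")
    # heights never decrease along the agglomeration
    set.seed(21)
    for (i in 1:10) {
        n <- sample(4:12, 1)
        M <- matrix(runif(n * n), n); M <- (M + t(M)) / 2; diag(M) <- 0
        expect_true(!is.unsorted(upgmaCluster(M)$height))
    }
})

test_that("UPGMA agrees with the brute-force average-linkage oracle", {
    set.seed(42)
    for (i in 1:20) {
        n <- sample(3:6, 1)
        M <- matrix(runif(n * n), n); M <- (M + t(M)) / 2; diag(M) <- 0
        hc <- upgmaCluster(M)
        oracle <- upgmaOracle(M)
        expect_equal(cladeMembers(hc), oracle$sets)
        expect_equal(hc$height, oracle$heights, tolerance = 1e-12)
    }
})

test_that("the C++ agglomeration matches stats::hclust on tie-free input", {
    set.seed(7)
    for (i in 1:20) {
        n <- sample(4:15, 1)
        M <- matrix(runif(n * n), n); M <- (M + t(M)) / 2; diag(M) <- 0
        hc <- upgmaCluster(M)
        cpp <- retscreen:::cpp_upgma(M)
        expect_equal(lapply(cpp$clades, sort), cladeMembers(hc))
        expect_equal(sort(cpp$heights), unname(hc$height),
            tolerance = 1e-12)
    }
})

test_that("multiscale bootstrap counts are deterministic and saturate", {
    # two identical-row blocks at maximal distance
    m <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(1, 1, 0, 0),
               c(0, 0, 1, 1), c(0, 0, 1, 1), c(0, 0, 1, 1))
    dimnames(m) <- list(paste0("g", 1:6), paste0("d", 1:4))
    bs1 <- multiscaleBootstrap(m, scales = 1, nBoot = 200, seed = 11)
    bs2 <- multiscaleBootstrap(m, scales = 1, nBoot = 200, seed = 11)
    expect_identical(bs1$counts, bs2$counts)
    blockA <- which(vapply(bs1$clades, function(s)
        identical(s, 1:3), TRUE))
    blockB <- which(vapply(bs1$clades, function(s)
        identical(s, 4:6), TRUE))
    expect_length(blockA, 1L)
    expect_gte(bs1$counts[blockA, 1], 198)  # ~100% recovery
    expect_gte(bs1$counts[blockB, 1], 198)
    expect_error(multiscaleBootstrap(m, scales = 0.1, nBoot = 200),
        "resample size")
    expect_error(multiscaleBootstrap(m, nBoot = 50), "nBoot")
})

test_that("AU fitting recovers the probit-linear law and its limits", {
    sc <- seq(0.5, 1.4, by = 0.1)
    # flat BP = 0.5 at every scale: v = c = 0, AU = 0.5
    flat <- auPvalue(rep(0.5, 10) * 1000, 1000, sc)
    expect_equal(flat$v, 0, tolerance = 1e-10)
    expect_equal(flat$c, 0, tolerance = 1e-10)
    expect_equal(flat$au, 0.5, tolerance = 1e-10)
    # noise-free curve generated from (v, c) = (0.5, 0.3)
    bp <- 1 - pnorm(0.5 * sqrt(sc) + 0.3 / sqrt(sc))
    fit <- auPvalue(bp * 10000, 10000, sc)
    expect_equal(fit$v, 0.5, tolerance = 1e-8)
    expect_equal(fit$c, 0.3, tolerance = 1e-8)
    expect_equal(fit$au, 1 - pnorm(0.2), tolerance = 1e-8)
    expect_false(fit$degenerate)
    # all counts at the ceiling: clipped, AU near 1, flagged degenerate
    top <- auPvalue(rep(1000, 10), 1000, sc)
    expect_true(top$degenerate)
    expect_gt(top$au, 0.95)
    # zero-curvature consistency: AU equals BP at r = 1
    bp0 <- 1 - pnorm(0.8 * sqrt(sc))
    fit0 <- auPvalue(bp0 * 10000, 10000, sc)
    expect_equal(fit0$au, fit0$bp, tolerance = 1e-6)
})

test_that("clade flags follow the red/green thresholds", {
    sup <- data.frame(p = c(0.03, 0.07, 0.5, 0.099, 0.1))
    expect_equal(flagClades(sup), c("red", "green", "", "green", ""))
    expect_error(flagClades(data.frame(p = c(0.03, NA))), "missing")
    # via AU: 0.97 -> red, 0.92 -> green, 0.5 -> unflagged
    expect_equal(flagClades(data.frame(p = 1 - c(0.97, 0.92, 0.5))),
        c("red", "green", ""))
})

test_that("domainClustering attaches support to every internal node", {
    tpl <- defaultDomainTemplates()
    m <- simulateDomainMatrix(tpl$templates, c(4, 4, 4), flipProb = 0.02,
        seed = 2)
    dc <- domainClustering(m, nBoot = 500, seed = 3)
    sup <- supportTable(dc)
    expect_equal(nrow(sup), nrow(m) - 1L)
    expect_true(all(sup$au >= 0 & sup$au <= 1))
    expect_true(all(sup$bp >= 0 & sup$bp <= 1))
    expect_equal(sup$p, 1 - sup$au, tolerance = 1e-12)
    # the three planted template clades exist and can be looked up
    gsets <- split(rownames(m), attr(m, "template"))
    au <- cladeAU(dc, gsets)
    expect_length(au, 3L)
})
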