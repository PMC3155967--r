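## Synthetic-data module: generators for every input the pipeline consumes.
## The defaults are the study conditions the analysis assumes: 3 replicates
## per design cell, i.i.d. Gaussian log2 noise with sd 0.25, planted effects
## of 4 x noise sd, an ISH detection threshold of 1 log2 unit (the two-fold
## criterion), and three domain templates of sizes 8/5/12 genes.

# Evaluate expr under a fixed RNG seed without disturbing the caller's RNG.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
    expr
}

#' Generate the complete 2x2x2 factorial design
#'
#' Builds the full mutation x tissue x stage design with a fixed replicate
#' count per cell. Sample labels follow the convention \code{WR36} (wild-type
#' retina, 36 hpf), \code{YR52} (mutant retina, 52 hpf), \code{WE36}/\code{YE52}
#' (whole embryo), suffixed by the replicate index.
#'
#' @param replicates replicates per design cell; at least 2, otherwise the
#'   residual variance of the saturated fit is inestimable.
#' @param seed accepted for interface symmetry with the other generators;
#'   the design is fully deterministic, so it is unused.
#' @return a \linkS4class{FactorialDesign}.
#' @export
#' @examples
#' generateDesign(3)
generateDesign <- function(replicates = 3L, seed = NULL) {
    replicates <- as.integer(replicates)
    if (is.na(replicates) || replicates < 2L)
        stop("replicates must be >= 2 (residual variance inestimable otherwise)")
    cells <- expand.grid(replicate = seq_len(replicates),
        T = c("36", "52"), R = c("whole", "retina"), M = c("WT", "yng"),
        stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    geno <- ifelse(cells$M == "WT", "W", "Y")
    tis <- ifelse(cells$R == "retina", "R", "E")
    lab <- paste0(geno, tis, cells$T, "_", cells$replicate)
    samples <- data.frame(sample = lab, M = cells$M, R = cells$R, T = cells$T,
        replicate = cells$replicate, stringsAsFactors = FALSE)
    new("FactorialDesign", samples = samples, replicates = replicates)
}

#' Indicator-coded design matrix of the saturated model
#'
#' Treatment (0/1 indicator) coding with reference levels WT, whole embryo
#' and 36 hpf, so every coefficient is directly a cell-mean contrast (e.g.
#' the YR36 - WR36 difference is \code{M + MR}).
#'
#' @param design a \linkS4class{FactorialDesign} or its sample table.
#' @return samples x 8 numeric matrix, columns in \code{\link{anovaTerms}}
#'   order, rownames = sample labels.
#' @export
designMatrix <- function(design) {
    s <- if (is(design, "FactorialDesign")) design@samples else design
    t <- as.numeric(s$T == "52")
    m <- as.numeric(s$M == "yng")
    r <- as.numeric(s$R == "retina")
    X <- cbind(mu = 1, T = t, M = m, R = r, TM = t * m, TR = t * r,
        MR = m * r, TMR = t * m * r)
    rownames(X) <- s$sample
    X
}

#' Construct a FactorialExperiment from a value matrix and a design
#'
#' @param values gene x sample matrix of log2 intensities; columns must
#'   match the design's sample labels.
#' @param design a \linkS4class{FactorialDesign}.
#' @param rowData optional per-gene annotation.
#' @return a \linkS4class{FactorialExperiment}.
#' @export
FactorialExperiment <- function(values, design, rowData = NULL) {
    s <- design@samples
    if (!identical(colnames(values), s$sample))
        values <- values[, s$sample, drop = FALSE]
    cd <- S4Vectors::DataFrame(M = s$M, R = s$R, T = s$T,
        replicate = s$replicate, row.names = s$sample)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(log2 = values), colData = cd)
    if (!is.null(rowData)) SummarizedExperiment::rowData(se) <- rowData
    new("FactorialExperiment", se)
}

# Canonical coefficient columns of a truth table.
truthCoefColumns <- function() c("mu", anovaTerms()[-1])

#' Planted per-gene truths for the four parsimonious model classes
#'
#' For each gene one model class is planted. Insignificant genes have all
#' effect coefficients zero; one-way genes a single random main effect;
#' two-way genes all three main effects plus one random two-way
#' interaction; three-way genes all seven effect terms (the three-way class
#' is equivalent to a nonzero \code{TMR} coefficient). Active coefficients
#' have magnitude \code{effect} with random sign.
#'
#' @param nPerClass named counts per class (names \code{insignificant},
#'   \code{one-way}, \code{two-way}, \code{three-way}).
#' @param effect magnitude of active coefficients, log2 units. The default
#'   1 is four times the default noise sd of
#'   \code{\link{simulateExpression}}.
#' @param mu baseline log2 intensity.
#' @param seed RNG seed.
#' @return data.frame with columns \code{gene}, \code{class}, \code{group},
#'   \code{mu} and the seven effect coefficients.
#' @export
makeGeneTruths <- function(nPerClass = c("insignificant" = 500,
        "one-way" = 500, "two-way" = 500, "three-way" = 500),
        effect = 1, mu = 8, seed = 1) {
    classes <- c("insignificant", "one-way", "two-way", "three-way")
    if (is.null(names(nPerClass)) || !all(names(nPerClass) %in% classes))
        stop("nPerClass must be named with the four model classes")
    withSeed(seed, {
        n <- sum(nPerClass)
        cls <- rep(names(nPerClass), nPerClass)
        B <- matrix(0, n, 8, dimnames = list(NULL, truthCoefColumns()))
        B[, "mu"] <- mu
        sgn <- function(k) sample(c(-1, 1), k, replace = TRUE)
        col <- function(terms, k) match(sample(terms, k, TRUE), colnames(B))
        i1 <- which(cls == "one-way")
        if (length(i1))
            B[cbind(i1, col(c("T", "M", "R"), length(i1)))] <-
                effect * sgn(length(i1))
        i2 <- which(cls == "two-way")
        if (length(i2)) {
            B[i2, c("T", "M", "R")] <- effect * matrix(sgn(3 * length(i2)),
                length(i2))
            B[cbind(i2, col(c("TM", "TR", "MR"), length(i2)))] <-
                effect * sgn(length(i2))
        }
        i3 <- which(cls == "three-way")
        if (length(i3))
            B[i3, 2:8] <- effect * matrix(sgn(7 * length(i3)), length(i3))
        data.frame(gene = sprintf("gene%05d", seq_len(n)), class = cls,
            group = "none", B, stringsAsFactors = FALSE)
    })
}

#' Planted truths for the three functional groups
#'
#' Generates genes whose true contrast structure places them in functional
#' group (i) (mutation-regulated retinal: the retinal mutation contrasts
#' YR36/WR36 and YR52/WR52 exceed two-fold), group (ii) (retina-specific,
#' mutation-independent: retina/whole contrasts exceed two-fold at both
#' stages, mutation contrasts null), group (iii) (mutation-regulated
#' outside the retina: whole-embryo mutation contrast two-fold, retinal
#' mutation contrasts cancel), or no group.
#'
#' @param n named counts, names \code{i}, \code{ii}, \code{iii},
#'   \code{none}.
#' @param mu baseline log2 intensity.
#' @param seed RNG seed.
#' @return truth data.frame as in \code{\link{makeGeneTruths}}.
#' @export
plantFunctionalGroups <- function(n = c(i = 200, ii = 100, iii = 100,
        none = 100), mu = 8, seed = 1) {
    if (is.null(names(n)) || !all(names(n) %in% c("i", "ii", "iii", "none")))
        stop("n must be named with groups i, ii, iii, none")
    withSeed(seed, {
        tot <- sum(n)
        grp <- rep(names(n), n)
        B <- matrix(0, tot, 8, dimnames = list(NULL, truthCoefColumns()))
        B[, "mu"] <- mu
        s <- sample(c(-1, 1), tot, replace = TRUE)
        gi <- grp == "i"    # YR36 contrast = M + MR = 2.1; YR52 = 3.1
        B[gi, "T"] <- 0.6; B[gi, "R"] <- 0.8
        B[gi, "M"] <- 1.2 * s[gi]; B[gi, "MR"] <- 0.9 * s[gi]
        B[gi, "TM"] <- 0.4 * s[gi]; B[gi, "TMR"] <- 0.6 * s[gi]
        gii <- grp == "ii"  # retina/whole = 1.5 at 36 hpf, 2.0 at 52 hpf
        B[gii, "T"] <- 0.4; B[gii, "R"] <- 1.5; B[gii, "TR"] <- 0.5
        giii <- grp == "iii" # whole-embryo mutation = 2; M + MR cancels
        B[giii, "T"] <- 0.3
        B[giii, "M"] <- 2 * s[giii]; B[giii, "MR"] <- -2 * s[giii]
        cls <- ifelse(gi, "three-way", ifelse(gii | giii, "two-way",
            "insignificant"))
        data.frame(gene = sprintf("gene%05d", seq_len(tot)), class = cls,
            group = grp, B, stringsAsFactors = FALSE)
    })
}

#' Simulate a log2 expression matrix from planted truths
#'
#' Each sample value is the sum of the gene's active coefficients for that
#' sample's design cell (indicator coding, reference levels WT /
#' whole-embryo / 36 hpf) plus independent Gaussian noise.
#'
#' @param design a \linkS4class{FactorialDesign}.
#' @param truths truth data.frame from \code{\link{makeGeneTruths}} or
#'   \code{\link{plantFunctionalGroups}}.
#' @param noiseSd Gaussian noise sd on the log2 scale (> 0); default 0.25,
#'   a typical replicate sd for log2 array intensities.
#' @param seed RNG seed; identical seeds give identical matrices.
#' @return a \linkS4class{FactorialExperiment} carrying the truth columns
#'   in \code{rowData}.
#' @export
#' @examples
#' d <- generateDesign(3)
#' tr <- makeGeneTruths(c("three-way" = 5, "insignificant" = 5), seed = 2)
#' simulateExpression(d, tr, seed = 2)
simulateExpression <- function(design, truths, noiseSd = 0.25, seed = 1) {
    stopifnot(is(design, "FactorialDesign"))
    if (!nrow(truths)) stop("empty truth table")
    if (!(noiseSd > 0)) stop("noiseSd must be > 0")
    B <- as.matrix(truths[, truthCoefColumns()])
    if (!all(is.finite(B))) stop("truth coefficients must be finite")
    X <- designMatrix(design)
    colnames(B) <- anovaTerms()   # mu column aligns with intercept
    mean <- B %*% t(X)
    values <- withSeed(seed,
        mean + matrix(rnorm(length(mean), 0, noiseSd), nrow(mean)))
    dimnames(values) <- list(truths$gene, rownames(X))
    FactorialExperiment(values, design,
        rowData = truths[, c("class", "group")])
}

#' Simulate qualitative ISH scores from contrast estimates
#'
#' The noise-free score is \code{sign(estimate)} when the absolute log2
#' estimate reaches \code{detectLog2} and 0 otherwise (an ISH comparison
#' only registers a change when it is large enough to see by eye). Each
#' score is then independently replaced by one of the two other values,
#' chosen uniformly, with probability \code{flipProb}.
#'
#' @param contrasts data.frame with columns \code{gene}, \code{comparison},
#'   \code{estimate} (log2).
#' @param detectLog2 detection threshold in log2 units; the default 1
#'   mirrors the two-fold criterion.
#' @param flipProb score corruption probability, in [0, 0.5).
#' @param seed RNG seed.
#' @return data.frame \code{gene}, \code{comparison}, \code{score} with
#'   scores in \{-1, 0, +1\}.
#' @export
simulateIshScores <- function(contrasts, detectLog2 = 1, flipProb = 0,
        seed = 1) {
    stopifnot(all(c("gene", "comparison", "estimate") %in% names(contrasts)))
    if (!(detectLog2 > 0)) stop("detectLog2 must be > 0")
    if (flipProb < 0 || flipProb >= 0.5)
        stop("flipProb must be in [0, 0.5)")
    est <- contrasts$estimate
    score <- ifelse(abs(est) >= detectLog2, sign(est), 0)
    withSeed(seed, {
        flip <- runif(length(score)) < flipProb
        if (any(flip)) {
            pick <- sample(1:2, sum(flip), replace = TRUE)
            others <- vapply(score[flip],
                function(s) setdiff(c(-1, 0, 1), s), numeric(2))
            score[flip] <- others[cbind(pick, seq_len(sum(flip)))]
        }
    })
    data.frame(gene = contrasts$gene, comparison = contrasts$comparison,
        score = as.integer(score), stringsAsFactors = FALSE)
}

#' Canonical retinal expression-domain columns
#'
#' The 18 domains scored per gene: 36 hpf ventral view (GC/BR, OR-b, OR-a),
#' 36 hpf lateral view (VP, AV, AD, PD, PV), 52 hpf ventral view (GCL,
#' INL-b, INL-m, INL-a, ONL) and 52 hpf lateral view (VP, AV, AD, PD, PV).
#' The 13-column variant scores the five lateral domains once, shared
#' between stages.
#'
#' @param layout \code{"18"} (lateral domains per stage, the default) or
#'   \code{"13"} (shared lateral domains).
#' @return character vector of column names.
#' @export
domainColumns <- function(layout = c("18", "13")) {
    layout <- match.arg(layout)
    lat <- c("VP", "AV", "AD", "PD", "PV")
    v36 <- c("GC.BR_36v", "OR.b_36v", "OR.a_36v")
    v52 <- c("GCL_52v", "INL.b_52v", "INL.m_52v", "INL.a_52v", "ONL_52v")
    if (layout == "18")
        c(v36, paste0(lat, "_36l"), v52, paste0(lat, "_52l"))
    else c(v36, v52, paste0(lat, "_lat"))
}

#' Default domain-pattern templates for the three expression groups
#'
#' Binary 18-domain templates emulating the three broad cellular
#' expression groups: (1) photoreceptor/ONL-specific expression at 52 hpf
#' (8 genes), (2) GCL and/or INL expression at both 36 and 52 hpf
#' (5 genes), (3) GCL and/or INL expression at 52 hpf only (12 genes).
#'
#' @return list with \code{templates} (3 x 18 binary matrix) and
#'   \code{sizes} (genes per template, \code{c(8, 5, 12)}).
#' @export
defaultDomainTemplates <- function() {
    cols <- domainColumns("18")
    t1 <- setNames(numeric(18), cols)   # ONL at 52 hpf, ventral patch
    t1[c("ONL_52v", "VP_52l")] <- 1
    t2 <- setNames(numeric(18), cols)   # GCL/INL at both stages
    t2[c("GC.BR_36v", "VP_36l", "AV_36l", "AD_36l",
         "GCL_52v", "INL.b_52v", "VP_52l", "AV_52l", "AD_52l", "PD_52l")] <- 1
    t3 <- setNames(numeric(18), cols)   # GCL/INL at 52 hpf only
    t3[c("GCL_52v", "INL.b_52v", "INL.m_52v", "INL.a_52v",
         "AV_52l", "AD_52l", "PD_52l", "PV_52l")] <- 1
    list(templates = rbind(t1, t2, t3), sizes = c(8, 5, 12))
}

#' Simulate a binary gene x domain matrix from pattern templates
#'
#' Each gene copies its template with independent bit flips at rate
#' \code{flipProb}; rows that come out all-zero are redrawn, since a gene
#' with no scored domain carries no pattern information and is excluded
#' from clustering.
#'
#' @param templates matrix of binary template rows (equal length).
#' @param genesPerTemplate integer vector, genes per template.
#' @param flipProb per-bit flip probability, in [0, 0.5).
#' @param seed RNG seed.
#' @param geneNames optional gene ids (default \code{gene01...}).
#' @return binary matrix with attribute \code{"template"} giving each
#'   row's template index.
#' @export
simulateDomainMatrix <- function(templates, genesPerTemplate,
        flipProb = 0.05, seed = 1, geneNames = NULL) {
    templates <- as.matrix(templates)
    if (any(rowSums(templates) == 0)) stop("all-zero template")
    if (length(genesPerTemplate) != nrow(templates))
        stop("one count per template required")
    if (flipProb < 0 || flipProb >= 0.5) stop("flipProb must be in [0, 0.5)")
    idx <- rep(seq_len(nrow(templates)), genesPerTemplate)
    n <- length(idx); p <- ncol(templates)
    mat <- withSeed(seed, {
        out <- matrix(0, n, p)
        for (g in seq_len(n)) {
            for (try in 1:1000) {
                row <- as.numeric(xor(templates[idx[g], ],
                    runif(p) < flipProb))
                if (sum(row) > 0) break
            }
            if (sum(row) == 0) stop("could not draw a nonzero row")
            out[g, ] <- row
        }
        out
    })
    if (is.null(geneNames))
        geneNames <- sprintf("gene%02d", seq_len(n))
    dimnames(mat) <- list(geneNames,
        colnames(templates) %||% domainColumns("18")[seq_len(p)])
    attr(mat, "template") <- idx
    mat
}

`%||%` <- function(a, b) if (is.null(a)) b else a
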