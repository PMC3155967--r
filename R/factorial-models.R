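## Factorial-models module: saturated 2x2x2 OLS fits per gene and
## parsimonious model-class assignment.

#' Fit the saturated three-way factorial model to every gene
#'
#' Ordinary least squares under indicator coding (reference levels WT,
#' whole embryo, 36 hpf). With a balanced design every coefficient equals
#' a closed-form combination of cell means, e.g. the three-way term is the
#' difference of the retinal and whole-embryo mutation-by-stage
#' interaction patterns. Per-term p-values are two-sided t tests on the
#' residual degrees of freedom (equivalent to type-III F tests in a
#' balanced design). Genes fitted with zero residual variance get p = 1
#' where the coefficient is exactly zero and p = 0 (degenerate) otherwise.
#'
#' @param x a \linkS4class{FactorialExperiment}, or a gene x sample value
#'   matrix when \code{design} is supplied.
#' @param design a \linkS4class{FactorialDesign}; unused when \code{x} is a
#'   \code{FactorialExperiment}.
#' @return a \linkS4class{FactorialFit}.
#' @export
#' @examples
#' d <- generateDesign(3)
#' tr <- makeGeneTruths(c("three-way" = 3, "insignificant" = 3), seed = 1)
#' fit <- fitSaturated(simulateExpression(d, tr, seed = 1))
#' head(coef(fit))
fitSaturated <- function(x, design = NULL) {
    if (is(x, "FactorialExperiment")) {
        Y <- SummarizedExperiment::assay(x, "log2")
        X <- designMatrix(designTable(x))
    } else {
        stopifnot(is.matrix(x), is(design, "FactorialDesign"))
        Y <- x[, design@samples$sample, drop = FALSE]
        X <- designMatrix(design)
    }
    if (!all(is.finite(Y))) stop("expression values must be finite")
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) stop("rank-deficient design")
    df <- nrow(X) - ncol(X)
    if (df < 1L) stop("zero residual degrees of freedom")
    XtXi <- chol2inv(chol(crossprod(X)))
    dimnames(XtXi) <- list(anovaTerms(), anovaTerms())
    B <- Y %*% X %*% XtXi                    # genes x 8
    colnames(B) <- anovaTerms()
    res <- Y - B %*% t(X)
    sigma2 <- rowSums(res^2) / df
    se <- sqrt(outer(sigma2, diag(XtXi)))
    dimnames(se) <- dimnames(B)
    tstat <- B / se
    p <- 2 * pt(-abs(tstat), df)
    # zero-residual genes: exact coefficients, p from the point null
    deg <- sigma2 <= .Machine$double.eps * 100
    if (any(deg))
        p[deg, ] <- ifelse(abs(B[deg, , drop = FALSE]) <
            sqrt(.Machine$double.eps), 1, 0)
    new("FactorialFit", coefficients = B, stderr = se, pvalues = p,
        sigma2 = unname(sigma2), df = as.integer(df), covUnscaled = XtXi,
        modelClass = character(0), decidingTerms = character(0))
}

# Term families used for classification: the three-way interaction, the
# two-way interactions, the main effects.
termFamilies <- function() list(
    "three-way" = "TMR",
    "two-way" = c("TM", "TR", "MR"),
    "one-way" = c("T", "M", "R"))

#' Assign each gene to its most parsimonious model class
#'
#' Top-down hierarchy on the saturated fit: a gene is \emph{three-way} if
#' its \code{TMR} term is significant, else \emph{two-way} if any two-way
#' interaction is significant, else \emph{one-way} if any main effect is
#' significant, else \emph{insignificant}. Significance is BH-FDR at level
#' \code{alpha}; with \code{scope = "family"} (default) the BH adjustment
#' pools p-values across genes within each term family (\code{TMR}; the
#' two-way terms; the main effects), with \code{scope = "global"} it pools
#' all seven effect terms of all genes.
#'
#' @param fit a \linkS4class{FactorialFit} covering at least two genes.
#' @param alpha FDR level, in (0, 1).
#' @param scope \code{"family"} or \code{"global"}.
#' @return the fit with \code{modelClass} and \code{decidingTerms} filled
#'   in; retrieve classes with \code{\link{modelClasses}}.
#' @export
classifyModels <- function(fit, alpha = 0.05,
        scope = c("family", "global")) {
    stopifnot(is(fit, "FactorialFit"))
    scope <- match.arg(scope)
    if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
    P <- fit@pvalues
    if (nrow(P) < 2L)
        stop("FDR across genes needs at least 2 genes")
    fams <- termFamilies()
    sig <- matrix(FALSE, nrow(P), 8L, dimnames = dimnames(P))
    if (scope == "family") {
        for (terms in fams) {
            q <- p.adjust(as.vector(P[, terms, drop = FALSE]), "BH")
            sig[, terms] <- matrix(q < alpha, nrow(P))
        }
    } else {
        terms <- unlist(fams, use.names = FALSE)
        q <- p.adjust(as.vector(P[, terms, drop = FALSE]), "BH")
        sig[, terms] <- matrix(q < alpha, nrow(P))
    }
    cls <- character(nrow(P)); dec <- character(nrow(P))
    for (g in seq_len(nrow(P))) {
        hit <- ""
        for (cl in names(fams)) {
            terms <- fams[[cl]][sig[g, fams[[cl]]]]
            if (length(terms)) { hit <- cl; dec[g] <- paste(terms,
                collapse = ","); break }
        }
        cls[g] <- if (hit == "") "insignificant" else hit
    }
    fit@modelClass <- cls
    fit@decidingTerms <- dec
    validObject(fit)
    fit
}
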