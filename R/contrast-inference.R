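## Contrast-inference module: the printed condition comparisons as weighted
## coefficient contrasts, FDR + fold-change filters, functional groups.

#' Comparison identifiers
#'
#' \code{retinalComparisons} returns the four retinal comparisons of the
#' validation study; \code{allComparisons} appends the retina-specificity
#' and whole-embryo mutation comparisons used for functional-group
#' assignment.
#'
#' @return character vector of comparison ids.
#' @export
retinalComparisons <- function() c("YR36/WR36", "YR52/WR52", "WR52/WR36",
    "YR52/YR36")

#' @rdname retinalComparisons
#' @export
allComparisons <- function() c(retinalComparisons(),
    "retina/whole@36", "retina/whole@52", "YE36/WE36", "YE52/WE52")

#' Coefficient weights of a condition comparison
#'
#' Returns the weight vector over the eight saturated-model coefficients
#' that expresses a two-condition comparison for a given model class.
#' Under indicator coding the weights are the cell-indicator differences,
#' e.g. for the three-way class YR36/WR36 selects \code{M + MR} and
#' YR52/WR52 selects \code{M + MR + TM + TMR}. For lower classes the
#' weights drop the terms absent from that class. The retina/whole
#' comparisons (retina specificity, evaluated in wild type) select
#' \code{R} at 36 hpf and \code{R + TR} at 52 hpf; the whole-embryo
#' mutation comparisons select \code{M} at 36 hpf and \code{M + TM} at
#' 52 hpf.
#'
#' For the one-way class at YR52/WR52, the model-implied weight is
#' \code{M} alone; \code{literalOneWay52 = TRUE} instead uses \code{M + T}
#' as printed in the source methods (the two disagree; see the methods
#' vignette).
#'
#' @param modelClass \code{"three-way"}, \code{"two-way"} or
#'   \code{"one-way"}.
#' @param comparison one of \code{YR36/WR36}, \code{YR52/WR52},
#'   \code{WR52/WR36}, \code{YR52/YR36}, \code{retina/whole@36},
#'   \code{retina/whole@52}, \code{YE36/WE36}, \code{YE52/WE52}.
#' @param literalOneWay52 use the literal printed one-way YR52/WR52 null.
#' @return named numeric weight vector of length 8 (entries in -1/0/1).
#' @export
#' @examples
#' contrastWeights("three-way", "YR52/WR52")
contrastWeights <- function(modelClass, comparison,
        literalOneWay52 = FALSE) {
    if (!modelClass %in% c("three-way", "two-way", "one-way"))
        stop("no contrasts are defined for class '", modelClass, "'")
    if (!comparison %in% allComparisons())
        stop("unknown comparison '", comparison, "'")
    w <- setNames(numeric(8), anovaTerms())
    terms <- switch(comparison,
        "YR36/WR36" = switch(modelClass,
            "three-way" = c("M", "MR"), "two-way" = c("M", "MR"),
            "one-way" = "M"),
        "YR52/WR52" = switch(modelClass,
            "three-way" = c("M", "MR", "TM", "TMR"),
            "two-way" = c("M", "MR", "TM"),
            "one-way" = if (literalOneWay52) c("M", "T") else "M"),
        "WR52/WR36" = switch(modelClass,
            "three-way" = c("T", "TR"), "two-way" = c("T", "TR"),
            "one-way" = "T"),
        "YR52/YR36" = switch(modelClass,
            "three-way" = c("T", "TR", "TM", "TMR"),
            "two-way" = c("T", "TR", "TM"), "one-way" = "T"),
        "retina/whole@36" = "R",
        "retina/whole@52" = switch(modelClass,
            "three-way" = c("R", "TR"), "two-way" = c("R", "TR"),
            "one-way" = "R"),
        "YE36/WE36" = "M",
        "YE52/WE52" = switch(modelClass,
            "three-way" = c("M", "TM"), "two-way" = c("M", "TM"),
            "one-way" = "M"))
    w[terms] <- 1
    w
}

#' Test a coefficient contrast for every gene
#'
#' The estimate is the weighted sum of fitted coefficients; its standard
#' error comes from the OLS covariance, and the p-value from a two-sided t
#' test on the residual degrees of freedom. A gene with zero residual
#' variance gets p = 1 for a zero estimate and p = 0 (degenerate) for a
#' nonzero one.
#'
#' @param fit a \linkS4class{FactorialFit}.
#' @param weights length-8 weight vector (see
#'   \code{\link{contrastWeights}}), or a genes x 8 matrix giving each
#'   gene its own weights.
#' @return data.frame \code{gene}, \code{estimate} (log2), \code{se},
#'   \code{p}.
#' @export
testContrast <- function(fit, weights) {
    stopifnot(is(fit, "FactorialFit"))
    if (fit@df < 1L) stop("positive residual df required")
    B <- fit@coefficients
    if (is.matrix(weights)) {
        stopifnot(nrow(weights) == nrow(B), ncol(weights) == 8L)
        est <- rowSums(B * weights)
        wvar <- rowSums((weights %*% fit@covUnscaled) * weights)
    } else {
        stopifnot(length(weights) == 8L)
        est <- drop(B %*% weights)
        wvar <- drop(crossprod(weights, fit@covUnscaled %*% weights))
    }
    se <- sqrt(fit@sigma2 * wvar)
    deg <- fit@sigma2 <= .Machine$double.eps * 100
    p <- ifelse(!deg, 2 * pt(-abs(est / se), fit@df),
        ifelse(abs(est) < sqrt(.Machine$double.eps), 1, 0))
    data.frame(gene = rownames(B), estimate = unname(est),
        se = unname(se), p = unname(p), stringsAsFactors = FALSE)
}

#' Signed linear fold change of a log2 difference
#'
#' The field's signed convention: \eqn{2^d} for \eqn{d \ge 0} and
#' \eqn{-2^{-d}} for \eqn{d < 0}, so a log2 difference of -0.226 prints as
#' -1.17. \eqn{|FC| \ge 2} is equivalent to \eqn{|d| \ge 1}.
#'
#' @param log2Estimate numeric vector of log2 differences.
#' @return signed fold changes; magnitude always >= 1.
#' @export
#' @examples
#' signedFoldChange(c(1, 0, log2(1/1.17)))
signedFoldChange <- function(log2Estimate) {
    stopifnot(all(is.finite(log2Estimate)))
    ifelse(log2Estimate >= 0, 2^log2Estimate, -(2^(-log2Estimate)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; monotone in the ranked p-values and never
#' smaller than the raw p.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted values (q-values in the BH sense).
#' @export
adjustFDR <- function(p) {
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
        stop("p-values must lie in [0, 1]")
    p.adjust(p, method = "BH")
}

#' Contrast results for a set of comparisons
#'
#' Runs \code{\link{testContrast}} for each requested comparison using
#' each gene's class-specific weights (insignificant-class genes get NA
#' results: no contrast is defined for them), BH-adjusts p-values across
#' genes within each comparison, and applies the two significance
#' criteria: q < \code{alpha} and |signed fold change| >= \code{fcCutoff}.
#'
#' @param fit a classified \linkS4class{FactorialFit}.
#' @param comparisons character vector of comparison ids.
#' @param alpha FDR level for the significance flag.
#' @param fcCutoff linear fold-change cutoff (>= 1).
#' @param literalOneWay52 see \code{\link{contrastWeights}}.
#' @return data.frame \code{gene}, \code{comparison}, \code{estimate},
#'   \code{fc} (signed), \code{p}, \code{q}, \code{significant}.
#' @export
retinalContrasts <- function(fit, comparisons = retinalComparisons(),
        alpha = 0.05, fcCutoff = 2, literalOneWay52 = FALSE) {
    cls <- modelClasses(fit)
    testable <- cls != "insignificant"
    out <- lapply(comparisons, function(cmp) {
        W <- matrix(0, length(cls), 8L)
        for (mc in c("three-way", "two-way", "one-way")) {
            i <- which(cls == mc)
            if (length(i))
                W[i, ] <- matrix(contrastWeights(mc, cmp, literalOneWay52),
                    length(i), 8L, byrow = TRUE)
        }
        r <- testContrast(fit, W)
        r$estimate[!testable] <- NA_real_
        r$p[!testable] <- NA_real_
        q <- rep(NA_real_, nrow(r))
        q[testable] <- adjustFDR(r$p[testable])
        fc <- rep(NA_real_, nrow(r))
        fc[testable] <- signedFoldChange(r$estimate[testable])
        data.frame(gene = r$gene, comparison = cmp, estimate = r$estimate,
            fc = fc, p = r$p, q = q,
            significant = !is.na(q) & q < alpha & abs(fc) >= fcCutoff,
            stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Assign three functional groups from contrast results
#'
#' Group (i), mutation-regulated retinal genes: either retinal mutation
#' contrast (YR36/WR36 or YR52/WR52) passes both criteria (q < alpha and
#' |FC| >= cutoff). Group (ii), retina-specific mutation-independent
#' genes: the retina/whole contrast passes at both 36 and 52 hpf. Group
#' (iii), mutation-regulated outside the retina: a whole-embryo mutation
#' contrast passes at either stage. Genes matching none of these get
#' \code{"none"}; the rules are applied in that order so every gene gets
#' exactly one group.
#'
#' @param contrasts output of \code{\link{retinalContrasts}} containing
#'   the comparisons \code{YR36/WR36}, \code{YR52/WR52},
#'   \code{retina/whole@36}, \code{retina/whole@52}, \code{YE36/WE36},
#'   \code{YE52/WE52}.
#' @return data.frame \code{gene}, \code{group} (\code{i}, \code{ii},
#'   \code{iii} or \code{none}), \code{deciding} (comparisons that fired).
#' @export
classifyFunctionalGroup <- function(contrasts) {
    need <- c("YR36/WR36", "YR52/WR52", "retina/whole@36",
        "retina/whole@52", "YE36/WE36", "YE52/WE52")
    missing <- setdiff(need, unique(contrasts$comparison))
    if (length(missing))
        stop("missing contrast(s): ", paste(missing, collapse = ", "))
    sig <- function(cmp) {
        x <- contrasts[contrasts$comparison == cmp, ]
        setNames(!is.na(x$significant) & x$significant, x$gene)
    }
    s <- lapply(setNames(need, need), sig)
    genes <- names(s[[1]])
    grp <- character(length(genes)); dec <- character(length(genes))
    for (k in seq_along(genes)) {
        g <- genes[k]
        if (s[["YR36/WR36"]][g] || s[["YR52/WR52"]][g]) {
            grp[k] <- "i"
            dec[k] <- paste(need[1:2][c(s[["YR36/WR36"]][g],
                s[["YR52/WR52"]][g])], collapse = ",")
        } else if (s[["retina/whole@36"]][g] && s[["retina/whole@52"]][g]) {
            grp[k] <- "ii"
            dec[k] <- "retina/whole@36,retina/whole@52"
        } else if (s[["YE36/WE36"]][g] || s[["YE52/WE52"]][g]) {
            grp[k] <- "iii"
            dec[k] <- paste(need[5:6][c(s[["YE36/WE36"]][g],
                s[["YE52/WE52"]][g])], collapse = ",")
        } else {
            grp[k] <- "none"; dec[k] <- ""
        }
    }
    data.frame(gene = genes, group = grp, deciding = dec,
        stringsAsFactors = FALSE)
}
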