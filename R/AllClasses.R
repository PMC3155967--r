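## Central S4 classes. Terms of the saturated 2x2x2 model are always kept in
## the fixed order below; indicator (treatment) coding with reference levels
## WT / whole-embryo / 36 hpf, so e.g. the YR36 - WR36 cell-mean difference
## is M + M:R on the coefficient scale.

#' Term names of the saturated three-way factorial model
#'
#' Coefficient order used throughout the package: intercept (\code{mu}),
#' main effects for stage (\code{T}, 52 vs 36 hpf), mutation (\code{M},
#' mutant vs wild type) and tissue (\code{R}, retina vs whole embryo),
#' the three two-way interactions and the three-way interaction.
#'
#' @return Character vector of length 8.
#' @export
#' @examples
#' anovaTerms()
anovaTerms <- function() c("mu", "T", "M", "R", "TM", "TR", "MR", "TMR")

setOldClass("hclust")

#' FactorialDesign: the 2x2x2 sample layout
#'
#' Describes the factorial design of the experiment: mutation
#' (\code{M}: \code{WT} / \code{yng}), tissue (\code{R}: \code{whole} /
#' \code{retina}) and developmental stage (\code{T}: \code{36} / \code{52}
#' hpf), with a fixed number of replicates per design cell. Sample labels
#' follow the field convention (WR36, YR52, WE36, YE52, ...), suffixed with
#' the replicate index.
#'
#' @slot samples data.frame with columns \code{sample}, \code{M}, \code{R},
#'   \code{T}, \code{replicate}; one row per array.
#' @slot replicates integer(1), replicates per design cell.
#' @export
setClass("FactorialDesign",
    representation(samples = "data.frame", replicates = "integer"))

setValidity("FactorialDesign", function(object) {
    s <- object@samples
    need <- c("sample", "M", "R", "T", "replicate")
    if (!all(need %in% names(s)))
        return(paste("samples must have columns", paste(need, collapse = ", ")))
    if (anyDuplicated(s$sample))
        return("sample labels must be unique")
    if (!all(s$M %in% c("WT", "yng"))) return("M levels must be WT/yng")
    if (!all(s$R %in% c("whole", "retina"))) return("R levels must be whole/retina")
    if (!all(s$T %in% c("36", "52"))) return("T levels must be 36/52")
    cell <- interaction(s$M, s$R, s$T, drop = FALSE)
    tab <- table(factor(cell, levels = levels(cell)))
    if (length(tab) != 8L) return("design must have exactly 8 cells")
    if (length(unique(as.integer(tab))) != 1L)
        return("every design cell must have the same replicate count")
    if (as.integer(tab[1L]) != object@replicates)
        return("replicates slot disagrees with the sample table")
    key <- interaction(s$M, s$R, s$T, s$replicate)
    if (anyDuplicated(key))
        return("(M, R, T, replicate) tuples must be unique")
    TRUE
})

#' FactorialExperiment: log2 expression with factorial annotations
#'
#' A \linkS4class{SummarizedExperiment} whose single assay \code{"log2"}
#' holds gene x sample log2 intensities and whose \code{colData} carries the
#' \code{M}, \code{R}, \code{T} and \code{replicate} annotations of a
#' \linkS4class{FactorialDesign}.
#'
#' @export
setClass("FactorialExperiment", contains = "SummarizedExperiment")

setValidity("FactorialExperiment", function(object) {
    if (!"log2" %in% SummarizedExperiment::assayNames(object))
        return("assay 'log2' is required")
    cd <- SummarizedExperiment::colData(object)
    need <- c("M", "R", "T", "replicate")
    if (!all(need %in% names(cd)))
        return(paste("colData must have columns", paste(need, collapse = ", ")))
    a <- SummarizedExperiment::assay(object, "log2")
    if (anyNA(a)) return("log2 assay must not contain missing values")
    cell <- paste(cd$M, cd$R, cd$T)
    if (any(table(cell) < 2L))
        return("at least 2 replicates per design cell are required")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        return("unique gene ids (rownames) are required")
    TRUE
})

#' FactorialFit: per-gene saturated three-way ANOVA fits
#'
#' Ordinary least-squares estimates of the eight coefficients of the
#' saturated model for every gene, with per-term t-test p-values and (after
#' \code{\link{classifyModels}}) the assigned parsimonious model class.
#'
#' @slot coefficients genes x 8 matrix of coefficient estimates (log2
#'   units), columns in \code{\link{anovaTerms}} order.
#' @slot stderr genes x 8 matrix of coefficient standard errors.
#' @slot pvalues genes x 8 matrix of two-sided per-term t-test p-values.
#' @slot sigma2 numeric vector of residual variances.
#' @slot df integer(1), residual degrees of freedom (n - 8).
#' @slot covUnscaled 8 x 8 unscaled coefficient covariance \eqn{(X'X)^{-1}}.
#' @slot modelClass character vector: \code{"three-way"}, \code{"two-way"},
#'   \code{"one-way"} or \code{"insignificant"} per gene (empty until
#'   \code{\link{classifyModels}} is run).
#' @slot decidingTerms character vector naming the term(s) that decided
#'   each gene's class.
#' @export
setClass("FactorialFit",
    representation(coefficients = "matrix", stderr = "matrix",
        pvalues = "matrix", sigma2 = "numeric", df = "integer",
        covUnscaled = "matrix", modelClass = "character",
        decidingTerms = "character"))

setValidity("FactorialFit", function(object) {
    if (!identical(colnames(object@coefficients), anovaTerms()))
        return("coefficient columns must be the canonical term order")
    if (any(object@sigma2 < 0)) return("residual variance must be >= 0")
    if (object@df < 1L) return("positive residual degrees of freedom required")
    if (length(object@modelClass) &&
        !all(object@modelClass %in% c("three-way", "two-way", "one-way",
                                      "insignificant")))
        return("unknown model class")
    TRUE
})

#' DomainClustering: dendrogram of expression-domain vectors with AU support
#'
#' Result of \code{\link{domainClustering}}: the average-linkage tree over
#' binary gene x retinal-domain vectors together with per-clade multiscale
#' bootstrap counts and approximately-unbiased (AU) support values.
#'
#' @slot hclust the \code{\link[stats]{hclust}} tree (binary distance,
#'   average linkage).
#' @slot matrix the binary gene x domain matrix that was clustered.
#' @slot support data.frame with one row per internal node: members
#'   (comma-separated gene ids), \code{bp} (bootstrap probability at scale
#'   1), \code{au}, \code{p} (= 1 - AU), fitted signed distance \code{v}
#'   and curvature \code{c}, and a \code{degenerate} flag.
#' @slot counts clades x scales matrix of bootstrap hit counts.
#' @slot scales numeric vector of resampling scales r.
#' @slot nBoot integer(1), bootstrap replications per scale.
#' @slot seed integer(1), RNG seed used for resampling.
#' @export
setClass("DomainClustering",
    representation(hclust = "hclust", matrix = "matrix",
        support = "data.frame", counts = "matrix", scales = "numeric",
        nBoot = "integer", seed = "integer"))
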