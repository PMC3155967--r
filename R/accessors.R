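## Accessors and show methods.

#' @describeIn FactorialDesign-class number of replicates per design cell.
#' @param object a \code{FactorialDesign}.
#' @export
setGeneric("replicates", function(object) standardGeneric("replicates"))

#' @export
setMethod("replicates", "FactorialDesign", function(object) object@replicates)

#' Sample annotation table of a design or experiment
#'
#' @param object a \linkS4class{FactorialDesign} or
#'   \linkS4class{FactorialExperiment}.
#' @return data.frame with columns \code{sample}, \code{M}, \code{R},
#'   \code{T}, \code{replicate}.
#' @export
setGeneric("designTable", function(object) standardGeneric("designTable"))

#' @export
setMethod("designTable", "FactorialDesign", function(object) object@samples)

#' @export
setMethod("designTable", "FactorialExperiment", function(object) {
    cd <- SummarizedExperiment::colData(object)
    data.frame(sample = colnames(object), M = cd$M, R = cd$R, T = cd$T,
        replicate = cd$replicate, stringsAsFactors = FALSE)
})

#' Assigned parsimonious model class per gene
#'
#' @param object a \linkS4class{FactorialFit} after
#'   \code{\link{classifyModels}}.
#' @return named character vector of classes.
#' @export
setGeneric("modelClasses", function(object) standardGeneric("modelClasses"))

#' @export
setMethod("modelClasses", "FactorialFit", function(object) {
    if (!length(object@modelClass))
        stop("no model classes assigned yet; run classifyModels()")
    setNames(object@modelClass, rownames(object@coefficients))
})

#' @export
setMethod("coef", "FactorialFit", function(object, ...) object@coefficients)

#' Per-clade support table of a domain clustering
#'
#' @param object a \linkS4class{DomainClustering}.
#' @return data.frame with one row per internal node of the dendrogram.
#' @export
setGeneric("supportTable", function(object) standardGeneric("supportTable"))

#' @export
setMethod("supportTable", "DomainClustering", function(object) object@support)

setMethod("show", "FactorialDesign", function(object) {
    cat("FactorialDesign: 2x2x2 (M x R x T),", object@replicates,
        "replicates/cell,", nrow(object@samples), "samples\n")
})

setMethod("show", "FactorialExperiment", function(object) {
    cat("FactorialExperiment:", nrow(object), "genes x", ncol(object),
        "samples (assay 'log2')\n")
    methods::callNextMethod()
})

setMethod("show", "FactorialFit", function(object) {
    cat("FactorialFit:", nrow(object@coefficients),
        "genes, residual df", object@df, "\n")
    if (length(object@modelClass)) {
        cat("model classes:\n")
        print(table(object@modelClass))
    } else {
        cat("model classes: not yet assigned (run classifyModels)\n")
    }
})

setMethod("show", "DomainClustering", function(object) {
    cat("DomainClustering:", nrow(object@matrix), "genes x",
        ncol(object@matrix), "domains; average linkage on binary distance\n")
    cat("multiscale bootstrap:", object@nBoot, "replicates x",
        length(object@scales), "scales (seed", object@seed, ")\n")
    flags <- flagClades(object)
    cat(sum(flags == "red"), "clades with p < 0.05,",
        sum(flags == "green"), "with 0.05 <= p < 0.1\n")
})
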