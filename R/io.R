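## IO module: TSV readers/writers for every table the pipeline exchanges,
## plus Newick export of the support-annotated dendrogram. All formats are
## plain text so round trips are exact and diffable.

#' Write / read a log2 expression matrix with its design sidecar
#'
#' The expression file is genes x samples TSV with a header row of sample
#' labels and gene ids in the first column; the sidecar maps each sample
#' to its M/R/T/replicate annotation.
#'
#' @param x a \linkS4class{FactorialExperiment}.
#' @param path expression TSV path.
#' @param designPath design sidecar TSV path.
#' @return \code{writeExpression}: invisibly, the paths.
#'   \code{readExpression}: a \code{FactorialExperiment}.
#' @export
writeExpression <- function(x, path, designPath) {
    stopifnot(is(x, "FactorialExperiment"))
    a <- SummarizedExperiment::assay(x, "log2")
    df <- data.frame(gene = rownames(a), a, check.names = FALSE,
        stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(designTable(x), designPath, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(c(path, designPath))
}

#' @rdname writeExpression
#' @export
readExpression <- function(path, designPath) {
    df <- read.delim(path, check.names = FALSE, colClasses = NA)
    if (names(df)[1L] != "gene") stop("first column must be 'gene'")
    if (anyDuplicated(df$gene)) stop("duplicate gene ids")
    s <- read.delim(designPath, colClasses = "character")
    s$replicate <- as.integer(s$replicate)
    design <- new("FactorialDesign", samples = s,
        replicates = as.integer(table(paste(s$M, s$R, s$T))[1L]))
    values <- as.matrix(df[, -1L, drop = FALSE])
    rownames(values) <- df$gene
    bad <- which(!is.finite(values), arr.ind = TRUE)
    if (nrow(bad))
        stop("non-numeric expression value at gene ", df$gene[bad[1L, 1L]],
            ", sample ", colnames(values)[bad[1L, 2L]])
    FactorialExperiment(values, design)
}

#' Write / read the per-gene comparison summary table (S1 shape)
#'
#' One row per gene; for every comparison a fold-change column
#' \code{fc.<comparison>}, a q-value column \code{q.<comparison>}, a
#' significance flag \code{sig.<comparison>} and (when scores are given)
#' an ISH score column \code{ish.<comparison>}. Comparison ids use
#' \code{.} in place of \code{/} in column names.
#'
#' @param contrasts output of \code{\link{retinalContrasts}}.
#' @param scores optional ISH score data.frame (\code{gene},
#'   \code{comparison}, \code{score}).
#' @param path TSV path.
#' @return \code{writeComparisonTable}: invisibly, the path.
#'   \code{readComparisonTable}: list with \code{contrasts} and
#'   \code{scores} data.frames in long form.
#' @export
writeComparisonTable <- function(contrasts, path, scores = NULL) {
    cmps <- unique(contrasts$comparison)
    genes <- unique(contrasts$gene)
    out <- data.frame(gene = genes, stringsAsFactors = FALSE)
    key <- function(prefix, cmp) paste0(prefix, ".", gsub("/", ".", cmp))
    for (cmp in cmps) {
        x <- contrasts[contrasts$comparison == cmp, ]
        i <- match(genes, x$gene)
        out[[key("fc", cmp)]] <- x$fc[i]
        out[[key("q", cmp)]] <- x$q[i]
        out[[key("sig", cmp)]] <- x$significant[i]
        if (!is.null(scores)) {
            sc <- scores[scores$comparison == cmp, ]
            out[[key("ish", cmp)]] <- sc$score[match(genes, sc$gene)]
        }
    }
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeComparisonTable
#' @export
readComparisonTable <- function(path) {
    df <- read.delim(path, check.names = FALSE)
    if (anyDuplicated(df$gene)) stop("duplicate gene ids")
    fcCols <- grep("^fc\\.", names(df), value = TRUE)
    cmps <- sub("^fc\\.", "", fcCols)
    toCmp <- function(x) sub("^([A-Za-z0-9]+)\\.", "\\1/", x)
    long <- lapply(cmps, function(cmp) {
        fc <- df[[paste0("fc.", cmp)]]
        data.frame(gene = df$gene, comparison = toCmp(cmp),
            estimate = ifelse(fc >= 0, log2(pmax(fc, 1)),
                -log2(pmax(-fc, 1))),
            fc = fc, q = df[[paste0("q.", cmp)]],
            significant = as.logical(df[[paste0("sig.", cmp)]]),
            stringsAsFactors = FALSE)
    })
    contrasts <- do.call(rbind, long)
    scores <- NULL
    ishCols <- grep("^ish\\.", names(df), value = TRUE)
    if (length(ishCols)) {
        scores <- do.call(rbind, lapply(sub("^ish\\.", "", ishCols),
            function(cmp) {
                sc <- df[[paste0("ish.", cmp)]]
                bad <- which(!sc %in% c(-1L, 0L, 1L))
                if (length(bad))
                    stop("score outside {-1,0,1} at gene ",
                        df$gene[bad[1L]], ", comparison ", toCmp(cmp))
                data.frame(gene = df$gene, comparison = toCmp(cmp),
                    score = as.integer(sc), stringsAsFactors = FALSE)
            }))
    }
    list(contrasts = contrasts, scores = scores)
}

#' Write / read a binary gene x domain matrix (S2 shape)
#'
#' @param mat binary matrix with gene rownames and domain colnames.
#' @param path TSV path.
#' @return \code{writeDomainMatrix}: invisibly, the path.
#'   \code{readDomainMatrix}: the validated matrix.
#' @export
writeDomainMatrix <- function(mat, path) {
    df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
        stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeDomainMatrix
#' @examples
#' f <- system.file("extdata", "synthetic_domain_matrix.tsv",
#'     package = "retscreen")
#' dim(readDomainMatrix(f))
#' @export
readDomainMatrix <- function(path) {
    df <- read.delim(path, check.names = FALSE)
    if (names(df)[1L] != "gene") stop("first column must be 'gene'")
    if (anyDuplicated(df$gene)) stop("duplicate gene ids")
    if (anyDuplicated(names(df))) stop("duplicate domain columns")
    mat <- as.matrix(df[, -1L, drop = FALSE])
    rownames(mat) <- df$gene
    bad <- which(!(mat %in% c(0, 1)))
    if (length(bad)) {
        rc <- arrayInd(bad[1L], dim(mat))
        stop("non-binary entry '", mat[bad[1L]], "' at gene ",
            rownames(mat)[rc[1L]], ", domain ", colnames(mat)[rc[2L]])
    }
    mat
}

#' Write a truth table or any plain data.frame as TSV
#' @param df data.frame.
#' @param path TSV path.
#' @return invisibly, the path.
#' @export
writeTable <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Export a support-annotated dendrogram as Newick
#'
#' Internal nodes are labelled \code{"AU|BP"} (both in [0,1], three
#' decimals). The tree is the UPGMA dendrogram converted to a phylo
#' object.
#'
#' @param dc a \linkS4class{DomainClustering}.
#' @param path output Newick path.
#' @return invisibly, the path.
#' @export
writeSupportTree <- function(dc, path) {
    phy <- ape::as.phylo(dc@hclust)
    ntip <- length(phy$tip.label)
    sup <- dc@support
    supKey <- vapply(strsplit(sup$members, ","),
        function(g) paste(sort(g), collapse = ","), "")
    labs <- character(phy$Nnode)
    for (node in seq_len(phy$Nnode)) {
        tips <- phy$tip.label[descendantTips(phy, ntip + node)]
        i <- match(paste(sort(tips), collapse = ","), supKey)
        labs[node] <- if (is.na(i)) "" else
            sprintf("%.3f|%.3f", sup$au[i], sup$bp[i])
    }
    phy$node.label <- labs
    ape::write.tree(phy, file = path)
    invisible(path)
}

# Tip indices descending from an internal node of a phylo tree.
descendantTips <- function(phy, node) {
    ntip <- length(phy$tip.label)
    out <- integer(0)
    stack <- node
    while (length(stack)) {
        x <- stack[1L]; stack <- stack[-1L]
        if (x <= ntip) out <- c(out, x)
        else stack <- c(stack, phy$edge[phy$edge[, 1L] == x, 2L])
    }
    sort(out)
}
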