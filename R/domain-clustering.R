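## Domain-clustering module: binary distance, UPGMA, multiscale bootstrap
## with approximately-unbiased (AU) clade support.

#' Binary (asymmetric Jaccard) distance between presence/absence vectors
#'
#' The number of positions where exactly one vector is 1, divided by the
#' number of positions where at least one is 1; joint absences carry no
#' information. Undefined (error) when both vectors are all-zero — such
#' genes are excluded upstream.
#'
#' @param a,b binary vectors of equal length.
#' @return distance in [0, 1].
#' @export
#' @examples
#' binaryDistance(c(1, 1, 0), c(0, 1, 1))  # 2/3
binaryDistance <- function(a, b) {
    if (length(a) != length(b)) stop("vectors must have equal length")
    if (!all(c(a, b) %in% c(0, 1))) stop("vectors must be binary")
    un <- sum(a | b)
    if (un == 0) stop("binary distance undefined for two all-zero vectors")
    sum(xor(a, b)) / un
}

#' Pairwise binary distances of a domain matrix
#'
#' @param mat binary gene x domain matrix with no all-zero rows.
#' @return a \code{\link[stats]{dist}} object.
#' @export
binaryDistMatrix <- function(mat) {
    mat <- as.matrix(mat)
    if (!all(mat %in% c(0, 1))) stop("matrix must be binary")
    if (any(rowSums(mat) == 0))
        stop("all-zero rows are not admitted to clustering: ",
            paste(rownames(mat)[rowSums(mat) == 0], collapse = ", "))
    dist(mat, method = "binary")
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Unweighted pair-group agglomeration on a distance matrix; merge heights
#' are non-decreasing. Ties are resolved by \code{\link[stats]{hclust}}'s
#' fixed internal ordering, so results are reproducible.
#'
#' @param d a \code{dist} object or symmetric matrix with zero diagonal.
#' @return an \code{hclust} tree.
#' @export
upgmaCluster <- function(d) {
    if (is.matrix(d)) {
        if (!isSymmetric(unname(d)) || any(diag(d) != 0))
            stop("distance matrix must be symmetric with zero diagonal")
        d <- as.dist(d)
    }
    if (attr(d, "Size") < 2L) stop("need at least 2 items")
    hclust(d, method = "average")
}

#' Leaf index sets of every internal node of an hclust tree
#'
#' Returned in merge order; the last set is the root (all leaves).
#'
#' @param hc an \code{hclust} object.
#' @return list of sorted integer leaf-index vectors.
#' @export
cladeMembers <- function(hc) {
    n <- length(hc$order)
    sets <- vector("list", n - 1L)
    for (k in seq_len(n - 1L)) {
        pick <- function(j) if (j < 0) -j else sets[[j]]
        sets[[k]] <- sort(c(pick(hc$merge[k, 1L]), pick(hc$merge[k, 2L])))
    }
    sets
}

#' Multiscale bootstrap counts for the clades of a domain clustering
#'
#' For each scale r, draws \code{nBoot} resamples of the domain columns
#' with replacement at size \code{round(r * ncol)}, reclusters each
#' resample (binary distance, UPGMA) and counts, for every clade of the
#' original tree, the resamples in which exactly that member set appears.
#' Columns are the resampling unit because genes are the clustered objects
#' and domains their features.
#'
#' @param mat binary gene x domain matrix (max 64 genes).
#' @param scales positive resampling scales; default r in 0.5 ... 1.4.
#' @param nBoot bootstrap replications per scale (>= 100).
#' @param seed RNG seed of the resampler (own generator; independent of
#'   R's RNG state).
#' @return list with \code{hclust}, \code{clades} (member index sets),
#'   \code{counts} (clades x scales), \code{scales}, \code{nBoot},
#'   \code{seed}.
#' @export
multiscaleBootstrap <- function(mat, scales = seq(0.5, 1.4, by = 0.1),
        nBoot = 10000L, seed = 1L) {
    mat <- as.matrix(mat)
    if (!all(mat %in% c(0, 1))) stop("matrix must be binary")
    if (nrow(mat) > 64L) stop("at most 64 genes are supported")
    if (any(scales <= 0)) stop("scales must be positive")
    if (nBoot < 100L) stop("nBoot must be >= 100")
    m <- round(scales * ncol(mat))
    if (any(m < 2L)) stop("resample size below 2 at the smallest scale")
    hc <- upgmaCluster(binaryDistMatrix(mat))
    clades <- cladeMembers(hc)
    imat <- mat
    storage.mode(imat) <- "integer"
    counts <- cpp_multiscale_counts(imat, clades, as.numeric(scales),
        as.integer(nBoot), as.integer(seed))
    dimnames(counts) <- list(NULL, paste0("r", scales))
    list(hclust = hc, clades = clades, counts = counts,
        scales = as.numeric(scales), nBoot = as.integer(nBoot),
        seed = as.integer(seed))
}

#' Approximately-unbiased p-value from multiscale bootstrap counts
#'
#' Per-scale bootstrap probabilities BP_r = count/nBoot are clipped to
#' [1/(2 nBoot), 1 - 1/(2 nBoot)] to keep probits finite, then the probit
#' transform is fitted as probit(1 - BP_r) = v sqrt(r) + c / sqrt(r) by
#' weighted least squares with binomial weights; AU = 1 - Phi(v - c) and
#' the cluster p-value is 1 - AU. BP is reported at the scale nearest 1.
#' When fewer than two scales have counts strictly inside (0, nBoot), the
#' fit runs on clipped values and the result is flagged degenerate.
#'
#' @param counts per-scale bootstrap hit counts for one clade (numeric;
#'   expected counts are accepted for calibration work).
#' @param nBoot replications per scale.
#' @param scales the resampling scales.
#' @return list with \code{bp}, \code{au}, \code{p}, \code{v}, \code{c},
#'   \code{degenerate}.
#' @export
#' @examples
#' sc <- seq(0.5, 1.4, 0.1)
#' bp <- 1 - pnorm(0.5 * sqrt(sc) + 0.3 / sqrt(sc))
#' auPvalue(bp * 10000, 10000, sc)   # recovers v = 0.5, c = 0.3
auPvalue <- function(counts, nBoot, scales) {
    stopifnot(length(counts) == length(scales), length(scales) >= 2L)
    eps <- 1 / (2 * nBoot)
    bpr <- pmin(pmax(counts / nBoot, eps), 1 - eps)
    degenerate <- sum(counts > 0 & counts < nBoot) < 2L
    bp1 <- counts[which.min(abs(scales - 1))] / nBoot
    if (all(counts <= 0) || all(counts >= nBoot)) {
        # no information in the curve: AU saturates to the clipped extreme
        au <- if (all(counts >= nBoot)) 1 - eps else eps
        return(list(bp = bp1, au = au, p = 1 - au, v = NA_real_,
            c = NA_real_, degenerate = TRUE))
    }
    z <- qnorm(1 - bpr)
    w <- nBoot * dnorm(z)^2 / (bpr * (1 - bpr))
    X <- cbind(sqrt(scales), 1 / sqrt(scales))
    fit <- solve(crossprod(X, w * X), crossprod(X, w * z))
    v <- fit[1L]; cc <- fit[2L]
    au <- pnorm(cc - v)
    list(bp = bp1, au = unname(au), p = unname(1 - au), v = unname(v),
        c = unname(cc), degenerate = degenerate)
}

#' Cluster a domain matrix with multiscale-bootstrap clade support
#'
#' The full clustering stage: binary distance, UPGMA tree, multiscale
#' bootstrap of the domain columns, and per-clade AU support.
#'
#' @inheritParams multiscaleBootstrap
#' @return a \linkS4class{DomainClustering}.
#' @export
#' @examples
#' tpl <- defaultDomainTemplates()
#' mat <- simulateDomainMatrix(tpl$templates, tpl$sizes, 0.05, seed = 1)
#' dc <- domainClustering(mat, nBoot = 1000, seed = 1)
#' head(supportTable(dc))
domainClustering <- function(mat, scales = seq(0.5, 1.4, by = 0.1),
        nBoot = 10000L, seed = 1L) {
    bs <- multiscaleBootstrap(mat, scales, nBoot, seed)
    sup <- lapply(seq_along(bs$clades), function(k) {
        a <- auPvalue(bs$counts[k, ], bs$nBoot, bs$scales)
        data.frame(node = k,
            members = paste(rownames(mat)[bs$clades[[k]]], collapse = ","),
            size = length(bs$clades[[k]]), bp = a$bp, au = a$au, p = a$p,
            v = a$v, c = a$c, degenerate = a$degenerate,
            stringsAsFactors = FALSE)
    })
    sup <- do.call(rbind, sup)
    rownames(sup) <- NULL
    new("DomainClustering", hclust = bs$hclust, matrix = as.matrix(mat),
        support = sup, counts = bs$counts,
        scales = bs$scales, nBoot = bs$nBoot, seed = bs$seed)
}

#' Significance flags for clades
#'
#' \code{"red"} for cluster p-value (1 - AU) below 0.05, \code{"green"}
#' for p in [0.05, 0.1), empty otherwise.
#'
#' @param x a \linkS4class{DomainClustering} or its support table.
#' @return character vector of flags, one per internal node.
#' @export
flagClades <- function(x) {
    sup <- if (is(x, "DomainClustering")) supportTable(x) else x
    if (is.null(sup$p) || anyNA(sup$p)) stop("missing clade support")
    ifelse(sup$p < 0.05, "red", ifelse(sup$p < 0.1, "green", ""))
}

#' AU support of specific gene sets
#'
#' Looks up the support entries whose member set equals each requested
#' gene set; NA when that clade is not in the tree.
#'
#' @param dc a \linkS4class{DomainClustering}.
#' @param geneSets list of character vectors of gene ids.
#' @return numeric vector of AU values (NA where absent).
#' @export
cladeAU <- function(dc, geneSets) {
    key <- vapply(geneSets,
        function(g) paste(sort(g), collapse = ","), "")
    have <- vapply(strsplit(dc@support$members, ","),
        function(g) paste(sort(g), collapse = ","), "")
    dc@support$au[match(key, have)]
}
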