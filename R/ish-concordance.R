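## ISH-concordance module: agreement between quantitative significance
## calls and qualitative {-1, 0, +1} in situ hybridization scores.

#' Compare one microarray call with one ISH score
#'
#' A pair is identical when the microarray comparison is significant and
#' the ISH score matches the sign of its estimate, or when the comparison
#' is insignificant and the ISH score is 0 (no visible change). With
#' \code{signStrict = FALSE} a significant call agrees with any nonzero
#' score.
#'
#' @param significant logical, microarray significance call.
#' @param estimate log2 estimate of the comparison.
#' @param score ISH score in \{-1, 0, +1\}.
#' @param signStrict require sign agreement (default) rather than any
#'   nonzero score.
#' @return logical: do the two calls agree?
#' @export
compareCall <- function(significant, estimate, score, signStrict = TRUE) {
    if (!all(score %in% c(-1, 0, 1))) stop("score must be in {-1, 0, 1}")
    if (any(significant & estimate == 0))
        stop("inconsistent input: significant call with zero estimate")
    ifelse(significant,
        if (signStrict) score == sign(estimate) else score != 0,
        score == 0)
}

#' Build the identity matrix of microarray vs ISH calls
#'
#' Elementwise \code{\link{compareCall}} over the (gene, comparison) keys
#' present in both inputs; keys present in only one are dropped with a
#' message.
#'
#' @param results data.frame with columns \code{gene}, \code{comparison},
#'   \code{significant}, \code{estimate} (as from
#'   \code{\link{retinalContrasts}}).
#' @param scores data.frame with columns \code{gene}, \code{comparison},
#'   \code{score}.
#' @param signStrict see \code{\link{compareCall}}.
#' @return data.frame \code{gene}, \code{comparison}, \code{significant},
#'   \code{estimate}, \code{score}, \code{identical}.
#' @export
buildIdentityMatrix <- function(results, scores, signStrict = TRUE) {
    stopifnot(all(c("gene", "comparison", "significant", "estimate")
        %in% names(results)),
        all(c("gene", "comparison", "score") %in% names(scores)))
    kr <- paste(results$gene, results$comparison, sep = "\r")
    ks <- paste(scores$gene, scores$comparison, sep = "\r")
    common <- intersect(kr, ks)
    if (!length(common))
        stop("no (gene, comparison) keys shared between results and scores")
    dropped <- length(setdiff(kr, ks)) + length(setdiff(ks, kr))
    if (dropped)
        message(dropped, " (gene, comparison) key(s) present in only one",
            " input were dropped")
    r <- results[match(common, kr), ]
    s <- scores[match(common, ks), ]
    data.frame(gene = r$gene, comparison = r$comparison,
        significant = r$significant, estimate = r$estimate,
        score = s$score,
        identical = compareCall(r$significant, r$estimate, s$score,
            signStrict),
        stringsAsFactors = FALSE)
}

#' Concordance rate of an identity matrix
#'
#' \code{subset = "all"} uses every cell; \code{subset = "significant"}
#' restricts to cells whose microarray call is significant within the two
#' mutation-contrast columns (YR36/WR36 and YR52/WR52) — the comparisons
#' the gene selection was based on.
#'
#' @param identity output of \code{\link{buildIdentityMatrix}}.
#' @param subset \code{"all"} or \code{"significant"}.
#' @return list with \code{k} (identical), \code{n} (subset size) and
#'   \code{rate} (= k/n).
#' @export
concordanceRate <- function(identity, subset = c("all", "significant")) {
    subset <- match.arg(subset)
    x <- identity
    if (subset == "significant")
        x <- x[x$significant &
            x$comparison %in% c("YR36/WR36", "YR52/WR52"), ]
    if (!nrow(x)) stop("empty subset")
    list(k = sum(x$identical), n = nrow(x),
        rate = sum(x$identical) / nrow(x))
}

#' One-sample proportion z test against a theoretical true discovery rate
#'
#' Tests whether the observed identical proportion k/n is compatible with
#' the theoretical true discovery rate p0, using the null-variance
#' denominator: \eqn{z = (k/n - p_0) / \sqrt{p_0 (1 - p_0) / n}}, with a
#' two-sided normal p-value.
#'
#' @param k identical count (0 <= k <= n).
#' @param n subset size (>= 1).
#' @param p0 theoretical true discovery rate, in (0, 1); default 0.95.
#' @return list with \code{z}, \code{p}, \code{phat}, \code{p0}.
#' @export
#' @examples
#' tdrZTest(28, 31, 0.95)
tdrZTest <- function(k, n, p0 = 0.95) {
    if (n < 1) stop("n must be >= 1")
    if (k < 0 || k > n) stop("k must be in [0, n]")
    if (!(p0 > 0 && p0 < 1)) stop("p0 must be in (0, 1)")
    phat <- k / n
    z <- (phat - p0) / sqrt(p0 * (1 - p0) / n)
    list(z = z, p = 2 * pnorm(-abs(z)), phat = phat, p0 = p0)
}

#' Concordance summary of microarray vs ISH calls
#'
#' Convenience wrapper computing the overall rate, the significant-only
#' rate and the z test against the theoretical true discovery rate in one
#' go.
#'
#' @inheritParams buildIdentityMatrix
#' @param p0 theoretical true discovery rate.
#' @return list with the identity matrix, both rates (with counts) and
#'   the z test.
#' @export
concordanceSummary <- function(results, scores, p0 = 0.95,
        signStrict = TRUE) {
    id <- buildIdentityMatrix(results, scores, signStrict)
    overall <- concordanceRate(id, "all")
    sig <- concordanceRate(id, "significant")
    list(identity = id, overall = overall, significant = sig,
        ztest = tdrZTest(sig$k, sig$n, p0))
}
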