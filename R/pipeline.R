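## Reporting module: configuration, the end-to-end pipeline and figures.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with the study defaults: FDR
#' level 0.05, two-fold change cutoff, theoretical true discovery rate
#' 0.95, 10000 bootstrap replications over scales 0.5 ... 1.4, three
#' replicates per design cell, log2 noise sd 0.25, planted effect 1 log2
#' unit, ISH detection threshold 1 log2 unit.
#'
#' @param fdr FDR level for all significance flags.
#' @param fcCutoff linear fold-change cutoff.
#' @param tdr theoretical true discovery rate for the z test.
#' @param nBoot bootstrap replications per scale.
#' @param scales multiscale-bootstrap scale grid.
#' @param seed master RNG seed of the run.
#' @param replicates replicates per design cell.
#' @param noiseSd log2 noise sd of the expression generator.
#' @param effect magnitude of planted active coefficients (log2).
#' @param nPerClass genes per model class for the generator.
#' @param nPerGroup genes per functional group for the generator.
#' @param detectLog2 ISH detection threshold (log2).
#' @param ishFlipProb ISH score corruption probability.
#' @param domainFlipProb domain-matrix bit-flip probability.
#' @param signStrict require sign agreement in concordance calls.
#' @param literalOneWay52 use the literal printed one-way YR52/WR52 null.
#' @param layout domain column layout, \code{"18"} or \code{"13"}.
#' @return a list of class \code{retscreenConfig}.
#' @export
pipelineConfig <- function(fdr = 0.05, fcCutoff = 2, tdr = 0.95,
        nBoot = 10000L, scales = seq(0.5, 1.4, by = 0.1), seed = 1L,
        replicates = 3L, noiseSd = 0.25, effect = 1,
        nPerClass = c("insignificant" = 500, "one-way" = 500,
            "two-way" = 500, "three-way" = 500),
        nPerGroup = c(i = 200, ii = 100, iii = 100, none = 100),
        detectLog2 = 1, ishFlipProb = 0.05, domainFlipProb = 0.05,
        signStrict = TRUE, literalOneWay52 = FALSE,
        layout = c("18", "13")) {
    stopifnot(fdr > 0, fdr < 1, fcCutoff >= 1, tdr > 0, tdr < 1,
        nBoot >= 100, all(scales > 0), replicates >= 2, noiseSd > 0)
    cfg <- list(fdr = fdr, fcCutoff = fcCutoff, tdr = tdr,
        nBoot = as.integer(nBoot), scales = scales,
        seed = as.integer(seed), replicates = as.integer(replicates),
        noiseSd = noiseSd, effect = effect,
        nPerClass = nPerClass, nPerGroup = nPerGroup,
        detectLog2 = detectLog2, ishFlipProb = ishFlipProb,
        domainFlipProb = domainFlipProb, signStrict = signStrict,
        literalOneWay52 = literalOneWay52, layout = match.arg(layout))
    class(cfg) <- "retscreenConfig"
    cfg
}

#' Write / read a pipeline configuration as YAML
#' @param config a \code{retscreenConfig}.
#' @param path YAML file path.
#' @return \code{writeConfig}: invisibly, the path. \code{readConfig}:
#'   the configuration.
#' @export
writeConfig <- function(config, path) {
    yaml::write_yaml(configAsList(config), path)
    invisible(path)
}

# Named vectors survive YAML only as maps, so expand them to lists.
configAsList <- function(config) {
    x <- unclass(config)
    x$nPerClass <- as.list(x$nPerClass)
    x$nPerGroup <- as.list(x$nPerGroup)
    x
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
    raw <- yaml::read_yaml(path)
    raw$nPerClass <- unlist(raw$nPerClass)
    raw$nPerGroup <- unlist(raw$nPerGroup)
    do.call(pipelineConfig, raw)
}

#' Run the full synthetic pipeline
#'
#' Executes simulate -> fit -> contrasts -> concordance -> clustering and
#' writes every artifact under \code{outDir}: expression + design TSVs,
#' per-gene fit table, comparison table with ISH scores (S1 shape),
#' identity matrix and concordance summary, domain matrix (S2 shape),
#' per-clade support TSV, Newick tree with AU|BP node labels, figures,
#' and a YAML run log with the seed and full configuration. Identical
#' configuration + seed gives byte-identical tables.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir output directory (created if missing).
#' @param stages which stages to run; later stages require the earlier
#'   ones in the same call.
#' @return invisibly, a list with the in-memory stage results and the
#'   paths written.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir,
        stages = c("simulate", "fit", "contrasts", "concord", "cluster")) {
    stopifnot(inherits(config, "retscreenConfig"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    pth <- function(f) file.path(outDir, f)
    res <- list(paths = character(0))
    need <- function(stage, dep) if (!dep %in% stages)
        stop("stage '", stage, "' requires stage '", dep,
            "' (missing artifact)")

    if ("simulate" %in% stages) {
        design <- generateDesign(config$replicates)
        truths <- rbind(
            makeGeneTruths(config$nPerClass, effect = config$effect,
                seed = config$seed),
            transformGroupIds(plantFunctionalGroups(config$nPerGroup,
                seed = config$seed + 1L)))
        expr <- simulateExpression(design, truths, config$noiseSd,
            seed = config$seed + 2L)
        writeExpression(expr, pth("expression.tsv"), pth("design.tsv"))
        writeTable(truths, pth("truths.tsv"))
        tpl <- defaultDomainTemplates()
        mat <- simulateDomainMatrix(tpl$templates, tpl$sizes,
            config$domainFlipProb, seed = config$seed + 4L)
        if (config$layout == "13") mat <- collapseLateral(mat)
        writeDomainMatrix(mat, pth("domain_matrix.tsv"))
        res$design <- design; res$truths <- truths; res$expr <- expr
        res$domainMatrix <- mat
        res$paths <- c(res$paths, pth(c("expression.tsv", "design.tsv",
            "truths.tsv", "domain_matrix.tsv")))
    }
    if ("fit" %in% stages) {
        need("fit", "simulate")
        fit <- classifyModels(fitSaturated(res$expr), alpha = config$fdr)
        tab <- data.frame(gene = rownames(coef(fit)), coef(fit),
            sigma2 = fit@sigma2, class = fit@modelClass,
            deciding = fit@decidingTerms, check.names = FALSE)
        writeTable(tab, pth("model_fits.tsv"))
        res$fit <- fit
        res$paths <- c(res$paths, pth("model_fits.tsv"))
    }
    if ("contrasts" %in% stages) {
        need("contrasts", "fit")
        con <- retinalContrasts(res$fit, allComparisons(),
            alpha = config$fdr, fcCutoff = config$fcCutoff,
            literalOneWay52 = config$literalOneWay52)
        groups <- classifyFunctionalGroup(con)
        ret <- con[con$comparison %in% retinalComparisons() &
            !is.na(con$estimate), ]
        scores <- simulateIshScores(ret, config$detectLog2,
            config$ishFlipProb, seed = config$seed + 3L)
        writeComparisonTable(ret, pth("comparisons.tsv"), scores)
        writeTable(groups, pth("functional_groups.tsv"))
        res$contrasts <- con; res$groups <- groups; res$scores <- scores
        res$paths <- c(res$paths, pth(c("comparisons.tsv",
            "functional_groups.tsv")))
    }
    if ("concord" %in% stages) {
        need("concord", "contrasts")
        ret <- res$contrasts[res$contrasts$comparison %in%
            retinalComparisons() & !is.na(res$contrasts$estimate), ]
        cs <- concordanceSummary(ret, res$scores, p0 = config$tdr,
            signStrict = config$signStrict)
        writeTable(cs$identity, pth("identity_matrix.tsv"))
        writeTable(data.frame(
            n_total = cs$overall$n, n_identical = cs$overall$k,
            overall_rate = cs$overall$rate,
            n_significant = cs$significant$n,
            n_identical_significant = cs$significant$k,
            significant_rate = cs$significant$rate,
            z = cs$ztest$z, z_p = cs$ztest$p, tdr = cs$ztest$p0),
            pth("concordance_summary.tsv"))
        grDevices::png(pth("concordance_panels.png"), 1200, 900, res = 120)
        plotConcordancePanels(cs$identity)
        grDevices::dev.off()
        res$concordance <- cs
        res$paths <- c(res$paths, pth(c("identity_matrix.tsv",
            "concordance_summary.tsv", "concordance_panels.png")))
    }
    if ("cluster" %in% stages) {
        need("cluster", "simulate")
        dc <- domainClustering(res$domainMatrix, scales = config$scales,
            nBoot = config$nBoot, seed = config$seed + 5L)
        writeTable(supportTable(dc), pth("clade_support.tsv"))
        writeSupportTree(dc, pth("dendrogram.nwk"))
        grDevices::png(pth("domain_heatmap.png"), 1200, 900, res = 120)
        plotDomainClustering(dc)
        grDevices::dev.off()
        res$clustering <- dc
        res$paths <- c(res$paths, pth(c("clade_support.tsv",
            "dendrogram.nwk", "domain_heatmap.png")))
    }
    log <- list(package = "retscreen",
        version = as.character(packageVersion("retscreen")),
        r_version = paste(R.version$major, R.version$minor, sep = "."),
        seed = config$seed, stages = stages, config = configAsList(config))
    yaml::write_yaml(log, pth("run_log.yaml"))
    res$paths <- c(res$paths, pth("run_log.yaml"))
    invisible(res)
}

# Give group-generator genes ids that do not collide with the class
# generator's.
transformGroupIds <- function(truths) {
    truths$gene <- sub("^gene", "grp", truths$gene)
    truths
}

# Collapse the two per-stage lateral blocks to the shared 13-column layout
# (a domain is present when present at either stage).
collapseLateral <- function(mat) {
    lat <- c("VP", "AV", "AD", "PD", "PV")
    out <- cbind(mat[, c("GC.BR_36v", "OR.b_36v", "OR.a_36v"), drop = FALSE],
        mat[, c("GCL_52v", "INL.b_52v", "INL.m_52v", "INL.a_52v",
            "ONL_52v"), drop = FALSE],
        (mat[, paste0(lat, "_36l"), drop = FALSE] |
         mat[, paste0(lat, "_52l"), drop = FALSE]) + 0)
    colnames(out) <- domainColumns("13")
    out
}

#' Three-panel concordance figure
#'
#' Log2 fold-change heatmap of the microarray comparisons, the qualitative
#' ISH score heatmap, and the Y/N identity matrix, drawn side by side.
#'
#' @param identity output of \code{\link{buildIdentityMatrix}}.
#' @export
plotConcordancePanels <- function(identity) {
    genes <- unique(identity$gene)
    cmps <- unique(identity$comparison)
    grab <- function(col) {
        m <- matrix(NA_real_, length(genes), length(cmps),
            dimnames = list(genes, cmps))
        m[cbind(match(identity$gene, genes),
            match(identity$comparison, cmps))] <- identity[[col]]
        m
    }
    est <- grab("estimate"); sco <- grab("score")
    idn <- grab("identical")
    op <- graphics::par(mfrow = c(1, 3), mar = c(6, 4, 3, 1))
    on.exit(graphics::par(op))
    rg <- max(abs(est), 1)
    pal <- grDevices::colorRampPalette(c("green3", "black", "red"))(255)
    panel <- function(m, zlim, col, main) {
        graphics::image(seq_along(cmps), seq_along(genes),
            t(m[rev(seq_along(genes)), , drop = FALSE]), zlim = zlim,
            col = col, axes = FALSE, xlab = "", ylab = "", main = main)
        graphics::axis(1, seq_along(cmps), cmps, las = 2, cex.axis = 0.8)
        graphics::axis(2, seq_along(genes), rev(genes), las = 2,
            cex.axis = 0.5)
    }
    panel(est, c(-rg, rg), pal, "log2 fold change")
    panel(sco, c(-1, 1), pal, "ISH score")
    panel(idn, c(0, 1), c("black", "white"), "identical (Y/N)")
}

#' Domain heatmap with support-flagged dendrogram
#'
#' Presence/absence heatmap in dendrogram leaf order with the UPGMA tree
#' on the left; internal nodes are marked red (p < 0.05) or green
#' (p < 0.1).
#'
#' @param dc a \linkS4class{DomainClustering}.
#' @export
plotDomainClustering <- function(dc) {
    hc <- dc@hclust
    mat <- dc@matrix[hc$order, , drop = FALSE]
    flags <- flagClades(dc)
    graphics::layout(matrix(1:2, 1), widths = c(1, 2.2))
    op <- graphics::par(mar = c(7, 1, 2, 0))
    on.exit({graphics::par(op); graphics::layout(1)})
    dend <- stats::as.dendrogram(hc)
    graphics::plot(dend, horiz = TRUE, leaflab = "none",
        main = "AU support")
    # mark flagged merges at their heights
    for (k in which(flags != "")) {
        memb <- cladeMembers(hc)[[k]]
        y <- mean(match(memb, hc$order))
        graphics::points(hc$height[k], y, pch = 19, cex = 1.2,
            col = ifelse(flags[k] == "red", "red", "green3"))
    }
    graphics::par(mar = c(7, 1, 2, 6))
    graphics::image(seq_len(ncol(mat)), seq_len(nrow(mat)), t(mat),
        col = c("black", "red"), axes = FALSE, xlab = "", ylab = "",
        main = "expression domains")
    graphics::axis(1, seq_len(ncol(mat)), colnames(mat), las = 2,
        cex.axis = 0.7)
    graphics::axis(4, seq_len(nrow(mat)), rownames(mat), las = 2,
        cex.axis = 0.7)
}
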