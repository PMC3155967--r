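# Independent brute-force oracles used to check the package's
# implementations. Deliberately naive and slow.

# Benjamini-Hochberg step-up, from the definition:
# q(i) = min_{j >= i} min(1, p_(j) * n / j), mapped back to input order.
bhOracle <- function(p) {
    n <- length(p)
    o <- order(p)
    ps <- p[o]
    q <- pmin(1, ps * n / seq_len(n))
    q <- rev(cummin(rev(q)))
    out <- numeric(n)
    out[o] <- q
    out
}

# Average-linkage agglomeration recomputed from first principles: the
# distance between two clusters is the mean of all cross-pair original
# distances. Returns member sets (sorted) and merge heights.
upgmaOracle <- function(D) {
    n <- nrow(D)
    clusters <- as.list(seq_len(n))
    sets <- list(); heights <- numeric(0)
    while (length(clusters) > 1L) {
        best <- Inf; bi <- bj <- NA
        for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
            if (j <= i) next
            d <- mean(D[clusters[[i]], clusters[[j]]])
            if (d < best) { best <- d; bi <- i; bj <- j }
        }
        merged <- sort(c(clusters[[bi]], clusters[[bj]]))
        sets[[length(sets) + 1L]] <- merged
        heights <- c(heights, best)
        clusters[[bi]] <- merged
        clusters[[bj]] <- NULL
    }
    list(sets = sets, heights = heights)
}

# Binary distance from its set definition: |A xor B| / |A union B|.
binaryDistanceOracle <- function(a, b) {
    A <- which(a == 1); B <- which(b == 1)
    length(union(setdiff(A, B), setdiff(B, A))) / length(union(A, B))
}

# Saturated-model coefficients as closed-form cell-mean combinations
# (indicator coding, reference WT / whole / 36 hpf). y is a named sample
# vector, design a FactorialDesign.
cellMeanOracle <- function(y, design) {
    s <- designTable(design)
    cm <- function(m, r, t) mean(y[s$sample[s$M == m & s$R == r & s$T == t]])
    m000 <- cm("WT", "whole", "36");  m100 <- cm("WT", "whole", "52")
    m010 <- cm("yng", "whole", "36"); m001 <- cm("WT", "retina", "36")
    m110 <- cm("yng", "whole", "52"); m101 <- cm("WT", "retina", "52")
    m011 <- cm("yng", "retina", "36"); m111 <- cm("yng", "retina", "52")
    c(mu = m000, T = m100 - m000, M = m010 - m000, R = m001 - m000,
      TM = m110 - m100 - m010 + m000, TR = m101 - m100 - m001 + m000,
      MR = m011 - m010 - m001 + m000,
      TMR = m111 - m110 - m101 - m011 + m100 + m010 + m001 - m000)
}

# Cell mean of a condition label (e.g. "YR52") from a sample vector.
cellMean <- function(y, design, label) {
    s <- designTable(design)
    mean(y[s$sample[startsWith(s$sample, paste0(label, "_"))]])
}

# Clade member sets of an hclust tree as sorted label vectors.
cladeLabelSets <- function(hc, labels) {
    lapply(cladeMembers(hc), function(i) sort(labels[i]))
}

# Build a synthetic 29 x 4 call/score table reproducing the published
# concordance counts: 31 significant cells within the two mutation
# contrasts with exactly 3 disagreements, and 19 disagreements overall.
concordanceFixture <- function() {
    genes <- sprintf("g%02d", 1:29)
    cmps <- retinalComparisons()
    grid <- expand.grid(gene = genes, comparison = cmps,
        stringsAsFactors = FALSE)
    grid$significant <- FALSE
    grid$estimate <- 0.2          # sub-threshold change
    grid$score <- 0L
    mut <- grid$comparison %in% c("YR36/WR36", "YR52/WR52")
    # 31 significant mutation-contrast cells: 15 genes in both columns,
    # gene 16 in the first column only
    sig <- mut & (grid$gene %in% genes[1:15] |
        (grid$gene == genes[16] & grid$comparison == "YR36/WR36"))
    grid$significant <- sig
    grid$estimate[sig] <- 2
    grid$score[sig] <- 1L
    # 3 disagreements among the significant cells (ISH saw no change)
    bad <- which(sig)[1:3]
    grid$score[bad] <- 0L
    # 16 further disagreements among the remaining 85 cells
    ns <- which(!sig)
    grid$score[ns[1:16]] <- 1L
    grid
}
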