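# retscreen

Factorial ANOVA screening and in situ validation of retinal gene
expression.

## The problem

In the zebrafish *smarca4* (*brg1*) null mutant *yng*, retinal cells are
specified but fail terminal differentiation. A 2×2×2 factorial
expression experiment — mutation (M: WT vs *yng*) × tissue (R: whole
embryo vs micro-dissected retina) × stage (T: 36 vs 52 hpf) — can
isolate mutation-specific *retinal* expression changes from global or
stage effects. `retscreen` implements the full computational chain for
this design, for anyone screening factorial expression data and
validating the calls against qualitative spatial expression
(whole-mount in situ hybridization, ISH):

1. **Per-gene factorial models.** Each gene's log2 expression is fitted
   saturated, `y = μ + T + M + R + T·M + T·R + M·R + T·M·R + ε`, with
   0/1 indicator coding (reference WT / whole embryo / 36 hpf), and
   assigned to the most parsimonious class — *three-way* (significant
   `T·M·R`, the most retina-specific mutation response), *two-way*,
   *one-way* or *insignificant* — by a top-down BH-FDR hierarchy.
2. **Contrast inference.** Printed condition comparisons as coefficient
   contrasts (e.g. YR52/WR52 under the three-way model tests
   `H0: M + M·R + T·M + T·M·R = 0`), with the two significance
   criteria: BH-adjusted q < 0.05 **and** signed fold change
   |FC| ≥ 2 (FC = 2^d for log2 estimate d ≥ 0, −2^(−d) otherwise).
   Genes are sorted into functional groups: (i) mutation-regulated
   retinal, (ii) retina-specific mutation-independent, (iii)
   mutation-regulated outside the retina.
3. **ISH concordance.** Qualitative scores {−1, 0, +1} are compared
   with the microarray calls cell by cell (the "identity matrix");
   overall and significant-only concordance rates are tested against a
   theoretical true discovery rate with a one-sample proportion z test.
4. **Domain clustering.** Binary gene × retinal-domain matrices are
   clustered with binary (asymmetric Jaccard) distance and UPGMA, and
   every clade gets multiscale-bootstrap support: BP and the
   approximately unbiased AU value from the probit-linear fit
   `Φ⁻¹(1−BP_r) = v√r + c/√r`, with clade p-value 1 − AU (red: p <
   0.05, green: p < 0.1).

A synthetic-data module generates every input with the statistical
structure the analysis assumes, so the whole chain is testable without
any external download.

## Worked example

```r
library(retscreen)
design <- generateDesign(replicates = 3)
truths <- plantFunctionalGroups(c(i = 6, ii = 3, iii = 3, none = 3), seed = 11)
expr   <- simulateExpression(design, truths, noiseSd = 0.25, seed = 11)
fit    <- classifyModels(fitSaturated(expr), alpha = 0.05)
fit
#> FactorialFit: 15 genes, residual df 16
#> model classes:
#> insignificant       one-way     three-way       two-way
#>             3             4             2             6

groups <- classifyFunctionalGroup(retinalContrasts(fit, allComparisons()))
table(planted = truths$group, called = groups$group)
#>        called
#> planted i ii iii none
#>    i    6  0   0    0
#>    ii   0  3   0    0
#>    iii  0  0   3    0
#>    none 0  0   0    3
```

All 15 planted genes land in their true functional group: the six
group-(i) genes pass the q < 0.05 and two-fold criteria on a retinal
mutation contrast, the three retina-specific genes pass the
retina/whole contrast at both stages, and so on.

```r
tpl <- defaultDomainTemplates()
mat <- simulateDomainMatrix(tpl$templates, tpl$sizes, flipProb = 0.05, seed = 11)
dc  <- domainClustering(mat, nBoot = 10000, seed = 11)
dc
#> DomainClustering: 25 genes x 18 domains; average linkage on binary distance
#> multiscale bootstrap: 10000 replicates x 10 scales (seed 11)
#> 17 clades with p < 0.05, 2 with 0.05 <= p < 0.1

round(cladeAU(dc, split(rownames(mat), attr(mat, "template"))), 3)
#> [1] 0.980 0.988 0.993
```

The three planted expression-pattern groups (8, 5 and 12 genes) are
recovered as clades with AU support 0.98–0.99, i.e. clade p-values well
below 0.05.

```r
tdrZTest(28, 31, 0.95)[c("z", "p")]
#> $z
#> [1] -1.194924
#> $p
#> [1] 0.2321167
```

A significant-only concordance of 28/31 (90.3%) is statistically
compatible with a theoretical true discovery rate of 95%.

`runPipeline(pipelineConfig(...), outDir)` chains all stages and writes
every table (TSV), the support-annotated dendrogram (Newick, node
labels `AU|BP`), figures and a YAML run log; identical configuration
and seed give byte-identical tables.

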