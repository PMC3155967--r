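---
title: "Factorial screening of retinal genes: models, concordance and clustering"
author: "retscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Factorial screening of retinal genes: models, concordance and clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retscreen)
```

# The problem

In the *smarca4* (*brg1*) null mutant *yng*, all zebrafish retinal cell
types are specified but fail terminal differentiation. A 2×2×2 factorial
expression experiment — mutation (M: wild type vs mutant), tissue (R:
whole embryo vs micro-dissected retina), developmental stage (T: 36 vs
52 hours post-fertilization) — lets one separate mutation-specific
*retinal* expression changes from everything else. `retscreen`
implements the downstream computational chain: per-gene factorial ANOVA
with parsimonious model selection, contrast inference with FDR and
fold-change filters, concordance of significance calls with qualitative
in situ hybridization (ISH) scores, and clustering of binary
expression-domain profiles with multiscale-bootstrap clade support.

# The per-gene model

Expression of a gene $g$ on the log2 scale is modelled saturated:

$$
y_g = \mu + T + M + R + T{\cdot}M + T{\cdot}R + M{\cdot}R
      + T{\cdot}M{\cdot}R + \varepsilon,\qquad
\varepsilon \sim N(0, \sigma^2),
$$

with 0/1 indicator (treatment) coding and reference levels wild type,
whole embryo, 36 hpf. This coding is used because every coefficient is
then directly a cell-mean contrast: the mutant-vs-wild-type retinal
difference at 36 hpf is $M + M{\cdot}R$, and at 52 hpf
$M + M{\cdot}R + T{\cdot}M + T{\cdot}M{\cdot}R$. `fitSaturated()`
estimates all eight coefficients by OLS, vectorised across genes;
with a balanced design the estimates equal closed-form cell-mean
combinations, which the test suite verifies to $10^{-10}$ against an
independent oracle.

## Parsimonious model classes

Each gene is assigned to one of four nested classes: *three-way* (the
$T{\cdot}M{\cdot}R$ term is active — the most retina-specific mutation
response), *two-way*, *one-way*, or *insignificant*. The verbal
definition does not prescribe a selection algorithm, so
`classifyModels()` uses a top-down significance hierarchy on the
saturated fit: three-way if $T{\cdot}M{\cdot}R$ is significant,
otherwise two-way if any two-way interaction is, otherwise one-way if
any main effect is, otherwise insignificant. This keeps classes
exclusive and exhaustive, avoids enumerating $2^3$ submodels, and the
per-term t tests from the saturated fit are equivalent to type-III F
tests under balance.

Significance is Benjamini–Hochberg FDR at level $\alpha = 0.05$,
applied across genes separately within each term *family* (the
three-way term; the three two-way terms pooled; the three main effects
pooled). Pooling within a family rather than per individual term keeps
a single significance threshold per hierarchy level; a `scope =
"global"` option pools all seven effect terms instead, since the
original study's choice is not recorded.

## Contrasts, fold changes and the two criteria

`contrastWeights()` returns the class-specific weight vector of each
printed comparison. One printed null deserves a note: for the one-way
class at YR52/WR52 the source prints $M + T = 0$, but under indicator
coding the YR52 − WR52 cell-mean difference in a main-effects-only
model is $M$ alone ($T$ cancels as both samples are at 52 hpf). The
package defaults to the model-implied weight $\{M\}$ and offers
`literalOneWay52 = TRUE` to reproduce the printed literal; neither
behaviour is guessed silently.

A comparison is *significant* when both criteria hold: BH-adjusted
$q < 0.05$ (adjusted across genes within the comparison) and signed
linear fold change $|FC| \ge 2$, where $FC = 2^d$ for a log2 estimate
$d \ge 0$ and $-2^{-d}$ otherwise, so $|FC| \ge 2 \iff |d| \ge 1$.

Functional groups are assigned in precedence order: **(i)**
mutation-regulated retinal genes — either retinal mutation contrast
significant; **(ii)** retina-specific, mutation-independent — the
retina/whole contrast ($R$ at 36 hpf, $R + T{\cdot}R$ at 52 hpf,
evaluated in wild type) significant at *both* stages, as the group is
defined by retina-specific expression at both time points; **(iii)**
mutation-regulated outside the retina — the whole-embryo mutation
contrast ($M$ at 36 hpf, $M + T{\cdot}M$ at 52 hpf) significant at
either stage. Group (iii) is never operationalised in the source; the
whole-embryo contrast with the same q/FC thresholds is this package's
design choice for it.

# Microarray/ISH concordance

ISH comparisons are scored qualitatively: $+1$ (over-expression), $0$
(no visible change), $-1$ (under-expression). A microarray call and an
ISH score are *identical* when the call is significant and the score
matches the sign of its estimate, or the call is insignificant and the
score is 0. "Corresponding differential expression" is read as
sign-matching rather than merely nonzero, because the colour semantics
of the validation pair over- with over-expression; `signStrict = FALSE`
relaxes this. The overall concordance rate uses all gene × comparison
cells; the significant-only rate restricts to significant cells in the
two mutation-contrast columns, the comparisons the gene selection was
based on.

The z test against the theoretical true discovery rate $p_0 = 0.95$ is
the standard one-sample proportion test with null variance,
$z = (\hat p - p_0)/\sqrt{p_0(1-p_0)/n}$, two-sided. For $\hat p =
28/31$ this gives $z \approx -1.195$, $p \approx 0.232$. The published
p-value of 0.83 for the same counts is not reproducible by any standard
one-sample proportion formula we tried; the package reports its own
value and documents the formula rather than reverse-engineering the
variant.

# Domain clustering with AU support

Cellular expression is scored present/absent in 18 retinal domains:
36 hpf ventral view (GC/BR, OR-b, OR-a), 52 hpf ventral view (GCL,
INL-b, INL-m, INL-a, ONL) and the five lateral-view domains (VP, AV,
AD, PD, PV) scored per stage. Scoring the lateral domains separately at
36 and 52 hpf preserves the stage information that distinguishes
"expressed at both stages" from "expressed at 52 hpf only" patterns; a
13-column variant with shared lateral domains is available via the
configuration.

Dissimilarity is the binary (asymmetric Jaccard) distance — discordant
domains over the union of scored domains; joint absences are
uninformative. All-zero rows are undefined under this distance and are
excluded from clustering (in the motivating data two genes were dropped
for analogous reasons). Trees are built by unweighted average-linkage
(UPGMA) agglomeration via `stats::hclust`; the bootstrap reclustering
loop uses a C++ UPGMA with lowest-index-pair tie-breaking, fixed so
resampled trees are reproducible, and cross-checked against `hclust` on
tie-free instances.

## Multiscale bootstrap

Clade support uses multiscale bootstrap resampling with 10000
replications per scale over the grid $r \in \{0.5, 0.6, \dots, 1.4\}$
(the conventional ten-scale default; per-scale replication follows the
cited methodology's convention). The resampling unit is the *columns*
(domains): genes are the clustered objects and domains their features.
For each scale, columns are drawn with replacement at size
$\mathrm{round}(r \times 18)$, the resample is reclustered, and each
original clade's exact member set is counted.

Per-scale bootstrap probabilities $BP_r$ are clipped to
$[1/(2n_b),\, 1 - 1/(2n_b)]$ to keep probits finite, then

$$
\Phi^{-1}(1 - BP_r) = v\sqrt{r} + c/\sqrt{r}
$$

is fitted by weighted least squares with binomial weights
($n_b\,\phi(z_r)^2 / (BP_r(1-BP_r))$), giving the signed distance $v$
and curvature $c$; the approximately unbiased value is
$AU = 1 - \Phi(v - c)$ and the clade p-value $1 - AU$. Clades with
counts at 0 or $n_b$ at *every* scale carry no curve information: AU
saturates to the clipped extreme and the entry is flagged degenerate.
Clades are flagged red when $p < 0.05$ and green when
$0.05 \le p < 0.1$, matching the dendrogram colouring convention of the
motivating study. With only 18 features, AU estimates are intrinsically
noisy; this is reported, not corrected.

# The synthetic-data generator

The generators produce every input the pipeline consumes, with the
statistical structure the analysis assumes:

* **Design**: the replicate count is not recorded in the motivating
  study (its array structure lives in an earlier publication); the
  default is 3 per cell — the smallest count giving a comfortably
  estimable residual variance — and is configurable.
* **Expression**: cell means from the indicator-coded truth
  coefficients plus i.i.d. Gaussian log2 noise, default sd 0.25, a
  typical replicate sd for log2 array intensities. Planted effects
  default to 1 log2 unit (4 × noise sd). The generator emulates only
  this cell-mean-plus-noise structure — not probe-level data,
  normalization artefacts, intensity-dependent variance or correlated
  probes — so passing tests demonstrate correctness of the inference
  chain, not robustness to raw-array pathologies.
* **ISH scores**: sign of the contrast estimate thresholded at 1 log2
  unit (mirroring the two-fold criterion), then corrupted to a
  uniformly chosen different score with a configurable flip
  probability. Real ISH scoring noise is not independent across
  comparisons of one gene; the generator's independence assumption is a
  simplification.
* **Domain matrices**: three templates emulating the three broad
  expression groups (photoreceptor/ONL at 52 hpf; GCL/INL at both
  stages; GCL/INL at 52 hpf only) with 8/5/12 genes and independent 5%
  bit flips; all-zero rows are redrawn.

# Numerical choices and degenerate inputs

* Genes fitted with numerically zero residual variance (noise-free
  fixtures) get exact per-term p-values: 1 for a zero coefficient, 0
  (flagged degenerate by construction) for a nonzero one; the same rule
  applies to contrasts.
* The bootstrap RNG is a self-contained splitmix64 stream seeded from
  the user seed, so resampling is bit-reproducible across platforms and
  independent of R's RNG state. Column indices are drawn by modulo;
  with 18–25 columns the modulo bias is below $10^{-17}$ and ignored.
* Two rows that are both empty *on a resample* (possible after column
  resampling even though full rows never are) are given distance 0.
* UPGMA ties in the C++ loop break to the lowest-index pair;
  `stats::hclust` applies its own fixed rule. Binary distances are
  small-denominator rationals, so ties do occur in resamples; they
  affect only which of several equally supported topologies is counted,
  not the determinism of the result.

# Problem sizes and known limitations

The packaged property suite runs the chain at 500 genes per model class
(2000 genes), 500 genes with planted functional-group structure, and
ten independent 25 × 18 domain matrices with 10000 bootstrap
replications per scale — sizes chosen so the whole suite completes in
about a minute and a half on one CPU while keeping Monte-Carlo error
small relative to the asserted margins.

One power limitation deserves emphasis. Under indicator coding the
saturated-fit three-way coefficient is a combination of all eight cell
means, with standard error $\sigma\sqrt{8/\text{replicates}} \approx
1.63\,\sigma$ at 3 replicates. A planted three-way effect of
4 × noise sd therefore yields a noncentral t of only
$4/1.63 \approx 2.45$ at 16 degrees of freedom — about 0.6 power at raw
$\alpha = 0.05$, and far less after FDR adjustment across genes.
Three-way genes at that effect size are consequently under-recovered
(overall class accuracy is about 0.69 in the packaged simulation, with
main effects recovering well and the three-way term poorly), and
reliable three-way recovery needs effects of roughly 8 × noise sd or
more replicates. This is an intrinsic property of the design, not of
the implementation; the acceptance suite reports the measured accuracy
honestly.
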