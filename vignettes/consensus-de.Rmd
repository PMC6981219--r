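---
title: "Consensus differential expression across a normalization-by-model grid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus differential expression across a normalization-by-model grid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consensusde)
```

## The procedure

Normalization choice and test choice each move the boundary of a
differential-expression (DE) call list, and on small bulk RNA-seq designs
(here: two groups, around six animals each, e.g. cocaine versus saline
brain tissue at an abstinence timepoint) they move it a lot. Rather than
committing to one pair, `consensusde` runs a whole grid:

* **eight normalizations** — TMM, TMM-CPM, RPKM, upper-quartile,
  full-quantile, median of nonzero counts, PoissonSeq-style iterative
  depths, and RUV-style hidden-factor removal — with
  `register_normalization()` accepting a ninth, user-supplied method for
  a 9 × 5 = 45-cell grid;
* **five DE models** — a negative-binomial Wald test, a robust
  negative-binomial likelihood-ratio test, the voom moderated t, the
  Mann-Whitney rank-sum test and a Welch t on log values.

Each `(normalization, model)` cell yields per-gene p-values that are
Benjamini-Hochberg adjusted *within that cell*, over all genes. For every
model the q-values are then averaged across the normalizations:

$$\bar q_{g,m} = \frac{1}{|N|}\sum_{n \in N} q_{g,n,m}.$$

A gene is a *target* of model $m$ when $\bar q_{g,m} < 0.25$ (strict
inequality), and a consensus DEG when it is a target of all five models
(`k_required` is configurable). The intersection trades power for
precision: a gene must survive every model family's assumptions, under
every normalization, at a permissive per-model level. The package's
replicated simulations verify the intended effect — the consensus call
set's empirical false discovery rate is consistently far below that of
the union of the single-model target sets.

The aggregation sentence this rule implements is ambiguous in isolation
("mean q smaller than 0.25 ... detected by the combination of five
different methods"). We read *mean* as the mean across normalizations
within a model and *five methods* as the five DE models — the only
reading under which "detected by five methods" is well-typed on a
normalizations × models grid. Both the threshold and `k_required` are
arguments, so the alternative reading is one `call_consensus()` call
away.

Direction is reported as the sign of the median log2 fold change across
all grid cells (a zero median is labeled *ambiguous*); the familiar
volcano classification (`classify_volcano()`, default q < 0.01) and DEG
set comparison between analyses (`compare_deg_sets()`) operate downstream
of the grid.

## Normalizations: factors, depths, offsets

Factor-type methods (TMM, UQ, Median, PoissonSeq) return one positive
scale factor per sample, rescaled to geometric mean 1. These factors are
*relative effective-depth estimates*: doubling one sample's counts
doubles its factor (exactly for UQ/median/PoissonSeq; to within the
variance-weight approximation for TMM, whose weights depend on the
library size being rescaled). The effective depth of sample $j$ is
`factor_j` × geometric-mean library size, which keeps depths on the
library-size scale without double-counting depth; count models receive
`log(effective_depth)` as an offset, and rank/t tests receive counts
divided by the factors.

TMM follows the standard recipe: reference sample with 75th
count-fraction percentile closest to the mean; pairwise log2 ratios of
depth-scaled counts doubly trimmed (30% on M, 5% on A); inverse
asymptotic-variance weights; all-genes-trimmed falls back to factor 1
with a warning. The implementation is cross-checked in the test suite
against both an independent transcription of the formula and edgeR's
effective library sizes.

Matrix-type methods return a transformed matrix: TMM-CPM (counts per
million on TMM effective depths), RPKM (per kilobase of *merged-isoform*
exon model — see below — per million library reads), full-quantile, and
RUV. Rank and t tests use the matrix directly. Count models need
integers, so the matrix is rounded, the cell is flagged
`rounded_matrix`, and the flag is persisted into the run summary — a
documented approximation that keeps all 40 cells defined.

Two conventions worth calling out:

* **Full-quantile ties.** Count matrices tie heavily (zeros above all).
  Tied values are mapped to the common reference distribution in stable
  input order rather than averaged: averaging tied positions would break
  the two definitional properties of the transform (every column shares
  one sorted value multiset; applying the transform twice changes
  nothing), both of which the test suite asserts to 1e-12.
* **Median** means the median of a sample's nonzero counts; DESeq-style
  median-of-ratios is a different estimator and is not in the grid.

RUV estimates `k` unwanted factors (default 1) by SVD of the
condition-centred log(count + 0.5) rows of control genes — by default
the "empirical controls", the half of genes least associated with the
condition in a first-pass Welch test — then regresses all genes on the
factors and subtracts the fitted component. Note that with unequal
library sizes the first estimated factor legitimately absorbs depth, so
RUV acts as a normalization here, not only as a batch correction.
Removing one factor from the $2(n-1)$ residual dimensions of an
$n$-per-group design necessarily absorbs a few percent of per-gene noise
even on clean data; the tests assert a median per-gene log-scale
correlation above 0.95 on clean equal-depth data, which is the floor
this dimension argument predicts.

## Gene lengths

RPKM needs one length per gene. Genes with multiple isoforms are
*collapsed*: all exons of all isoforms are merged (interval union,
strand ignored) and the covered width is the length. This is checked
against a per-base coverage bitmap on random gene models. The phrase
"longest collapsed isoform" could alternatively mean the single longest
isoform after deduplication; the union reading matches the collapse
convention of the tooling this label usually refers to, and is the one
implemented.

## The five models

**NB Wald.** Group-specific NB means fitted by Newton iteration on the
log mean at fixed gene-wise dispersion, depth offsets included; under
equal offsets the fitted means are exactly the group sample means, so
the reported `log2_fc` is the unshrunken log2 ratio of group means. The
statistic is lfc over its Fisher-information standard error, two-sided
normal p.

**Robust NB LRT.** Same mean model; the statistic is
$2(\ell_{\text{full}} - \ell_{\text{null}})$ against $\chi^2_1$, with
per-observation weights fixed from the unweighted full fit: any
observation with Pearson residual $|r| > 2.5$ is down-weighted to
$2.5/|r|$, protecting null genes with a single aberrant animal.

**Dispersion** (shared by both NB models, one fit per normalization) is
parameterised by NB variance $\mu + \phi\mu^2$ and estimated in three
stages: method-of-moments within groups on depth-adjusted counts
(clipped at zero); a robust least-squares fit of the decreasing trend
$\phi(\mu) = a/\mu + b$ over genes with positive raw estimates; and a
weight-0.5 geometric-mean shrinkage of raw toward trend, which keeps the
final value between the two (genes with undefined raw take the trend).
One numerical choice matters at $n = 6$ per group: the moment
estimator's sampling distribution is approximately $\chi^2_{df}/df$
with $df = n_{\text{samples}} - 2$, so both the robust trend (a median)
and the geometric average (a log-mean) sit systematically below the
true dispersion. The raw estimates are therefore multiplied by the
consistency factor $\exp(-(\psi(df/2) - \log(df/2)))$ before the trend
fit and shrinkage. Without it the final dispersions run ~8% low and the
NB tests are visibly anti-conservative; with it, a plug-in fit matches
the calibration of an oracle run with the true dispersions.

**Voom moderated t** delegates to `limma::voom()`, `lmFit()` and
`eBayes()` on `log2((count + 0.5)/(depth + 1) * 1e6)` with the
normalization's effective depths as library sizes. Genes with zero
effect *and* numerically zero residuals (e.g. exactly identical groups)
are a 0/0 of rounding errors in which the mean-variance trend has
nothing to fit and the precision weights diverge; they are reported as
statistic 0, p = 1. Below 10 genes the trend is meaningless and the
function falls back to an unweighted Welch t with a warning.

**Mann-Whitney** uses the exact enumeration p-value for tie-free genes
when $n_1 + n_2 \le 10$ and the tie- and continuity-corrected normal
approximation otherwise (`stats::wilcox.test`); constant genes get
p = 1. Its reported fold change, `log2((mean_t + 0.5)/(mean_c + 0.5))`,
is display-only.

**Welch t** runs vectorised on `log2(x + 0.5)` values (the pseudo-count
0.5 is the package-wide continuity correction) with Satterthwaite
degrees of freedom, and is checked per-gene against `stats::t.test`.
Zero-variance genes get p = 1 when the group means agree and a flagged
p = 0 otherwise.

All tests are two-sided. Genes with zero counts in every sample are
never dropped: they carry lfc 0, p = q = 1 and the flag `all_zero`, so
every grid cell shares one gene universe and the consensus intersection
is well defined. No expression pre-filter is applied, which inflates
the tested-gene count (and deflates per-cell power slightly) relative
to pipelines that filter.

## The synthetic generator

`simulate_dataset()` draws
$\text{counts}_{gj} \sim \text{NB}\!\left(\mu_g \, 2^{x_j \lambda_g} d_j e^{u_{gj}},\ \phi_g\right)$
with $x_j$ the 0/1 condition indicator. Defaults describe the study
conditions the pipeline is meant for, chosen once:

| parameter | default | rationale |
|---|---|---|
| `n_per_group` | 6 | animals per arm of a mouse cohort |
| `n_genes` | 15000 | transcriptome scale after detection |
| baseline $\mu_g$ | log-normal(4, 1.5) | median ≈ 55 counts, heavy right tail |
| $\phi(\mu) = a/\mu + b$ | a = 2, b = 0.05 | decreasing trend; asymptotic BCV ≈ 0.22, typical for inbred-animal bulk tissue |
| dispersion jitter | log-normal sd 0.2 | gene-to-gene scatter around the trend |
| `frac_de` | 0.10 | planted fraction; 0 and 0.05 are the other study settings |
| planted lfc | sign ± , magnitude ≥ 0.5 (centre 1.5, sd 0.4) | bounded away from 0 so "DE" and power are well defined |
| depth factors | log-normal sd 0.3 | 2-fold library-size spread |
| hidden factors | 0 (configurable) | switch on to exercise RUV |

One integer seed drives everything; `simulate_null()` refuses any
configuration with planted effects, and `evaluate_calls()` /
`recovery_report()` score any call set against the planted truth
(`empirical_fdr = FP/max(1, FP+TP)`, so an empty call set scores 0).

What the generator does **not** emulate: isoform structure and
length-coupled counting biases (gene lengths are drawn independently of
expression, so RPKM's length correction is exercised but not stressed),
GC/composition biases, correlated gene modules, sample outliers beyond
NB tails, and any read-level artefact. Passing tests therefore show the
machinery is correct and calibrated under the model class it assumes,
not that any particular normalization wins on real tissue.

## Calibration checks and their definitions

Type-I error is checked on null simulations at the study's group size
(2000 genes, n = 6/group): each model's rejection rate at
$\alpha = 0.05$ must fall in the exact central 99% binomial interval.
The p-value distribution check is one-sided by design: the Mann-Whitney
support at n = 6/group has ~37 atoms, so any correct rank test is far
from Uniform(0,1) in two-sided Kolmogorov-Smirnov distance. What FDR
control actually requires is super-uniformity, so the suite asserts
that the empirical cdf of null p-values never exceeds the uniform cdf
by more than the one-sided KS critical value at the 1% level, in at
least 19 of 20 seeded replicates per model.

Problem sizes used by the automated checks (chosen to keep a default
run in minutes): oracle-equivalence blocks at 50 × 6; calibration at
2000 genes plus 20 × 1200-gene replicates; effect-size recovery at 5000
genes; power-ordering at 2500 genes on a 4 × 5 grid; consensus-vs-union
precision aggregated over 20 replicates of 500 genes on a 3 × 5 grid;
byte-level determinism on a full 8 × 5 grid at 150 genes.
`scripts/acceptance.R` recomputes the same quantities from scratch at a
caller-supplied seed.

## Known limitations

* PORT-style read-level normalization cannot be computed from a count
  matrix and is not in the grid; the 45-cell layout is available through
  `register_normalization()`.
* Two-group designs only: no covariates, pairing, or multi-factor
  contrasts.
* Matrix-kind normalizations reach the count models through rounding —
  flagged, but still an approximation of a proper offset formulation.
* The NB Wald test retains a mild residual liberality (~0.055 at
  nominal 0.05) inherent to plug-in dispersion at n = 6; the consensus
  rule's intersection blunts its effect on final calls.
* DEG counts on real archived datasets depend on alignment, annotation
  version and filtering upstream of the count matrix; this package
  starts at the count matrix.
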