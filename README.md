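# consensusde

Consensus calling of differentially expressed genes (DEGs) from two-group
bulk RNA-seq counts — for analysts who do not want a single
normalization × test choice to decide their gene list.

On small designs (two conditions, ~6 replicates each — e.g. drug versus
vehicle brain tissue at one timepoint) the DE call set moves substantially
with both the normalization and the test. `consensusde` runs the whole
grid instead:

* **8 normalizations**: TMM, TMM-CPM, RPKM, upper-quartile,
  full-quantile, median of nonzero counts, PoissonSeq-style iterative
  depth estimation, RUV-style hidden-factor removal (a 9th user-supplied
  method can be registered for a 45-cell grid);
* **5 DE models**: negative-binomial Wald, robust negative-binomial
  likelihood-ratio, voom moderated t, Mann-Whitney, Welch t.

Each of the 40 cells gets Benjamini-Hochberg q-values over all genes.
For gene *g* and model *m* the q-values are averaged over the
normalizations,

    mean_q[g, m] = mean over normalizations n of q[g, n, m],

gene *g* is a *target* of model *m* when `mean_q[g, m] < 0.25`, and a
**consensus DEG** when it is a target of all five models. The
intersection trades some power for a much lower false discovery rate
than any single cell or their union.

The package also ships a seeded negative-binomial count simulator
(planted fold changes, mean-dispersion trend, library-size spread,
optional hidden factors) plus truth-aware evaluation — so calibration
(type-I error), FDR, power and effect recovery of every stage are
testable without any external download.

## Worked example

```r
library(consensusde)

cfg  <- sim_config(n_genes = 2000, n_per_group = 6, frac_de = 0.1, seed = 42)
sim  <- simulate_dataset(cfg)
grid <- run_grid(sim$counts, sim$design)     # 8 normalizations x 5 models
calls <- call_consensus(grid, threshold = 0.25)
calls
#> <consensus_calls> 158 DEGs of 2000 genes (mean q < 0.25 in >= 5 of 5 models)
glance(calls)
#> # A tibble: 1 × 7
#>   n_genes n_deg  n_up n_down n_ambiguous threshold k_required
#>     <int> <int> <int>  <int>       <int>     <dbl>      <int>
#> 1    2000   158    86     72           0      0.25          5
```

2000 genes were simulated with 200 planted effects (|log2 fold change|
≥ 0.5); the consensus rule calls 158 genes, split into 86 up- and 72
down-regulated. Because the truth is known, the call set can be scored:

```r
recovery_report(grid, sim$truth)
#> # A tibble: 6 × 7
#>   set            lfc_bias lfc_rmse n_lfc_genes n_called empirical_fdr power
#>   <chr>             <dbl>    <dbl>       <int>    <int>         <dbl> <dbl>
#> 1 nb_wald       -0.00515     0.287         148      239        0.276  0.865
#> 2 nb_lrt_robust -0.00515     0.287         148      240        0.279  0.865
#> 3 voom          -0.0463      0.293         148      207        0.222  0.805
#> 4 mann_whitney  -0.000363    0.284         148      171        0.146  0.73
#> 5 welch_t       -0.00202     0.289         148      191        0.199  0.765
#> 6 consensus     -0.0135      0.286         148      158        0.0759 0.73
```

Each single model's permissive target set (mean q < 0.25) carries a
15–28% empirical FDR here; the five-model consensus drops it to 7.6%
while keeping 73% power, and the fold-change estimates on well-expressed
planted genes are essentially unbiased (|bias| ≤ 0.05 log2 units).

Downstream helpers mirror the usual reporting: `classify_volcano()`
labels one cell's genes up/down/ns at q < 0.01 for a volcano plot
(`plot_volcano()`, `autoplot()`), and `compare_deg_sets()` summarises
the overlap between two DEG lists (e.g. two abstinence timepoints).
`run_pipeline()` wraps read → normalize → test → aggregate → call →
report into one call that writes per-cell DE tables, the consensus
table, volcano tables and a JSON run summary; a thin command-line
wrapper lives in `inst/cli/consensusde.R`.

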