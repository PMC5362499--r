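# lncsubpath

Identify, inside KEGG-style pathway graphs, connected **subpathway
regions** whose protein-coding genes (PCGs), gene–gene interactions, and
associated risk **lncRNAs** are jointly dysregulated between two sample
groups — and name the key lncRNAs driving each region.

The package is for transcriptomics analysts with matched lncRNA/mRNA
expression (e.g. tumour vs normal FPKM) who want pathway interpretation of
a risk-lncRNA set at sub-pathway resolution, plus a fully synthetic
benchmark engine so every stage can be exercised without external data.

## The method in brief

For each pathway gene $v$ with associated risk lncRNAs $L_1,\dots,L_m$:

$$w_v = \alpha\,|\log_2 FC_v| + (1-\alpha)\sum_{j=1}^m d_{vL_j}\,
|\log_2 FC_{L_j}|, \qquad d_{vL_j} = 1 + |r^{case}_{vL_j} - r^{ctl}_{vL_j}|$$

normalized within the pathway to prizes $b_v = \beta (w_v -
w_{\min})/w_{\max}$ ($\alpha = 0.5$, $\beta = 15$). Edges cost
$c_e \propto w_e = 1 - |r^{case}_e - r^{ctl}_e|$, so *stable* interactions
are expensive and rewired ones cheap. The dysregulated region is the
connected subgraph minimizing $\sum_{e} c_e - \sum_{v} b_v$
(prize-collecting Steiner tree, `pcst_solve()`, validated against an
exhaustive oracle). Node- and edge-level permutation tests against
background pools give $p_v$ and $p_e$; regions are ranked by the joint
$p = p_v\,p_e$ with BH adjustment, and a greedy coverage rule selects the
key lncRNAs (importance $IS = \gamma\,|\log_2 FC_L| +
(1-\gamma)\sum_j d_{LG_j} D_{G_j}$, $\gamma = 0.3$, coverage target 0.8).

See the methods vignette (`vignettes/lncsubpath-methods.Rmd`) for the full
model, parameter table and design discussion.

## Worked example

Simulate a dataset with planted dysregulation (node fold change 4, edge
correlation change 0.5, half the linear pathway altered) and run the full
identification:

```r
library(lncsubpath)

scenario <- simulation_scenario(topology = "linear", n = 4, e = 0.5,
                                p = 0.5, N = 250)
ds  <- simulate_dataset(scenario, seed = 11, quiet = TRUE)
res <- lnc_subpathway(ds$pair, unname(fixture_pathways()), ds$network,
                      permutations = 1000, seed = 42, quiet = TRUE)
res
#> <lnc_subpathway_result> 2 reported subpathway(s); 11 risk lncRNA(s)
#> # A tibble: 2 x 6
#>   region_id n_nodes n_edges p_joint p_adjusted key_lncrnas
#>   <chr>       <int>   <int> <chr>   <chr>      <chr>
#> 1 linear_1       20      19 <0.001  <0.001     lnc44,lnc13,lnc35,lnc18,lnc23,ln...
#> 2 erbb_1         42      53 0.973   0.973      lnc35,lnc13,lnc50,lnc47,lnc16

glance(res)
#> # A tibble: 1 x 6
#>   n_risk_lncrnas n_tested n_reported n_significant node_pool_size edge_pool_size
#>            <int>    <int>      <int>         <int>          <int>          <int>
#> 1             11        2          2             1             17             90
```

The pathway carrying the planted signal (`linear_1`) is recovered with a
joint permutation P below the 1/1000 resolution and survives BH
adjustment; the untouched ERBB-style pathway is reported but insignificant
(P = 0.973). Eleven of the 50 simulated lncRNAs pass the risk filter
(adjusted P < 0.25 and fold change > 1.5 or < 2/3), and the key-lncRNA
column lists the minimal set covering ≥ 80% of the region's associated
genes. `tidy(res)` flattens the result for export;
`autoplot()` methods draw weighted pathways and study summaries.

Reproducibility utilities mirror the cross-dataset comparison workflow:

```r
overlap_p(214, 32, 18, 11)   # hypergeometric pathway-set overlap
#> [1] 2.437783e-06
```

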