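---
title: "Locating risk lncRNA-associated dysregulated subpathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating risk lncRNA-associated dysregulated subpathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(lncsubpath)
```

## The problem

Long non-coding RNAs (lncRNAs) are rarely interpretable one at a time: a
set of disease-associated ("risk") lncRNAs typically acts on *regions* of
signalling and metabolic pathways rather than on whole pathways, and it can
do so both by shifting the expression of protein-coding genes (PCGs) and by
rewiring the correlations between lncRNAs, genes, and gene pairs.
`lncsubpath` scores both layers at once: it searches each pathway graph for
a connected subgraph whose genes are differentially expressed, whose
gene–gene co-expression has shifted between conditions, and whose genes are
associated with differentially expressed lncRNAs — then names the lncRNAs
that drive each region.

## Inputs

* matched lncRNA and PCG abundance matrices (e.g. FPKM) over the identical
  sample set, with a two-group (`case` / `control`) annotation
  (`expression_pair()`, `filter_low_expression()` with the default
  "non-zero in at least 20% of samples" rule);
* pathway topologies as undirected gene graphs, either converted from KGML
  (`kgml_to_graph()`) or loaded from edge lists;
* a bipartite lncRNA–PCG association network, loaded from an edge list or
  built from (i) multi-dataset co-expression and (ii) shared-miRNA (ceRNA)
  evidence (`build_coexpression_network()`, `build_cerna_network()`,
  `merge_networks()`).

## The model

**Risk lncRNAs.** Differential expression uses a two-sided Welch t-test on
`log2(x + pseudocount)` (pseudocount 0.01 on the FPKM scale) with
Benjamini–Hochberg adjustment. A lncRNA is a risk lncRNA when adjusted
P < 0.25 and its linear fold change is > 1.5 or < 2/3 — deliberately
permissive bounds, since the set feeds a network score rather than a final
call; all three comparisons are strict.

**Node prizes.** For a pathway gene $v$ with associated risk lncRNAs
$L_1,\dots,L_m$,

$$w_v = \alpha\,|\log_2 FC_v| + (1-\alpha)\sum_{j=1}^{m} d_{vL_j}\,
|\log_2 FC_{L_j}|,\qquad d_{vL_j} = 1 + |r^{case}_{vL_j} - r^{ctl}_{vL_j}|,$$

with $\alpha = 0.5$ by default, so gene-level and lncRNA-level
dysregulation contribute equally; $d \in [1,3]$ amplifies lncRNAs whose
coupling to the gene changed. Raw weights are normalized within one
pathway to prizes $b_v = \beta\,(w_v - w_{\min})/w_{\max}$ with
$\beta = 15$. The denominator is $w_{\max}$, not $w_{\max}-w_{\min}$ — we
keep the printed form of the rule; `range_normalize = TRUE` switches to
the range version, and with non-negative raw weights both keep
$b_v \in [0, \beta]$.

**Edge costs.** An edge weight $w_e = 1 - |r^{case}_e - r^{ctl}_e|$ is
*large for unchanged interactions*; after the analogous normalization
$c_e = (w_e - w_{e\min})/w_{e\max}$, stable edges are expensive and
rewired edges cheap. All correlations are Pearson correlations computed
within each group on the same `log2(x + pseudocount)` scale used for fold
changes; a group with fewer than 3 samples yields no correlation and is
treated as 0 with a warning. Pathway genes missing from the expression
matrix keep their place in the topology with $w_v = 0$ and neutral
incident edges ($w_e = 1$), so the graph is never fragmented by
missingness.

**Region search.** The dysregulated region is the connected subgraph
$G' = (V', E')$ minimizing $\sum_{e \in E'} c_e - \sum_{v \in V'} b_v$ — a
prize-collecting Steiner tree problem. `pcst_solve()` combines strong
pruning of component minimum spanning trees with a deterministic
steepest-descent local search (single-node removals and cheapest-path
additions, ties broken by objective, then region size, then node ids);
`pcst_solve_exact()` is an exhaustive oracle over all connected subsets
(refused above 15 nodes) against which the search is validated on random
instances. Only tree edges pay costs; significance below uses the
region's full induced edge set. `extract_subpathways()` iterates the
search on node-disjoint remainders to recover several regions per pathway
(`max_regions`).

**Significance.** A region's node score is the mean *raw* $w_v$; its edge
score is the mean edge differentiality $1 - w_e = |\Delta r|$. We score
edges by differentiality rather than by raw $w_e$ so that "larger = more
dysregulated" holds at both levels and the permutation tail is on the
right side; this is a deliberate reorientation of the printed edge
statistic. Each level is compared with 1000 randomizations against a
background pool: for nodes, the raw weights of *every* expressed gene
associated with at least one lncRNA of interest (independent of the
pathway collection); for edges, the differentialities of all edges across
all analysed pathways. Each randomization draws a same-sized set without
replacement and the P-value is the fraction of randomizations whose mean
is equal to or greater than the observed score ("equal or greater" wins
over the strictly-greater indicator; `strict_tail` restores the latter).
P resolution is exactly $1/R$ and a reported 0 means "< 1/R"
(`add_one` gives the $(k+1)/(R+1)$ variant). Because the node pool holds
only associated genes while a region may also contain unassociated ones
(which score lower), the node-level test is conservative under the null;
exact uniformity holds for the matched statistic that averages a region's
associated genes, which is what the calibration tests check. The joint P is the product
$p_v\,p_e$ — anticonservative for independent uniforms (CDF
$t(1-\ln t)$), which is why calibration is checked by simulation — and is
BH-adjusted across all tested subpathways. Reported regions must have at
least one associated risk lncRNA.

**Key lncRNAs.** Associated lncRNAs are ranked by
$IS = \gamma\,|\log_2 FC_L| + (1-\gamma)\sum_j d_{LG_j} D_{G_j}$
($\gamma = 0.3$; $D_{G_j}$ = degree of gene $j$ inside the region), then a
greedy pass seeds with the top lncRNA and adds a candidate only when it
strictly increases the fraction of region genes covered (union coverage),
stopping at coverage `pert` = 0.8. Rejected candidates are discarded
permanently — a single pass, which is how the stepwise rule reads; ties
break by larger |log2FC|, then id.

## The synthetic-data engine

The exact multivariate-normal parameterization of the original simulation
studies is not published, so the generator fixes its own, documented
conditions (all constants are arguments of `simulation_scenario()`):

* every dataset holds 150 PCGs and 50 lncRNAs: a 20-gene linear pathway, a
  51-gene ERBB-signalling-style topology (a synthetic stand-in bundled at
  `inst/extdata/erbb_edges_synthetic.tsv`, built to follow the KEGG ERBB
  structure), and independent noise genes; the two pathway systems share
  no interactions;
* log2 expression is multivariate normal with unit variances and baseline
  level 6 (about 64 FPKM); matrices are returned as $2^x$ so abundances
  are linear-scale and non-negative;
* baseline correlation $\rho_0 = 0.6$ on pathway edges and lncRNA–gene
  association pairs; lncRNAs attach to pathway genes by a seeded random
  bipartite graph with mean degree 2;
* dysregulation: a fraction $p$ of the target pathway's nodes (and the
  lncRNAs attached to them) gain a case-group mean shift of $\log_2 n$; a
  fraction $p$ of its edges, and the associations of altered genes, have
  their case correlation reduced by $e$;
* correlation patterns that are not positive definite (a 0.6 chain
  already is not) are repaired with the nearest correlation matrix
  (`Matrix::nearPD`), which shrinks realized correlations somewhat below
  $\rho_0$ — planted contrasts are therefore slightly conservative;
* null data (`simulate_null()`) draw both groups from one distribution;
  the `choi` preset fixes compound-symmetry correlation within each
  pathway block (0.6) and the lncRNA block (0.3), the `goel` preset
  redraws the two block correlations per dataset from U(0.2, 0.8) and
  U(0.1, 0.5).

What passing tests on these data do and do not show: the generator
emulates planted mean shifts and correlation rewiring under Gaussian
noise with a known association network. It does not emulate count noise,
library-size artefacts, outlier samples, mis-annotated associations, or
correlated noise genes — so the simulation results certify the
machinery's calibration and recovery behaviour, not performance on any
particular real dataset.

## The three studies

`run_sensitivity_study()` sweeps $(n, e, p)$ and records the fraction of
replicates whose best region of the target pathway reaches joint P below
0.01 / 0.05; detection ratios rise with both $n$ and $e$.
`run_fpr_study()` runs both null presets and scores, per pathway model,
the fraction of replicates whose best reported region reaches joint
P < 0.01; under the null the risk-lncRNA filter is rarely passed at all,
which is the method's main false-positive guard. `run_recall_study()`
plants four documented connected regions (`planted_regions()`: linear
g6–g12 and three disjoint 5–8-gene ERBB regions) and reports the mean
fraction of each region recovered by the identified subpathways.

Default desk-scale problem sizes — 100 null replicates per preset, 20
recall replicates, 30 replicates per sensitivity cell, 500 permutations
per level — were chosen once as the smallest sizes at which the binomial
noise of the reported rates is clearly below the margins being checked.

## Numerical choices and degenerate inputs

* All-zero (or constant) raw node weights give all-zero prizes; a pathway
  with no positive prize yields an explicit "no region" result rather
  than an empty tree.
* A region with no induced edges has an undefined edge score and edge
  P = 1 (the joint P then reduces to the node level).
* If a background pool is smaller than the region, sampling falls back to
  with-replacement with a classed warning.
* Tail probabilities (shared-miRNA test, pathway-overlap test) are
  accumulated in log space and validated against direct combinatorial
  summation; the shared-miRNA tail is strictly greater than the observed
  count, as the printed formula states, with a `tail = "geq"` switch.
* Fold-change and FDR thresholds are strict inequalities.
* Eq-style normalizations divide by the maximum; see `range_normalize`
  above for the range variant.

## Known limitations

* The lncRNA layer is unsigned: activation and repression are treated
  alike (the direction of lncRNA regulation is deliberately out of
  scope).
* Permutation backgrounds are defined over the supplied pathway
  *collection*; running a single pathway in isolation changes edge-level
  P-values (node-level pools are collection-independent by construction).
* The joint P is anticonservative as a nominal probability; it is meant
  to rank regions and to be compared against its own permutation-derived
  thresholds, and the false-positive-rate study is the calibration
  evidence.
* The bundled ERBB-style topology is a documented synthetic stand-in, not
  a KEGG export; analyses of real data should convert current KGML.
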