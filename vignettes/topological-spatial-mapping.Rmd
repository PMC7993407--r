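---
title: "Topological-consistency spatial mapping of single cells: models and methods"
author: "topomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological-consistency spatial mapping of single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topomap)
```

## The problem

Standard scRNA-seq destroys the spatial context of each cell. When a
binarized in situ hybridization atlas is available — a matrix $W \in
\{0,1\}^{n \times g}$ giving, for each of $n$ spatial location bins, the
on/off state of $g$ marker genes, together with bin coordinates $L \in
\mathbb{R}^{n \times 3}$ — cells can be mapped back to candidate bins by
comparing their expression profiles with the atlas. In the *Drosophila*
embryo setting that motivates this package the atlas has 3039 half-embryo
bins and 84 markers, and the expression matrix $Y$ holds 1297 cells; the
harder task is doing this with a *reduced* marker panel (60, 40 or 20
genes), which is what the gene-selection and gene-weighting machinery here
is for. `topomap` implements the full pipeline at any scale: preprocessing,
gold-standard assignment, gene selection, weight learning, neighbor-weighted
prediction, evaluation, and a synthetic-data generator with known ground
truth.

## Preprocessing

Raw UMI counts are library-size normalized per cell, with a pseudo-count of
1 and a natural log:
$y'_{cg} = \ln(1 + y_{cg}\, S / T_c)$, where $T_c$ is the cell's total
count. The scale $S$ defaults to the **median cell total**, keeping
normalized magnitudes comparable to raw counts; it is overridable. The
pseudo-count value, log base and scale are deliberate package choices — the
underlying procedure is conventionally described only as "UMI normalization
with pseudo-count and log transform".

Binarization then matches the atlas's correlation structure: for each
candidate quantile $q$ on a grid (default $0.05, 0.10, \dots, 0.95$; no
canonical grid exists), every gene is thresholded at its **own** $q$-quantile
(strictly greater than the threshold maps to 1, so an all-zero gene stays
all-zero), and the $q$ minimizing the RMSE between the gene–gene Pearson
correlation matrices of the binarized expression and of the atlas is
selected. Decisions worth noting:

* one *global* quantile with *per-gene* thresholds keeps the search
  one-dimensional while letting genes differ in expression breadth;
* the RMSE is taken over distinct gene pairs (upper triangle) — diagonal
  entries are identically 1 on both sides and would only dilute the error;
* Pearson correlation involving a zero-variance (constant) binary column is
  defined as 0 throughout the package;
* ties in the minimum RMSE go to the smaller quantile.

Because quantile thresholds commute with monotone maps, the binarization is
invariant to any strictly increasing transform applied uniformly to the
normalized matrix — one of the property tests asserts exactly this.

## Gold-standard locations

Each binarized cell profile is compared with every bin's atlas profile by
the Matthews correlation coefficient
$\mathrm{MCC} = (TP\cdot TN - FP\cdot FN)/\sqrt{(TP{+}FP)(TP{+}FN)(TN{+}FP)(TN{+}FN)}$,
taking 0 when any marginal is zero. The bin with the maximal MCC is the
cell's gold-standard location $l^*_c$; ties go to the smallest bin index so
assignments are platform-stable. This proxy ground truth is what the
supervised machinery trains against.

## Topological-consistency gene selection

The working hypothesis: a gene panel that predicts location well must make
expression similarity agree with geometric proximity. Three metrics express
this, all with neighborhood size $k$ (default 10, matching the number of
reported locations per cell; configurable):

* $M_1$ (unsupervised, atlas only): for each bin, the mean distance to the
  $k$ bins with the most correlated atlas profiles over the panel (self
  excluded). Small $M_1$ = expression-similar bins are spatially close.
* $M_2$ (unsupervised, atlas + cells): for each cell, find the $k$ bins most
  correlated with it and the single best bin $l_c$; average the distances
  from $l_c$ to the $k$ bins (the self term contributes 0, so $M_2 \equiv 0$
  at $k=1$).
* $N$ (supervised): for each cell, the mean distance between its gold bin
  and the gold bins of its $k$ most expression-similar cells (self
  excluded).

Panels are searched by greedy stepwise backward elimination: each step
evaluates all single-gene removals and keeps the subset minimizing the
objective ($M_1 + M_2$ unsupervised — an unweighted sum, both terms being
distances in the same units — or $N$ supervised), until the target size.
Greedy search carries no optimality guarantee; it is used because the
exhaustive alternative is infeasible and hybrid forward/backward search is
out of scope here. Supervised selection can be run per cross-validation fold
to produce the per-fold signatures used in the stability analysis.

All three metrics are invariant under rigid motions of the geometry, scale
linearly with global coordinate scaling, and ignore gene order — all
asserted as property tests against brute-force double-loop oracles.

## PSO gene weighting

Genes contribute unequally; a per-gene weight vector $w$ is learned by
particle swarm optimization against the fitness
$M_3(w) = \sum_c \sum_{j \in S_k^w(c)} D_{l^*_c, j}/(km)$, where
$S_k^w(c)$ are the $k$ bins whose *weighted* profiles correlate best with
the cell's *weighted* expression. The published description never defines
"weighted expression pattern"; this package multiplies **both** the cell
vector and each atlas row entry-wise by $w$ before the ordinary Pearson
correlation. This is the simplest symmetric reading and makes $M_3$
invariant to positive rescaling of $w$ (asserted directly). A
weighted-covariance correlation is a plausible alternative; it was
considered and not adopted as the default.

The update rule is exactly
$w_i \leftarrow w_i + \alpha\, r_1 \circ (Pbest_i - w_i) + \beta\, r_2 \circ (Gbest - w_i)$
with fresh uniform(0,1) vectors $r_1, r_2$ per agent per iteration — no
velocity memory, no inertia, no clamping. Further choices the rule itself
leaves open:

* initialization uniform over $[0,1]$ per entry, matching the scale of the
  $r$ draws;
* synchronous updates — all agents move using the previous iteration's
  bests, then bests are refreshed on strict improvement — making the result
  independent of agent order;
* a single seeded RNG stream, draws consumed in fixed agent order
  ($r_1$ then $r_2$, agent by agent), so runs are bit-reproducible.

Defaults are $\alpha = \beta = 0.2$, 200 agents, 40 iterations — the
full-challenge-scale setting. The test-suite and acceptance runs use reduced
swarms (typically 30–40 agents, 15–20 iterations) on fixtures of 25–150
bins; these sizes are the package's own test-scale choices and converge well
there. The global-best fitness is non-increasing by construction, and on
fixtures the optimized weights beat uniform weights and upweight a planted
location-determining gene — both asserted.

## Neighbor-weighted prediction

The raw bin–cell association matrix is
$C_{ij} = \mathrm{PCC}(w \circ W_{i\cdot},\, w \circ y_j)$ over the panel.
Smoothing multiplies by an affinity matrix $A_{ij} = e^{-d_{ij}/d^*}$, with
$d^*$ the median over bins of the nearest-other-bin distance:
$P = A\,C$. Each bin's final score is thus its own score plus an
exponentially distance-discounted sum of all other bins' scores, so an
isolated high scorer is discounted relative to one surrounded by other high
scorers. $A$ is computed densely (a few thousand bins squared is small), and
negative correlations in $C$ are kept — the monotone inequality
$P \ge C$ therefore only holds, and is only asserted, for nonnegative $C$.
The $k$ highest-scoring bins per cell (default 10, ties to the smaller bin
index) form the prediction. The three challenge presets map to: `sc1` =
learned weights + smoothing, `sc2` = uniform weights + smoothing, `sc3` =
learned weights, no smoothing (with very small panels the predicted
neighborhood itself is unreliable, so smoothing can hurt).

## Evaluation

With $d_K(c)$ the mean distance from cell $c$'s gold bin to its top-10 bins
predicted with $K$ genes, and $p_K(c) = d_{84}(c)/d_K(c)$ the ratio against
the full-panel uniform-weight reference prediction:

* $s_1 = \sum_c \frac{p_K(c)}{\sum_i p_K(i)}\,\mathrm{MCC}(f_{\mathrm{top1}(c)}, f_{l^*_c})$,
  profiles restricted to the $K$ selected genes by default (a flag compares
  full profiles instead — the published text does not fully pin this down);
* $s_2 = \operatorname{mean}_c p_K(c)$, which exceeds 1 when the reduced
  panel localizes better than the full panel;
* $s_3 = \sum_s u_s\, \mathrm{MCC}_{\forall c}(t_{\cdot s}, f_{\mathrm{top1}(\cdot),s})$
  with gene weights $u_s$ proportional to
  $\mathrm{MCC}_{\forall c}(t_{\cdot s}, f_{l^*_\cdot, s})$ normalized over
  the panel. The printed formula for $s_3$ is ambiguous about where the
  weight MCCs are evaluated; the default takes them at the gold bins and a
  documented flag (`weight_bins = "ref84"`) takes them at the full-panel
  reference's top-1 bins. Neither is presented as canonical.

If $d_K(c) = 0$ (all ten predictions at the gold bin) the ratio is assigned
the maximum finite $p_K$ over cells — perfection is rewarded without
producing infinities; this degenerate case is a package decision.

Panel stability uses the Jaccard index, its closed-form expectation for two
independent uniform $m$-subsets of $n$ genes
$E(J) = \sum_k \frac{k}{2m-k}\binom{m}{k}\binom{n-m}{m-k}/\binom{n}{m}$
(the intersection size is hypergeometric), and the upper-tail hypergeometric
probability for observed overlaps (a one-sided enrichment test, computed via
`phyper` and cross-checked against `fisher.test` in the tests). Virtual in
situ reconstruction turns a score matrix back into one spatial pattern per
gene: per bin, a weighted average of cell expression with weights
$\max(P_{bc}, 0)$ normalized within the bin. The reference methodology is
only described by pointer, so this weighted-average rule is a package
decision, isolated so alternatives can be swapped in.

## Synthetic fixtures

`make_fixture()` generates the three inputs with a known ground truth. The
default scale — 150 bins on a half-ellipsoid shell (semi-axes 2, 1, 1, the
half-embryo analogue), 30 genes of which 20 carry signal, 100 cells, 5%
flip noise, no dropout — is the condition set used by the recovery tests
and the acceptance script; every test completes in seconds at this scale.
Signal genes cycle through gradients (random direction), stripes (periodic
bands along the principal axis; period multiples of the nearest-neighbor
spacing, so a period-2 stripe on a unit line alternates exactly — the
segmentation-like hard case), and radial fields, each thresholded at its
median so about half the bins express each gene. Noise genes are fair coin
flips. Cells draw a uniform origin bin and emit Poisson counts
($\lambda_{\mathrm{high}} = 10$ where the origin bin's atlas entry is 1,
$\lambda_{\mathrm{low}} = 0.5$ elsewhere); flip noise swaps the two rates
per entry, and dropout (off by default; an optional stressor) zeroes
observed counts. Poisson emission — rather than directly binary cells —
exists precisely so that normalization and quantile binarization are
exercised on count-like data.

What the generator does *not* emulate: gene–gene correlation beyond shared
spatial structure, cell-type cluster structure, batch effects, ambient
contamination, or realistic library-size variation. Passing recovery tests
therefore demonstrates algorithmic correctness and reasonable statistical
behavior, not performance on real embryo data.

RNG discipline: geometry, atlas and cells seed private streams at
`seed + 0/1/2`, so each piece and the whole are reproducible; PSO and fold
splitting likewise run under `withr::with_seed` and never touch the
caller's RNG state.

## Numerical choices

* Correlations are computed with the zero-variance → 0 convention
  everywhere (constant binary profiles are routine, `stats::cor` would
  return `NA`).
* Ranked similarities are rounded to 10 decimals before ordering. Binary
  profiles frequently tie exactly in correlation; rounding makes the
  smallest-index tie rule decide those ties identically across
  algebraically equivalent computation routes instead of leaving them to
  float noise.
* All argmax/top-k ties break toward the smaller index; tied
  backward-elimination candidates break toward the lexicographically
  smallest removed gene name.
* Even-count medians (e.g. in $d^*$) are the midpoint of the central pair.
* Cross-validation folds are a seeded random partition with sizes differing
  by at most one.

## A worked example

```{r example, eval = FALSE}
fx <- make_fixture(fixture_spec(seed = 1))
norm <- normalize_counts(fx$cells_raw)
bin <- binarize_by_quantile_match(norm, fx$atlas)
gs <- gold_standard(bin$binarized, fx$atlas)
mean(gs$bin == fx$true_origin)            # origin recovery of the gold standard

sel <- select_genes(fx$atlas, norm, fx$geometry, "unsupervised", target_size = 20)
mean(sel$final %in% fx$signal_genes)      # planted-signal retention

fit <- optimize_gene_weights(sel$final, norm, fx$atlas, fx$geometry, gs,
                             pso_config(n_agents = 40, max_iter = 15, seed = 7))
pred <- predict_locations(norm, fx$atlas, fx$geometry, sel$final, fit$weights)
ref  <- predict_locations(norm, fx$atlas, fx$geometry)
challenge_scores(pred, ref, gs, bin$binarized, fx$atlas, fx$geometry, sel$final)
```

The same pipeline is scripted in `scripts/acceptance.R`, which regenerates
the fixture from a seed and reports these quantities as JSON.

## Known limitations

* The greedy elimination can discard a gene whose value only shows in
  combination with others; no optimality guarantee.
* The PSO weighting scheme and the $s_3$ weight placement are documented
  interpretations of under-specified procedures; both alternatives are
  implemented behind flags but results can differ between readings.
* The quantile search assumes a single global quantile serves all genes;
  panels with very heterogeneous expression breadth may binarize some genes
  poorly.
* Inputs are plain delimited text only; no HDF5/10x loaders and no dropout
  imputation (imputation is deliberately out of scope — it is reported not
  to help this pipeline).
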