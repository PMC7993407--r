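# topomap

Spatial mapping of single cells to location bins of an embryo from a
binarized in situ reference atlas, built on the principle of *topological
consistency*: a good marker panel makes expression similarity agree with
geometric proximity.

Given a binary atlas `W` (bins × marker genes), bin coordinates `L`
(bins × x,y,z) and an scRNA-seq matrix `Y` (cells × genes), the package

1. **preprocesses** `Y` (per-cell UMI normalization, `ln(1 + y·S/T_c)`,
   then per-gene quantile binarization, choosing the quantile whose
   binarized gene–gene correlation matrix best matches the atlas's);
2. assigns each cell a **gold-standard bin** — the bin maximizing the
   Matthews correlation coefficient (MCC) between the cell's binarized
   profile and the bin's atlas profile;
3. **selects reduced gene panels** by greedy backward elimination under the
   topological-consistency metrics `M1`/`M2` (unsupervised) or `N`
   (supervised), where e.g.
   `M1 = Σ_i Σ_{j∈topk(i)} D_ij / (k·n)` averages the distance from each
   bin to its k most correlation-similar bins;
4. learns **per-gene weights** by particle swarm optimization
   (`w_i ← w_i + α r₁∘(Pbest_i − w_i) + β r₂∘(Gbest − w_i)`) against the
   fitness `M3`, the mean distance between each cell's gold bin and its
   top-k weighted-correlation bins;
5. **predicts locations**: raw bin–cell correlation scores `C`, optional
   neighbor weighting `P = A·C` with `A_ij = exp(−d_ij/d*)` (`d*` = median
   nearest-bin distance), and the top-10 bins per cell;
6. **evaluates** with the challenge-style scores `s1` (weight-averaged
   profile MCC), `s2` (mean distance ratio vs. the full-panel reference)
   and `s3` (gene-wise expression-recovery MCC), plus panel-stability
   statistics (Jaccard, exact expected Jaccard, hypergeometric overlap
   test) and virtual in situ pattern reconstruction;
7. ships a seeded **synthetic fixture generator** (geometry, spatially
   coherent atlas, Poisson-count cells with known origins) so the whole
   pipeline is testable without any external download.

## Worked example

```r
library(topomap)

fx   <- make_fixture(fixture_spec(seed = 1))      # 150 bins, 30 genes, 100 cells
norm <- normalize_counts(fx$cells_raw)
bin  <- binarize_by_quantile_match(norm, fx$atlas)
gs   <- gold_standard(bin$binarized, fx$atlas)
mean(gs$bin == fx$true_origin)
#> [1] 0.99

sel <- select_genes(fx$atlas, norm, fx$geometry, "unsupervised", target_size = 20)
mean(sel$final %in% fx$signal_genes)
#> [1] 0.85

fit <- optimize_gene_weights(sel$final, norm, fx$atlas, fx$geometry, gs,
                             pso_config(n_agents = 40, max_iter = 15, seed = 7))
pred <- predict_locations(norm, fx$atlas, fx$geometry, sel$final, fit$weights)
ref  <- predict_locations(norm, fx$atlas, fx$geometry)   # full panel, uniform
str(challenge_scores(pred, ref, gs, bin$binarized, fx$atlas, fx$geometry, sel$final))
#> List of 4
#>  $ s1: num 0.819
#>  $ s2: num 1.08
#>  $ s3: num 0.716
#>  $ K : int 20
```

Read: the gold standard recovers 99% of the true origin bins; elimination
from 30 genes to 20 keeps 85% planted signal genes; the 20-gene weighted
panel localizes slightly *better* than the 30-gene uniform reference
(`s2 > 1`) while agreeing strongly with the gold-bin profiles (`s1`) and
recovering per-gene expression (`s3`).

A command-line interface wraps the same functions
(`topomap simulate | gold-standard | select-genes | optimize-weights |
predict | evaluate | stability | reconstruct`); see `exec/topomap`.

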