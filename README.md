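# gpsnet

Network-based identification of cancer-type-specific disease modules and
in silico drug repurposing against them.

## The problem

Somatic mutations from tumor sequencing are sparse: per cohort, most genes
carry few or no mutations even when their pathway is recurrently hit, and
statistically called driver genes alone are hard to drug.  Disease genes
do, however, cluster into densely interconnected subgraphs of the human
protein–protein interactome ("disease modules").  `gpsnet` finds such a
module for a cohort and then asks which drugs plausibly act on it.  It is
aimed at computational biologists working with an interactome edge list,
a per-gene mutation table, a tumor expression matrix, and a panel of drug
targets and drug-induced expression signatures.

## The method

1. **Score and smooth.**  Each gene gets a length-normalized mutation
   score `s0(i) = m(i)/l(i)`, diffused over the interactome by a random
   walk with restart, `s_{t+1} = (1−α) W s_t + α s0` with
   `W_ij = 1/k(j)` and restart probability `α = 0.5`.
2. **Grow modules.**  A module `M` of `m` genes scores
   `Z_m = Σ_{i∈M}(s(i)−μ)/√m` with `μ` the mean smoothed score.  From
   random seeds, interactome neighbours of the module are admitted
   greedily (best expanded score first) while they (a) link to the module
   more than degree-matched chance expects (hypergeometric tail
   `P(i) < 0.05`), (b) are significantly co-expressed with an interacting
   module gene (Pearson `r`, F-statistic `p < 0.05` over tumor samples),
   and (c) strictly increase `Z_m`.
3. **Aggregate.**  Raw modules smaller than 10 genes are discarded, the
   top 1% by score are pooled, genes appearing in more than 0.5% of them
   are kept, and their largest connected component in the co-expressed
   network is the final disease module.
4. **Screen drugs.**  Per drug: the closest network distance from module
   genes `S` to targets `T`, `d(S,T) = mean_t min_s d(s,t)`, standardized
   into a z-score against 1000 degree-preserving resamples of both sets;
   and a hypergeometric over-representation test of the drug's
   amplitude-derived signature (`a = (t−c)/((t+c)/2)`, up if `a > 0.67`,
   down if `a < −0.67`) among module genes.  P-values are BH-adjusted per
   method across the panel and drugs significant by either method are
   flagged.

Permutation validation statistics (LCC modularity, reference-set
enrichment, Jaccard module similarity, tissue-expression z-scores) and
seeded synthetic-data generators with planted ground truth round out the
package.  See `vignettes/gpsnet-methods.Rmd` for the full model, parameter
defaults, and design decisions.

## Worked example

A complete seeded study — scale-free 500-gene interactome, a planted
20-gene module with 10-fold elevated mutation rates and co-expression
0.6, and a 12-drug panel with 3 proximal and 3 concordant drugs:

```r
library(gpsnet)

study <- generate_study(seed = 42)
res <- find_disease_module(study$graph, study$profile, study$expr,
                           params = growth_params(rng_seed = 42))
res$final
#> Disease module: 15 genes
#>   from 1 top raw modules ( 38 surviving / 2500 raw )
jaccard_index(res$final$genes, study$planted)
#> [1] 0.75

set.seed(42)
lcc_significance(study$graph, res$final$genes, n_perm = 1000)
#> Permutation test (greater): observed = 15, p 0.003, z = 3 [1000 permutations]

set.seed(42)
screen <- repurpose_screen(study$drugs, res$final$genes, study$graph,
                           n_perm = 1000)
head(screen[, c("drug", "distance", "z", "adj_p_proximity",
                "adj_p_signature", "significant")], 5)
#>     drug distance      z adj_p_proximity adj_p_signature significant
#> 1 drug03     1.00 -0.728           1.000        3.48e-07        TRUE
#> 2 drug01     1.00 -0.873           1.000        2.26e-06        TRUE
#> 3 drug02     1.00 -0.776           1.000        2.26e-06        TRUE
#> 4 drug09     2.33  2.529           0.264        1.00e+00       FALSE
#> 5 drug12     1.33  1.181           1.000        2.78e-01       FALSE
```

Reading the output: the recovered 15-gene module overlaps the planted
truth at Jaccard 0.75 and forms a far larger connected component than
degree-matched random genes (permutation p = 0.003).  The three drugs the
generator planted (`drug01`–`drug03`) rank first: their targets sit at
mean distance 1 from the module (negative proximity z) and their
signatures are strongly enriched in it, while the nine decoys are
non-significant.

The same pipeline runs from the shell on TSV/GMT files:

```sh
exec/gpsnet simulate     --config run.yaml
exec/gpsnet build-module --config run.yaml
exec/gpsnet screen       --config run.yaml
```

where `run.yaml` holds the parameters and input paths (see
`default_run_config()`).  Outputs are TSVs stamped with the config hash
and seed; reruns with the same config and seed are byte-identical.

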