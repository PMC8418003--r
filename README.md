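# netprop

Expression-weighted network propagation for disease-gene prioritization.

## The problem

Given a set of genes with established disease association (*seed genes*,
e.g. from OMIM), which other genes in the protein–protein interaction
(PPI) network are most likely to be disease-relevant? `netprop` answers
this by combining two signals measured in a case/control expression study:

- **vertex weights** — differential expression:
  `w(v) = mean expression of v in disease samples / mean in normal samples`;
- **edge weights** — co-expression in the disease state:
  `w(u,v) = |Pearson r|` of the two genes across disease samples.

Disease risk is then propagated from the initial scores through the
weighted network with a restart-style recurrence

```
S(i+1) = (1 − k) · T · S(i) + k · S(0)
```

where `T` is the column-normalized transition matrix
`t(v|u) = w(u,v) / Σ_{r ∈ neighbor(u)} w(u,r)` (zero column when `u` has no
neighbors), `S(0)` gives seed genes an `h`-fold emphasis,
`s(v) ∝ h·w(v)` for seeds and `w(v)` otherwise, and `k ∈ [0,1]` balances
vertex information (restart) against edge information (propagation).
Iteration stops when successive score vectors differ by less than `1e-8`.
Genes are ranked by the converged scores in descending order.

Performance is assessed by leave-one-out cross-validation (LOOCV): each
seed gene is demoted to candidate status in turn, re-ranked using the
remaining seeds, and the distribution of held-out ranks yields a
rank-sum (Mann–Whitney) AUC. Grid search over `h ∈ {1,10,15,30}` and
`k ∈ {0, 0.1, …, 1}` selects the operating point; balanced subsampling
probes robustness to cohort size. A synthetic planted-module generator
provides ground-truth benchmarks so the whole pipeline is testable
without any external database.

## Worked example

```r
library(netprop)

# a synthetic benchmark: 300 genes, ~900 edges, a planted 15-gene module,
# 30 disease + 30 normal samples, twofold differential expression
spec <- simulationSpec(rngSeed = 7L)
bundle <- generateBenchmark(spec, "bench")

net <- buildWeightedNetwork(bundle$edges, bundle$data)
#> WeightedNetwork: 300 vertices, 894 edges (0 vertices, 0 edges dropped without expression)

res <- loocv(net, bundle$seeds, propagationConfig(h = 1, k = 0.7))
res
#> LoocvResult: 15 folds, AUC = 0.9724
#>   median held-out rank: 9.0 of 286
```

Each of the 15 planted module genes was held out once and re-ranked among
286 genes (285 candidates plus itself) by the remaining seeds; an AUC of
0.9724 means a held-out module gene outranks a random candidate about
97% of the time; the median held-out gene came back at rank 9 of 286. Ranking
real data works the same way from three TSV files and a seed list:

```r
edges <- readEdgeList("string_edges.tsv")
data  <- readExpression("expression.tsv", "labels.tsv")
seeds <- readGeneSet("omim_seeds.txt")
net   <- buildWeightedNetwork(edges, data)
s     <- propagate(transitionMatrix(net),
                   initialScores(net, seeds, h = 1),
                   propagationConfig(k = 0.7))$scores
rankGenes(s, seeds)        # candidate ranking
```

A command-line wrapper with `rank`, `loocv`, `grid`, `robustness` and
`simulate` subcommands is installed at
`system.file("scripts", "netprop.R", package = "netprop")`.

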