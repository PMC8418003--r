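---
title: "Methods: expression-weighted propagation and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression-weighted propagation and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netprop)
```

## The model

`netprop` scores every gene in a protein–protein interaction (PPI)
network for disease relevance by blending two expression-derived signals.
Differential expression enters through the vertex weight

$$w(v) = \frac{\bar E_{v,D} + \varepsilon}{\bar E_{v,N} + \varepsilon},$$

the ratio of the gene's mean expression in disease samples to its mean in
normal samples (pseudocount $\varepsilon$, default $10^{-6}$ on the
data's scale, keeps the ratio finite when the normal mean is zero; the
raw ratio is used, not a log-ratio). Co-expression enters through the
edge weight: the Pearson correlation of the two genes across the
*disease* samples only, mapped into $[0,1]$ by a transform (below).

From the edge weights a column-normalized transition matrix is built,

$$t(v \mid u) = \frac{w(u,v)}{\sum_{r \in \mathrm{neighbor}(u)} w(u,r)},$$

stored in (to, from) orientation so that propagation is the
left-multiplication $T S$. A vertex with no neighbors — or whose incident
edge weights are all zero — contributes an all-zero column; no
teleportation is added, so the stated formula is preserved and a little
score mass simply drains at such columns. Seed genes shape the initial
vector

$$s(v) = \frac{m_v\, w(v)}{\sum_{a \in G} h\, w(a) + \sum_{a \notin G} w(a)},
\qquad m_v = h \text{ if } v \in G \text{ else } 1,$$

which sums to one and is invariant to a global rescaling of the vertex
weights. Scores are then iterated to the fixed point of

$$S^{(i+1)} = (1-k)\, T S^{(i)} + k\, S^{(0)},$$

and genes are ranked by the converged $S$ in descending order, ties
broken by gene symbol (a stable, documented rule shared by every ranking
code path).

### Assumptions

- Expression inputs are pre-normalized (FPKM-like or microarray
  intensities); no count model, library-size correction or
  differential-expression testing is applied.
- Identifiers reconcile across files by exact uppercase symbol match;
  no alias dictionaries.
- The interaction list is taken at face value (any confidence filtering
  happened upstream).

## Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `h` | seed emphasis (integer ≥ 1) multiplying seed genes' initial scores | 1 | the grid search consistently favors the low end; `h = 1` treats seeds and candidates as equally important |
| `k` | restart weight in $[0,1]$: vertex vs edge information | 0.7 | interior optimum of the AUC grid; `k=1` disables propagation, `k=0` is pure power iteration |
| `tolerance` | convergence threshold on the residual | $10^{-8}$ | the method's stated stopping rule |
| `norm` | residual norm, `L1` or `Linf` | `L1` | the stopping rule names no norm; L1 matches the contraction bound below |
| `maxIterations` | iteration cap | 10000 | safety guard; unreachable for `k` ≥ 0.1 (see below) |
| `epsilon` | vertex-weight pseudocount | $10^{-6}$ | negligible against expression scales ~1–10, only active at zero normal means |
| `transform` | negative-correlation handling | `abs` | anticorrelation is still co-regulation evidence; `clip_negative` is available for the conservative reading |
| `missingPolicy` | network genes without expression | `drop` | avoids inventing weights; `neutral` (w = 1, zero-weight edges) keeps topology intact |

The negative-correlation question deserves a note: the transition scores
require non-negative weights while a Pearson $r$ is signed, and both
magnitudes (`abs`) and positive parts (`clip_negative`) appear in the
network-biology literature. `abs` is the default so that strongly
anticorrelated interactors are not silently disconnected.

## Numerical behaviour

For $k > 0$ the update map is a contraction with L1 factor at most
$(1-k)$ (columns of $T$ sum to 1 or 0), so the iteration reaches the
$10^{-8}$ criterion in at most $\lceil \log 10^{-8} / \log(1-k) \rceil$
steps — about 52 iterations at $k = 0.3$ and 16 at $k = 0.7$ — and the
fixed point equals the closed form
$S = k\,(I - (1-k)T)^{-1} S^{(0)}$, which `solveDirect()` computes by a
sparse LU solve and which the test suite uses as the oracle for the
iterative path. At $k = 0$ there is no contraction guarantee (a
bipartite component oscillates forever); the package runs it anyway,
raising a convergence error at the iteration cap rather than guessing,
and the grid search records such points as `NA`.

Without zero columns the iterates conserve total mass
($\sum S^{(i)} = 1$); with them the total decreases monotonically to a
value in $[k, 1]$. Zero-variance genes get edge weight 0; rounding just
past $\pm 1$ in the correlation is clipped.

One property worth stating precisely: raising `h` increases the *seed
set's aggregate share* of the propagated mass, but not necessarily every
individual seed-to-candidate score ratio — a candidate bordering several
seeds can profit from the amplified seed mass more than a peripherally
placed seed does. The property tests assert the aggregate form.

## Cross-validation conventions

LOOCV holds out each seed in turn. Design choices a reader should know:

- the held-out gene is *demoted to candidate*: it keeps its vertex
  weight but loses the `h` emphasis;
- the remaining training seeds are excluded from the ranked list, so the
  held-out gene competes only against true candidates (the standard
  prioritization convention — training seeds would otherwise crowd the
  top ranks);
- the AUC is the rank-sum (Mann–Whitney) estimator
  $\mathrm{AUC} = \overline{(n - r)/(n - 1)}$ over folds, with score
  ties entering as midranks (half credit). It is exact, threshold-free
  and equals the trapezoid area for rank data;
- sensitivity at a rank cutoff is the fraction of held-out genes at or
  above it; specificity is computed over each fold's *non-test ranked
  genes*. (Defining specificity over the test genes themselves, as the
  phrase "percentage of test genes ranked below the threshold" would
  imply, forces sensitivity + specificity ≡ 1 and AUC ≡ ½ regardless of
  the method — a degenerate reading we deliberately do not implement.)

The network and transition matrix are fixed across folds; only the
initial scores change, which keeps a 15-seed LOOCV on a 300-gene network
well under a second.

## The synthetic benchmark

`simulationSpec()` describes instances at a scale where every stage runs
in seconds: 300 genes, ~900 edges, a planted 15-gene disease module,
30 + 30 samples (defaults chosen to mirror, at roughly one-tenth scale,
the few-thousand-gene networks and ~100-per-arm cohorts this class of
method is applied to). Two generators derive everything from one
integer seed (network: `rngSeed`; expression: `rngSeed + 1`):

- **Topology** — a preferential-attachment background (PPI degree
  distributions are heavy-tailed; Erdős–Rényi available), vertex labels
  shuffled so the module does not land on the oldest (hub) vertices.
  The module is planted by *degree-preserving double-edge swaps*: each
  desired within-module edge (probability 0.3 per module pair, far
  above the ~0.02 background density) replaces one background edge at
  each endpoint, reconnecting the freed stubs. Every vertex keeps its
  background degree.
- **Expression** — baseline mean 5 (FPKM-like), Gaussian noise with
  SD 1, values clipped at zero (negligible at this mean/SD). Module
  genes have their disease-class mean multiplied by `foldChange` and
  share a per-sample latent factor with loading
  $\sqrt{\rho}$, giving expected pairwise within-module Pearson
  correlation exactly $\rho$ = `moduleCorrelation` in disease samples —
  the simplest mechanism with a controllable pairwise target.

Why degree preservation matters: a restart walk on a column-normalized
matrix systematically favors high-degree (more precisely, high-strength)
vertices, so planting the module by *adding* edges would let topology
alone separate it — with `h = 1` the ranking does not depend on the seed
identities at all, and a benchmark would score near-perfect AUC even
when the expression carries no signal. Degree-preserving planting
removes that confound. A subtler bias remains and is worth knowing
about: mass that enters a densely interlinked cluster takes longer to
escape, so module genes retain a modest score advantage purely from
their internal wiring even under an expression-null configuration
(`foldChange = 1`, `moduleCorrelation = 0`). The acceptance script
quantifies this as `mean_null_loocv_auc`; it sits meaningfully above ½,
and that is a property of the propagation kernel combined with *any*
topologically enriched module, not a generator artifact. Consequently,
passing the signal-recovery checks shows the pipeline ranks truly
perturbed modules near the top; it does not show the method is unbiased
on modules that are wired but not perturbed.

What the generator does **not** emulate: count noise (negative
binomial), library-size effects, microarray background, correlated
background modules, or seed sets scattered across several weakly
connected regions — results on real cohorts depend on all of these.

## Problem sizes used in the checks

Unit and property tests run on networks of 2–200 vertices; the
oracle-equivalence and contraction checks use random networks up to 500
vertices across the full `k` range. Benchmark-level checks use the
default 300-gene spec: 20 signal replicates, 50 null replicates, the
full 4 × 11 `(h, k)` grid, and 100 balanced subsamples at each of four
cohort sizes (12–48). The grid check runs on a co-expression-only
configuration (`foldChange = 1`, `moduleCorrelation = 0.6`): with the
default twofold change the vertex weights alone are nearly perfect and
the qualitative contrast between `k = 1` and the interior optimum would
be invisible.

## Known limitations

- Zero columns drain mass; rankings are unaffected (the drain is
  uniform in the limit) but absolute scores are not probabilities.
- `k = 0` may legitimately fail to converge; the package reports this
  rather than capping silently.
- Symbol-level identifier matching will drop genes whose expression and
  interaction sources use different aliases.
- The rank-based AUC treats folds as exchangeable; seeds in tiny
  disconnected components can only be recovered through their vertex
  weight.
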