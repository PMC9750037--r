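---
title: "Predicting drug side effects by heterogeneous-graph link prediction"
author: "adrgraph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug side effects by heterogeneous-graph link prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adrgraph)
options(adrgraph.quiet = TRUE)
```

## The problem

Post-marketing surveillance repeatedly uncovers adverse drug events (ADEs)
that clinical trials missed. Resources such as SIDER, OFFSIDES and FAERS
record known drug/side-effect associations, but the recorded matrix is
incomplete: an absent cell may be a true negative or an association nobody
has reported yet. Ranking those absent cells — link prediction on the
bipartite drug/side-effect graph — prioritizes candidate ADEs for review.

Two ingredients carry the signal. First, the observed bipartite structure
itself: drugs sharing many side effects tend to share more. Second, an
external drug-drug similarity (here: cosine similarities between drug-name
embeddings learned from biomedical text), which connects drugs whose
mechanisms are described similarly. `adrgraph` combines both into one
heterogeneous graph — drug and side-effect nodes, unweighted bipartite
association edges, and weighted drug-drug similarity edges — and scores
unobserved drug/effect pairs on it.

## Methods implemented

### The GCN + MLP link predictor

Every node $v$ carries a representation $h_v^k$ updated over $k = 1..K$
aggregation rounds:

$$ h_v^k = \mathrm{l2norm}\Big(\phi\big(\mathrm{concat}\big(h_v^{k-1},\;
\textstyle\frac{1}{|N(v)|}\sum_{u \in N(v)} \omega_{uv}\, h_u^{k-1}
\;+\; \max_{u \in N(v)} h_u^{k-1}\big)\big)\Big) $$

with $N(v)$ the neighbors across both edge types, $\omega_{uv}$ the
similarity weight (1 for bipartite edges), elementwise max, and $\phi$ a
single dense layer + ReLU, realized as two weight blocks: $B_k$ applied to
the self term and $W_k$ applied to the aggregated term. A pair
$(\mu, \nu)$ is scored $y_{\mu\nu} = \Phi(h_\mu^K, h_\nu^K)$, where
$\Phi$ is either a one-hidden-layer MLP on the concatenated pair (default)
or a plain dot product, squashed through a sigmoid. Training minimizes
binary cross-entropy of observed links (label 1) against sampled absent
cells (label 0) with full-batch Adam; everything — initialization,
negative draws, hence the whole loss trace — is determined by the
configuration seed.

Three choices matter and were genuinely open:

* **Initial representations.** No chemical descriptors accompany the
  data, so $h^0$ cannot be measured features. Free random embeddings are
  the textbook fallback, but in our experiments they let the model
  memorize the training links outright (training AUROC 1.0, held-out
  AUROC barely above an uninformed baseline). We instead initialize
  $h_v^0$ as a seeded random projection of the node's *structural
  profile* — for a drug, its similarity row concatenated with its
  training-link indicator row; for an effect, the indicator of its linked
  drugs — normalized to unit length. Random projections approximately
  preserve profile inner products, so neighborhood aggregation starts out
  scoring a candidate pair roughly by its similarity-weighted path count,
  and training refines from there (the embeddings remain learnable).
* **Row-wise L2 normalization** of each layer output. This bounds the
  scale of every representation, which is what prevents the remaining
  free-embedding capacity from drifting back into memorization; it is the
  convention of the sample-and-aggregate GCN family this encoder belongs
  to.
* **Per-epoch negative resampling.** A fixed negative set is itself
  memorizable. Epoch 1 uses the evaluation split's own training
  negatives; every later epoch redraws `negRatio` × (number of training
  positives) cells uniformly from the complement of the *training*
  positives only — test positives are not consulted, so an occasional
  held-out true link can appear as a training negative (harmless label
  noise at 5% density).

Defaults: depth 3 (the depth at which held-out performance peaks in our
experiments), width 64, MLP scorer with one hidden layer of 64,
Adam at learning rate 3e-3 for 400 epochs — the loss has plateaued well
before 400 under negative resampling at desk scale. Probability threshold
for Precision/Recall/F1 is 0.5. Test positives are excluded from message
passing during training *and* scoring (standard transductive hygiene).

### NMF and NMF with heat diffusion

The matrix-completion baseline factorizes the $m \times n$ 0/1 association
matrix $V \approx W H$ ($W, H \ge 0$) by Lee-Seung multiplicative updates
from a seeded uniform-random start; the reconstructed cell $(WH)_{pq}$
scores the pair. Multiplicative updates guarantee a non-increasing
Frobenius objective, which the tests assert numerically. Rank defaults to
64 (capped at $\min(m, n)$); the solver stops at 500 iterations or when
the relative objective change falls below 1e-6.

NMFHD first diffuses $V$ along the drug-similarity graph:
$V' = e^{\alpha t D} V$, where the generator $D$ has off-diagonal entries
$\omega_{ji}/d_j$ on similarity edges and diagonal
$-(\tau_i/d_i)\sum_k \omega_{ik}$, with $d_j$ the unweighted neighbor
count (a weighted-degree variant sits behind a flag) and
$\tau \in [0,1]$ a per-node outflow damping (default 1, pure
conservation: columns of $D$ sum to zero and total mass is conserved).
$\alpha$ and $t$ enter only through their product, exposed as the single
parameter `alphaT` (default 1). Isolated drugs get a zero row/column —
the no-flux limit. The matrix exponential is computed by
`Matrix::expm()`; `alphaT = 0` bypasses it entirely so NMFHD then equals
NMF bit for bit. Diffusing *after* factorization is available as
`order = "post"` for comparison.

### Heuristic indices

Adamic-Adar, resource allocation, preferential attachment (degree
product; the convention for the index whose defining formula the
benchmark literature leaves implicit), truncated/closed-form Katz
(β = 0.005, length ≤ 5 by default, with a numeric subcriticality check),
and personalized PageRank (ω = 0.85, power iteration, dangling mass
returned to the source). All run on the *combined* heterogeneous
adjacency with similarity edges binarized at any positive weight: in a
purely bipartite graph a drug and an effect can never share a common
neighbor, so AA and RA would be identically zero — the similarity layer
is what makes these indices informative, and a test asserts exactly that
contrast. Logarithms in AA are natural.

### Evaluation protocol

Positives are shuffled once per repeat and split into $k$ folds. The test
fraction is a free parameter rather than forced to $1/k$ (so $k$ and the
held-out percentage can be varied independently, reproducing protocol
tables that vary them separately); when it equals $1/k$ the folds
partition the positives exactly. Negatives are drawn uniformly from the
never-observed cells at a 1:1 ratio by default — the full negative
universe (tens of millions of cells at real-data scale, counted exactly
by `negativeUniverseSize()`) is never materialized. Per fold we report
positive-class Precision/Recall/F1 at 0.5 plus AUROC (rank/Mann-Whitney
form, ties half-counted) and AUPR (step summation over distinct
thresholds — no interpolation, so constant scores score exactly the
prevalence). Mean ± sample sd is aggregated both across all
$k \times$ repeats folds and across per-repeat means (the two readings of
"run 10 times"); `compareMethods()` is a two-sided Welch t-test on the
per-fold vectors, appropriate when methods have very different fold
variances, with no multiplicity correction (none is applied in the
protocol this follows).

## The synthetic generator

`generateSynthetic()` emulates the two input files end to end. Ground
truth is a logistic latent-factor model: drug factors $U$ ($m \times r$)
and effect factors $E$ ($n \times r$) with i.i.d. $N(0, \sigma^2)$
entries, link probability $P = \sigma(U E^\top + b)$ with $b$ set by
bisection so the mean probability equals the target density, links drawn
as independent Bernoullis, an optional fraction of cells flipped
(`noise`), and similarity defined as the cosine of drug factor rows
(negatives clipped to zero) when informative, or an independent random
symmetric matrix as a negative control. Defaults: $m = 100$, $n = 200$,
$r = 5$, density 0.05 (about a thousand positives — trains the GCN in
seconds on one CPU), noise 0, informative similarity.

The factor variance (`signal`, default 2) is the one parameter with no
external anchor, and it sets how recoverable the planted structure is. At
unit variance most link probabilities hover in a noisy mid-range: even
scoring pairs by their *true* probabilities barely separates held-out
links from random cells, so no method — however good — could demonstrate
anything there. At `signal = 2` roughly a third of realized links have
true probability above 0.9, which matches the intuition that reported
drug/ADE associations are reproducible findings rather than coin flips,
while leaving a substantial noisy margin; all methods then order the way
the real-data benchmarks order (GCN above NMF above the heuristic
indices on AUPR). We fixed 2 once on that reasoning.

What the generator does *not* emulate: MedDRA term hierarchies, the heavy
skew of real side-effect frequencies, reporting biases correlated between
similar drugs, and text-derived similarity noise. Passing benchmarks on
synthetic graphs therefore demonstrates correctness of the machinery and
the expected qualitative method ordering under a recoverable planted
model — not real-data effect sizes.

## Numerical choices and degenerate inputs

* Multiplicative-update denominators carry a 1e-12 guard; the all-zero
  matrix is a fixed point reached after one update.
* `heatPropagate` clips the (theoretically non-negative) propagated
  matrix at zero against floating-point undershoot.
* Similarity must be symmetric within 1e-8 (1e-12 for a stored graph) and
  in [0, 1]; file scores outside by ≤ 1e-6 are clamped with a warning,
  larger violations error.
* Ranking ties: AUROC counts ties 1/2; AUPR groups tied scores into one
  threshold block; `predictTopK` breaks probability ties by effect index.
* Degenerate folds (single-class test sets) abort rather than being
  silently skipped; an all-excluded candidate list in `predictTopK`
  returns an empty frame with a warning.
* Zero learning rate is allowed and leaves the model exactly at its
  initialization (useful for testing); a non-finite loss aborts with the
  epoch number.

## Problem sizes used in tests

Module tests run on graphs of 2-20 drugs; the benchmark and ranked-query
checks use the generator's default 100 × 200 graph with the 10-fold,
10%-held-out, 1:1-negative protocol (one repetition), and ten generator
seeds for the held-out-link recovery check. These sizes were chosen so the
planted structure is comfortably estimable while the full suite stays a
desk-scale run.

## Known limitations

* The encoder is transductive: a drug absent from training has no
  embedding. Inductive scoring of new drugs would need feature-based
  $h^0$ for unseen nodes.
* Heuristic indices use the binarized similarity graph; weighted variants
  and one-mode projections are deliberately out of scope.
* The negative universe is sampled, never enumerated, so Precision/Recall
  are relative to a balanced sample, not to all ~$mn$ absent cells.
* Checkpoints store dense weight arrays as JSON — fine at desk scale,
  inefficient for very large graphs.
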