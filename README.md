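# adrgraph

Link prediction for adverse drug event (ADE) discovery on a heterogeneous
graph. Resources like SIDER, OFFSIDES and FAERS record which drugs are
*known* to cause which side effects, but the recorded matrix is incomplete;
`adrgraph` ranks the unrecorded drug/side-effect cells by how likely they
are to be true, unreported associations, so pharmacovigilance effort can be
focused.

The graph has two node types (m drugs, n side effects) and two edge types:
observed bipartite associations, and weighted drug–drug similarity edges
(cosine similarities supplied as a three-column file). On this graph the
package implements:

* **GCNMLP** — a graph-convolutional encoder with an MLP link scorer. Each
  of K aggregation rounds updates
  `h_v ← l2norm(φ(concat(h_v, mean_{u∈N(v)} ω_uv h_u + max_{u∈N(v)} h_u)))`
  over both edge types; a pair (μ, ν) is scored
  `y_{μν} = σ(Φ(h_μ, h_ν))`. Trained end-to-end (full-batch Adam, analytic
  gradients, negatives resampled every epoch) against sampled absent
  cells.
* **NMF / NMFHD** — matrix completion `V ≈ WH` by multiplicative updates,
  optionally after heat diffusion `V' = exp(αtD) V` of the association
  matrix along the similarity graph (generator D with per-node outflow
  flags τ).
* **Heuristic indices** — Adamic–Adar, resource allocation, preferential
  attachment, Katz and personalized PageRank on the combined adjacency.
* **An evaluation harness** — repeated k-fold cross-validation over the
  positive links with uniformly sampled negatives, Precision / Recall /
  F1 / AUROC / AUPR as `mean±sd`, ROC/PR curve export, and Welch t-tests
  between methods.
* **A synthetic generator** — seeded logistic latent-factor graphs written
  in the exact file dialects the readers parse, so the entire pipeline is
  testable offline.

See the methods vignette (`vignettes/link-prediction-methods.Rmd`) for the
model, parameter and protocol details.

## Worked example

```r
library(adrgraph)

# a seeded synthetic dataset drawn on a 100 x 200 grid (~1000 links;
# drugs/effects that realize no link do not enter the graph)
synth <- generateSynthetic(syntheticSpec(seed = 7))
g <- synth$graph
g
#> HeteroGraph: 93 drugs x 164 side effects, 975 positive links,
#>   2155 similarity edges (threshold 0)

# benchmark the GCN against Adamic-Adar on shared 10-fold splits
reports <- runBenchmark(graph = g, methods = c("gcnmlp", "aa"),
                        k = 10, testFraction = 0.1, baseSeed = 8)
reports$gcnmlp
#> MetricsReport for 'gcnmlp' (10 folds x 1 repeats):
#>   precision 0.879±0.023
#>   recall    0.625±0.072
#>   f1        0.728±0.049
#>   auroc     0.866±0.027
#>   aupr      0.872±0.019
reports$aa
#> MetricsReport for 'aa' (10 folds x 1 repeats):
#>   precision 0.841±0.039
#>   recall    0.433±0.077
#>   f1        0.567±0.069
#>   auroc     0.817±0.024
#>   aupr      0.813±0.018
compareMethods(reports$gcnmlp, reports$aa, "aupr")$p_value
#> [1] 1.256596e-06

# train on the full graph and rank unreported side effects for one drug
model <- trainGcn(g, config = gcnConfig(seed = 1))
predictTopK(model, g, "DRUG0001", k = 5)
#>   side_effect_name probability rank
#> 1      effect_0162   0.9666859    1
#> 2      effect_0063   0.9309497    2
#> 3      effect_0071   0.7887545    3
#> 4      effect_0040   0.7770260    4
#> 5      effect_0052   0.7571105    5
```

The benchmark report reads as: on held-out links (balanced 1:1 against
sampled absent cells) the GCN separates true from absent associations with
AUROC ≈ 0.87 and AUPR ≈ 0.87, ahead of the best closed-form index; the
t-test confirms the AUPR gap is far beyond fold noise. The top-k table
ranks side effects *not* recorded for the drug by predicted probability —
the candidates one would review first.

Real exports (a four-column association file and a three-column similarity
file) enter the same way via `readAssociations()` / `readSimilarity()` /
`buildHeteroGraph()`, or through the command-line dispatcher
`inst/cli/adrgraph.R` (subcommands `simulate`, `train`, `evaluate`,
`benchmark`, `predict`).

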