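# damgcn

Supervised adversarial domain adaptation between patient similarity graphs,
for cross-domain clinical risk classification.

## The problem

Risk cohorts collected under different outcome definitions (all-cause death,
cardiac-function level, major adverse cardiac events, ...) share label
semantics but not distributions. Represent each cohort as a graph — patients
as nodes, edges between patients with similar feature profiles — and a
classifier trained on one graph transfers poorly to another: both the feature
marginals and the topology shift. `damgcn` trains **one** model on a labeled
source graph and a related target graph so that knowledge flows across, and
classification on the target (and usually the source too) improves.

## The model

Each domain `(A, X, Y)` is encoded by a shared dual-channel graph
convolutional encoder:

- **local channel**: two stacked convolutions over the symmetric normalized
  adjacency `D̃^{-1/2} (A + I) D̃^{-1/2}` (widths `d → 128 → 16`, ReLU,
  dropout 0.5);
- **global channel**: the same architecture over a positive pointwise mutual
  information (PPMI) operator `D^{-1/2} P D^{-1/2}`, where
  `P_ij = max(log(p_ij / (p_i· p_·j)), 0)` is harvested from skip-gram
  co-occurrence counts of random walks over the graph — longer-range
  "similar context" structure that one-hop adjacency misses.

Per node, an attention scorer (`v' tanh(W [z ‖ Jx] + b)`, softmax over the
two channels) fuses the channel embeddings into a convex combination `Z`.
Three heads sit on `Z`: source and target softmax label classifiers and a
sigmoid domain classifier behind a **gradient-reversal layer** (identity
forward, gradient times `-λ` backward). The joint objective

```
L = L_S + γ1 · L_DA + γ2 · L_T
```

is minimized by full-batch Adam (`lr = 3e-3`, 300 epochs, `γ1 = 1`,
`γ2 = 0.8`, seed 21), with `λ` ramping as `min(2/(1+e^{-10p}) − 1, 0.1)`
over training progress `p`. The adversary pushes the domain head to separate
domains while the reversed gradient pushes the shared encoder to mix them:
embeddings become class-discriminative *and* domain-invariant.

The backward pass is derived by hand in matrix form and verified in the test
suite against finite differences over every parameter. Ablation variants
(`no_target`, `no_global`, `no_domain`) switch off each component.

## Worked example

Everything runs on synthetic paired domains that mimic the shape of the
clinical setting (25 features, rare positive outcome, larger source than
target, covariate-shifted target):

```r
library(damgcn)

pair <- generate_domain_pair(synthetic_spec())   # 300 + 200 patients, k = 6
fit  <- train_damgcn(pair$source, pair$target)   # full model, 300 epochs
fit
#> <damgcn_fit> variant = full, 300 epochs
#>   source: 300 nodes | target: 200 nodes | embedding dim 16
#>   final losses: L_S = 0.0166, L_DA = 0.6711, L_T = 0.0171, total = 0.7013

evaluate_fit(fit, "target")   # metric suite on the target test split
#> # A tibble: 1 × 9
#>   task      n accuracy   auc precision recall    f1   mcc balanced_accuracy
#>   <chr> <dbl>    <dbl> <dbl>     <dbl>  <dbl> <dbl> <dbl>             <dbl>
#> 1 <NA>     80    0.925 0.939     0.853  0.853 0.853 0.706             0.853
```

Both classifier losses collapse toward zero while the domain-adversarial
loss hovers near `log 2 ≈ 0.693` — the domain classifier is reduced to
guessing, i.e. the embeddings are domain-invariant. On the 40 % held-out
target split the model reaches 92.5 % accuracy and 0.71 MCC despite the
15 % positive-class imbalance. An ablation over seeds 21–25
(`run_ablation(pair$source, pair$target, seeds = 21:25)`) orders the mean
target accuracies full (0.932) ≥ no_domain (0.930) ≥ no_global (0.922) ≥
no_target (0.905): every component helps, and dropping the target classifier
loss hurts most.

`tidy(fit)` returns the per-epoch loss trace, `glance(fit)` a one-row
summary, `autoplot(fit)` the loss curves, and
`export_embeddings(pair$target, "fused", fit, ...)` writes final-layer
embeddings plus aligned labels for external t-SNE/UMAP projection.

## Command line

A thin CLI over the same functions lives at `inst/cli/damgcn`
(`system.file("cli", "damgcn", package = "damgcn")` after installation):

```sh
damgcn simulate --out-dir data --seed 1
damgcn train --source data/source --target data/target \
       --config run.yaml --checkpoint fit.rds --trace trace.csv
damgcn evaluate --checkpoint fit.rds
damgcn ablate --source data/source --target data/target --seeds 21,22,23
damgcn export-embeddings --checkpoint fit.rds --layer fused \
       --out emb.csv --labels-out labels.txt
```

Domains on disk are plain text: `features.csv`, `labels.txt`, and a 0-based
undirected `edges.tsv`. YAML run configs use the standard key names
(`epochs`, `k`, `lr`, `nhid1`, `nhid2`, `dropout`, `gamma1`, `gamma2`,
`seed`). `ppmi_operator(..., cache_dir =)` caches frequency/PPMI matrices
(RDS, keyed by graph hash and walk configuration) so reruns skip walk
sampling.

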