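# molgcn

Multi-task classification of chemical compounds from SMILES with a
**cost-sensitive graph convolutional network**.

The package was built for organ-Meridian annotation of herbal ingredient
compounds — a 12-task binary classification problem in which each compound
inherits the Meridian labels of the herbs containing it — but the machinery
is generic: any compound table (SMILES plus binary multi-label annotations)
with heavy class imbalance fits the same mould.

## The model

A compound is a heavy-atom graph *G = (V, E)*. Starting from a 28-dimensional
per-atom encoding (element, degree, hydrogen count, aromaticity, formal
charge), each hidden layer applies a **degree-indexed graph convolution**

> h<sup>t+1</sup>(v) = ReLU( W<sup>t</sup><sub>deg(v)</sub> ( h<sup>t</sup>(v) + Σ<sub>u∈N(v)</sub> h<sup>t</sup>(u) ) + b<sup>t</sup><sub>deg(v)</sub> )

— one weight matrix per node degree (0–6) — followed by node-level batch
normalization and max-pooling over each atom's closed neighbourhood. A
degree-weighted **graph-gather** readout

> g = tanh( Σ<sub>i</sub> Φ<sub>deg(v_i)</sub> h(v_i) + β )

produces one embedding per molecule, and a dense sigmoid head emits one
probability per task. Training minimizes the **focal loss**

> ℓ = −α (1−ŷ)<sup>γ</sup> log ŷ  (y = 1),  ℓ = −(1−α) ŷ<sup>γ</sup> log(1−ŷ)  (y = 0)

(defaults γ = 2, α = 0.5) with Adam (lr 0.0005, batch 64, 200 epochs, depth
3, width 1024 as reference defaults). At γ = 0 the loss reduces to scaled
cross entropy; γ > 0 down-weights easy negatives so rare-positive tasks keep
a gradient. Forward and backward passes (including batch-norm
backpropagation) are implemented in vectorized R; gradients are verified
against finite differences in the test suite.

Around the model the package provides:

* SMILES parsing (OpenBabel via ChemmineOB) into heavy-atom graphs, and
  hashed circular **ECFP4-style fingerprints** (radius 2, 1024 bits) for
  external baseline classifiers,
* four splitting strategies — index, random, **iterative multi-label
  stratified**, and **Bemis–Murcko scaffold** split with leakage guarantees,
* evaluation: per-task confusion matrices, midrank Mann–Whitney **ROC-AUC**,
  macro averages, task-task cosine similarity,
* a **synthetic planted-motif generator**: valence-safe fragment
  concatenation with per-task substructure motifs and controllable positive
  fractions (default profile: 761 molecules, 12 tasks, positive fractions
  0.53 down to 0.007), so every component is testable without external data,
* an experiment runner (`run_experiment()`, `run_sweep()`) and a thin CLI
  wrapper (`inst/cli/molgcn.R`) with simulate / featurize / split / train /
  evaluate / sweep subcommands.

## Worked example

Simulate an imbalanced two-task dataset, split it with multi-label
stratification, train a small network, and evaluate on the held-out fold:

```r
library(molgcn)

spec  <- synth_spec(n_molecules = 300, n_tasks = 2,
                    positive_fraction = c(0.2, 0.05),
                    motifs = task_motifs(2), seed = 7)
ds    <- simulate_dataset(spec)
ds$labels
#> label_matrix: 300 compounds x 2 tasks
#>   positives per task: 60 15

split <- stratified_split(ds$labels, seed = 7)
split
#> split_result (random_stratified): 240/30/30 train/valid/test

fit <- fit_gcn(ds$graphs, ds$labels, split,
               fit_config(depth = 2, width = 32, epochs = 30, seed = 7))
fit
#> gcn_fit: 30 epochs; best epoch 29
#>   final train loss 0.01472 valid macro AUC 0.8661

evaluate_model(fit$params, ds$graphs, ds$labels, split$test)
#> eval_report: macro AUC 0.9310 over 2 defined tasks
#>      task tp fp tn fn      auc  n
#> 1   liver  4  0 24  2 1.000000 30
#> 2 stomach  0  0 29  1 0.862069 30
```

Reading the output: the two planted substructures are recovered almost
perfectly in ranking terms (AUC 1.00 and 0.86) after 30 epochs on 240
training molecules. The rare task (15/300 positives) shows the
characteristic imbalance signature — good AUC but zero recall at the fixed
0.5 threshold — which is precisely the regime the focal loss and the
stratified split are designed for; `imbalance_benchmark()` quantifies both
effects on a grid of positive fractions and loss settings.

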