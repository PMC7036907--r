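---
title: "Cost-sensitive graph convolutional classification of molecules: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-sensitive graph convolutional classification of molecules: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Herbal medicines are annotated with organ-Meridian categories (liver,
stomach, lung, ..., twelve in all), and each herb contains many ingredient
compounds. Treating every compound as inheriting the Meridians of its herbs
yields a compound-level multi-label classification problem with two defining
difficulties: the labels are heavily imbalanced (in the motivating data the
positive fraction per task ranges from roughly 0.53 down to 0.007), and the
predictive signal lives in molecular *structure*, which fixed-length
fingerprints summarize lossily. `molgcn` addresses both: a graph
convolutional network learns task-relevant substructure features directly
from the molecular graph, and a focal-loss objective keeps the rare-positive
tasks from being drowned out by easy negatives.

# Model

A compound is an undirected heavy-atom graph $G = (V, E)$; hydrogens are
implicit and enter through the atom features. Each atom $v$ starts with a
fixed-length feature vector (one-hot element over $\{C, N, O, S, F, P, Cl,
Br, I, \mathrm{other}\}$, one-hot degree $0{-}6$, one-hot hydrogen count
$0{-}4$, an aromaticity flag, one-hot formal charge clipped to $[-2, 2]$;
28 dimensions in total). The network stacks, per hidden layer $t$:

1. **Degree-indexed graph convolution.** With $d = \deg(v)$ clipped to
   $[0, 6]$,
   $$h^{t+1}(v) = \mathrm{ReLU}\!\left(W^t_{d}\Big(h^t(v) + \sum_{u \in N(v)} h^t(u)\Big) + b^t_{d}\right),$$
   i.e. one weight matrix per node degree, shared between the centre atom
   and the neighbour sum exactly as the update is written. A configuration
   switch (`tied = FALSE`) unties the self and neighbour matrices for
   ablation studies.
2. **Node-level batch normalization.** Each feature channel is normalized
   to zero mean and unit variance over *all atoms of all molecules in the
   mini-batch* (population variance, $\varepsilon = 10^{-5}$), with learned
   scale and shift; running statistics (momentum 0.9) are used at
   evaluation time. Per-batch rather than per-molecule statistics were
   chosen because molecules are small (often 2-40 atoms) and training is
   batched; a single molecule would give extremely noisy statistics.
3. **Neighbourhood max-pooling.** Each atom takes the element-wise maximum
   of its closed neighbourhood $\{v\} \cup N(v)$.

After the hidden layers a **graph-gather readout** forms one embedding per
molecule,
$$g = \tanh\!\left(\sum_{i=1}^{N} \Phi_{\deg(v_i)}\, h(v_i) + \beta\right),$$
followed by a dense layer with element-wise sigmoid, one output per task.
The gather bias is implemented as a *single shared vector* added after the
node sum: a per-degree bias subscripted by one node inside a sum over all
nodes is not well defined as written, and a shared bias is the unique
interpretation that keeps the readout permutation-invariant.

Degree-indexed parameter collections always cover degrees 0-6 (organic
valence rarely exceeds 6; larger degrees are clipped when indexing), so
parameter shapes are fixed and serialization is trivial. Parameters for
degrees absent from the data exist but stay at initialization.

# Objective and training

The focal loss for one cell (binary target $y$, predicted probability
$\hat y$) is
$$\ell(y, \hat y) = \begin{cases} -\alpha\,(1 - \hat y)^{\gamma} \log \hat y & y = 1,\\ -(1 - \alpha)\,\hat y^{\gamma} \log(1 - \hat y) & y = 0,\end{cases}$$
with defaults $\gamma = 2$, $\alpha = 0.5$. At $\gamma = 0$ and
$\alpha = 0.5$ it is exactly half the binary cross entropy; larger $\gamma$
suppresses the loss (and gradient) of confidently-correct cells, which under
severe imbalance are overwhelmingly easy negatives. The batch objective is
the *mean* over all (sample, task) cells, making the learning-rate meaning
independent of batch size and task count. Probabilities are clamped to
$[10^{-7}, 1 - 10^{-7}]$ before the logarithm.

Training uses hand-written reverse-mode gradients (including the batch-norm
backward pass through the batch statistics) and Adam with the standard
moments ($\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$).
Reference defaults follow the original protocol: depth 3, width 1024, batch
size 64, 200 epochs, learning rate 0.0005. Weights are initialized
scaled-uniform $U(-1/\sqrt{f}, 1/\sqrt{f})$ with fan-in $f$; biases start at
zero. All randomness (initialization, shuffling) flows from the single
`seed` of `fit_config()`, so runs are bit-reproducible on one platform.
The returned parameters are those of the epoch with the best validation
macro-AUC: the protocol this package mirrors reports scores on train,
validation and test folds, which implies validation-driven selection
without fixing the rule, so best-validation-epoch is the package's
documented choice; final-epoch parameters remain reachable through the
training history.

# Dataset splitting

Four strategies, all targeting 80/10/10 train/validation/test:

* **index** — first block train, next validation, rest test, in input
  order.
* **random** — a seeded permutation followed by the index split.
* **random stratified** — iterative multi-label stratification: tasks are
  processed from rarest to most common; each task's not-yet-assigned
  positives are apportioned 80/10/10, after first ensuring every fold holds
  at least one positive of any task with $\ge 3$ positives (evicting or
  swapping already-placed samples when a fold is full, provided no other
  task loses its own coverage). Tasks with 1-2 positives put them in train
  with a warning. Remaining samples fill the folds to their exact target
  sizes. The guarantee is best-effort: with more mutually disjoint tasks
  than small-fold slots it is infeasible and a warning is raised instead.
* **scaffold** — molecules are grouped by identical canonical Bemis-Murcko
  scaffold (iteratively pruning degree-1 atoms, then canonicalizing the
  remaining ring-and-linker subgraph); groups are sorted by size
  (descending, ties by scaffold string) and assigned whole to train until
  it reaches 80%, then validation until 10%, remainder test. Acyclic
  molecules share one pseudo-scaffold group — treating each as a singleton
  would scatter structurally trivial molecules across folds and weaken the
  leakage guarantee.

Fold sizes use largest-remainder apportionment, which keeps every fold
within one sample of its exact fractional size for every $n$ (a
floor/floor/remainder rule can drift by almost two samples on the last
fold).

# Evaluation

Per task: a confusion matrix at threshold 0.5 (threshold-dependent, so only
descriptive) and ROC-AUC computed by the midrank Mann-Whitney formula —
ties receive half credit. Tasks whose evaluation fold contains a single
class report an undefined AUC and are *skipped* by the macro average rather
than imputed; with tasks as small as a handful of positives, imputing 0.5
(or 0) would materially distort the average. Task-task cosine similarity of
the binary label columns is available for inspecting label correlation
structure.

# Synthetic planted-motif data

The generator assembles each molecule by concatenating 2-6 fragments from a
built-in library of ~30 valence-safe SMILES fragments (alkyl chains and
branches, benzene rings, cycloalkanes, internal ethers and ketones); every
fragment begins and ends with an atom that tolerates one extra single bond,
so any concatenation parses. For each task, `round(fraction * n)` molecules
receive that task's motif fragment at a random position; labels are then
computed *honestly* by subgraph matching (not copied from the plant), and
optional label noise flips each cell independently. The default
specification mirrors the motivating data's imbalance spread: 761
molecules, 12 tasks, positive fractions $\{0.53, 0.37, 0.34, 0.32, 0.28,
0.26, 0.17, 0.08, 0.05, 0.035, 0.007, 0.007\}$.

Two deliberate design properties:

* The base library contains no nitrogen, sulfur, halogens, alkenes,
  boundary oxygens or carbonyl-adjacent oxygens, and the twelve default
  motifs each carry a feature absent from the base library, so a motif
  cannot arise by accidental concatenation and planted counts are exact.
* The motifs are pairwise non-matching, so one task's plant never turns
  another task positive.

What passing tests on this generator do **not** show: real compound series
have correlated scaffolds, stereochemistry, tautomers, much larger rings
and charge states, and their labels are not determined by any single
substructure. The generator validates the machinery (parsing, learning,
splitting, evaluation) under a controllable ground truth, not chemical
realism.

# Numerical choices and degenerate inputs

* Probability clamp $10^{-7}$; batch-norm $\varepsilon = 10^{-5}$,
  momentum 0.9; Adam defaults as above.
* Max-pooling ties route the (sub)gradient to the first maximal
  contributor; the forward value is unaffected.
* Zero-variance batch-norm channels map to zero (the $\varepsilon$ guard).
* Single-atom molecules are valid (degree-0 convolution, pooling is the
  identity); a single-atom *batch* in train mode is rejected because batch
  statistics are undefined.
* Malformed SMILES fail fast with the offending string; multi-fragment
  (salt) SMILES stay one graph with several components, and the gather sum
  runs over all atoms regardless of connectivity.
* Compounds are merged by canonical SMILES before label assembly, and a
  compound found in several herbs takes the element-wise union (OR) of
  their label vectors — the maximal-recall reading of herb-level
  inheritance.
* Checkpoints are versioned JSON with 17-significant-digit doubles, which
  round-trip bit-exactly.

# Problem sizes used by the test suite

The packaged tests exercise the full protocol at reduced scale so the suite
stays fast: layer oracles on 200 random graphs of up to 6 nodes; the
planted-motif learning check at $n = 500$, one task at positive fraction
0.1, depth 2, width 64, 60 epochs, 3 seeds; the imbalance comparison at
$n = 1000$, positive fraction 0.02, label noise 0.05, $\gamma \in \{0, 2\}$, 100 epochs,
3 seeds. These sizes are the package's own benchmarking choices; the
reference protocol (depth 3, width 1024, 200 epochs) remains the default of
`fit_config()`. Note that at positive fraction 0.02 with 5% label noise the
flipped negatives outnumber true positives roughly 2.5:1, which caps the
attainable test AUC well below 1 — the imbalance benchmark checks the
*direction* of the focal-loss effect, not its magnitude.

# Known limitations

* No stereochemistry, tautomer handling, or 3D information; featurization
  is a conventional 2D atom encoding. The original work learns features
  from the same kind of 2D graph.
* The substructure matcher compares kekulized bond classes with an
  aromatic-bond class; exotic aromatic systems that kekulize differently
  between query and target could in principle mismatch (irrelevant for the
  built-in motifs, which are matched against molecules parsed by the same
  pipeline).
* CPU-only, pure-R linear algebra: fine at benchmark scale, slow at width
  1024 on tens of thousands of molecules.
* The multi-label stratification guarantee is best-effort under infeasible
  capacity (see above).
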