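---
title: "Hybrid swarm gene selection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid swarm gene selection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Expression matrices from microarray or sequencing studies typically carry
thousands of genes for a few dozen samples. Classifiers trained on the full
matrix are slow, overfit easily, and their decisions are hard to interpret.
Wrapper feature selection attacks this directly: candidate gene subsets are
scored by the cross-validated accuracy of an actual classifier, and a search
procedure looks for the subset that maximizes it. Because the subset lattice
is astronomically large, the search is delegated to a population
metaheuristic; because classifier evaluations are expensive, the gene set is
first reduced by a filter.

This package implements that pipeline with a hybrid of two swarm
optimizers — cuckoo search (CSA) and spider monkey optimization (SMO) — in
which the spider-monkey *local* mechanism is replaced by cuckoo search. SMO
contributes structured global exploration through its group fission–fusion
dynamics; CSA contributes aggressive local refinement through heavy-tailed
Lévy flights. Both standalone optimizers are included as baselines under the
identical encoding, fitness, and termination rules, so any difference in
results is attributable to the hybridization.

## Stage 1: normalization

`normalize_expression()` rescales each gene; the default is min–max to
$[0, 1]$, which matches the optimizer's unit-hypercube position space and
keeps all genes on a common scale for distance-based classification. A
z-score alternative (sample standard deviation, $n-1$ denominator) is
provided. Constant genes map to 0 under both methods.

Normalization is computed **once on the full matrix**, before any
cross-validation split. This leaks a small amount of information from
held-out samples into the per-gene scale factors; with LOOCV on dozens of
samples the effect on accuracy is negligible, but users comparing against
externally validated results should renormalize per fold themselves.

## Stage 2: mRMR prefiltering

The minimum-redundancy maximum-relevance filter ranks genes greedily.
Relevance and redundancy are both plug-in mutual information estimates on
discretized expression values:

$$I(X;Y) = \sum_{x,y} p(x,y)\,\log\frac{p(x,y)}{p(x)\,p(y)}$$

in nats, with the $0 \log 0 := 0$ convention. Choices made here, since filter
variants differ across the literature:

* **Discretization**: 3 quantile bins per gene (near-equal occupancy),
  computed independently of the labels. Quantile binning is the classic
  choice for expression data because it is monotone-invariant; equal-width
  binning is available. Heavily tied genes may collapse to fewer bins;
  constant genes carry zero information by construction.
* **Scheme**: the difference form (MID), score
  $I(g; y) - \overline{I(g; s)}$ over already-selected genes $s$. The
  quotient form (MIQ) is available, with the denominator floored at
  $10^{-12}$.
* **Ties**: every argmax breaks to the lowest gene index, making the ranking
  fully deterministic.
* **Pool size `k`**: default `min(200, n_genes)`. The pool size trades
  search-space dimension against the risk of discarding signal; it is a
  logged, configurable value.

An exact duplicate of a selected gene can never be chosen while an equally
relevant non-redundant gene remains: its redundancy penalty equals its full
self-entropy.

## Stage 3: the hybrid search

### Encoding

A candidate solution is a continuous position in $[0,1]^d$, $d$ the pool
size. A coordinate **strictly greater than** the threshold (default 0.5)
selects its gene. This keeps both the Lévy-flight arithmetic of CSA and the
interpolation updates of SMO applicable without binary transfer functions.
An empty decode is repaired deterministically to the pool's top-ranked gene.
Fitness is cached by decoded mask: two positions selecting the same subset
share one classifier evaluation, and the evaluation counter reflects the
true classifier cost.

### Fitness

The fitness of a mask is the leave-one-out cross-validation accuracy of a
classifier restricted to the selected genes, on the 0–100 scale:

$$\mathrm{Accuracy} = \frac{CC}{N} \times 100$$

with $CC$ the correctly classified count. The identity is exact (integer
arithmetic). The classifier inside the search loop is a deterministic 1-NN:
with a swarm of 50, hundreds of generations, several proposals per member
per generation and $N$ folds per evaluation, a deep network inside the loop
would be computationally indefensible; the convolutional classifier is
applied to the *final* subset instead (Stage 4). Both are selectable.

The 1-NN surrogate is written for bit-reproducibility: distance ties resolve
to the lowest training index, vote ties to the lowest class code.

### Phases

Each generation applies, in order (equations are the standard SMO forms,
with $U(a,b)$ uniform draws taken fresh per dimension):

1. **Local leader phase.** Every member $i$ of group $g$ perturbs each
   dimension $j$ independently with probability $pr$ (perturbation rate):
   $x_{ij} \leftarrow x_{ij} + U(0,1)(LL_{gj} - x_{ij}) +
   U(-1,1)(x_{rj} - x_{ij})$, $r$ a random group-mate. Clipped to $[0,1]$,
   accepted only if strictly fitter (greedy). Singleton groups skip the
   mate term.
2. **Selection probabilities.** $p_i = 0.9\,f_i/\max f + 0.1$ — the floor
   keeps every member active, the best member is selected with certainty.
3. **Global leader phase.** Members selected by $\mathrm{Bernoulli}(p_i)$
   update one uniformly chosen dimension toward the global leader with a
   random-mate term; greedy acceptance. A flag enables all-dimension updates
   for ablation.
4. **Leader learning.** Leaders are replaced only on strict improvement;
   ties and stagnation increment per-group and global counters.
5. **Local leader decision — the hybrid step.** A group whose counter
   exceeds the local leader limit forages by cuckoo search: `n_eggs` rounds
   in which each member proposes an egg
   $x' = x + \alpha\,L_\beta \odot (x - LL)$ with $L_\beta$ a Mantegna Lévy
   step, the egg greedily replaces a uniformly chosen nest, and each round
   ends by re-randomizing non-best nests with probability $p_a$. The same
   mechanism refines the initial local leader at startup, so the hybrid
   benefits from cuckoo search even in short runs. The standalone SMO
   baseline uses the classic random-reinitialization decision instead.
6. **Global leader decision.** Global stagnation splits the swarm into one
   more contiguous near-equal group, up to `max_groups`; at the ceiling the
   groups fuse back into one. Local leaders are re-learned from the new
   groups.

The egg-discovery probability ramps linearly from `pa_min` to `pa_max` over
the run. Termination is the generation cap, plus an early stop when fitness
reaches 100 (accuracy cannot exceed it).

### Control parameters

| Parameter | Default | Meaning |
|---|---|---|
| `swarm_size` / `n_nests` | 50 | one population shared by both mechanisms |
| `n_eggs` | 10 | cuckoo rounds per local-search invocation |
| `n_generations` | 200 | generation cap |
| `pa_min`, `pa_max` | 0.3, 0.5 | abandonment schedule endpoints |
| `alpha_step` | 1 | Lévy step scale |
| `max_groups` | 5 | fission ceiling |
| `global_leader_limit` | 50 | global stagnation threshold |
| `local_leader_limit` | 1500 | local stagnation threshold |
| `n_runs` | 100 | repeats for multi-run statistics |
| `pr` | 0.3 | perturbation rate (standard SMO practice) |
| `levy_beta` | 1.5 | Lévy stability index (standard CSA practice) |
| `binarize_threshold` | 0.5 | position-to-mask decode |

With the default limits the local decision rarely fires inside a 200-
generation run — the counters increment once per generation — so the cuckoo
contribution enters mainly through the initial local-leader refinement; the
limits are configurable for studies of the decision dynamics.

Reproducibility: each run consumes a single seeded RNG stream in a fixed
documented order (initialization → initial cuckoo refinement → per-generation
phases), so identical configuration and seed give byte-identical results
with the deterministic surrogate. Multi-run experiments use sequential seed
offsets.

## Stage 4: the convolutional classifier

The final classifier is a compact convolutional network implemented in
vectorized base R (im2col convolutions; gradients verified against finite
differences in the test suite):

* the selected gene vector is laid out row-major on a
  $\lceil\sqrt d\rceil \times \lceil\sqrt d\rceil$ single-channel grid,
  zero-padded at the tail;
* six blocks of 2×2 convolutions at stride 1 with 8, 16, 32, 64, 128, 256
  filters, each followed by batch normalization and ReLU, with 2×2 stride-2
  max pooling after every block except the last (pooling and convolution
  are skipped/padded when a spatial dimension falls below 2);
* flatten → dense → softmax head.

Training choices (standard, since no canonical values exist for this
setting): cross-entropy loss, Adam at learning rate $10^{-3}$, mini-batches
of `min(16, n_train)`, 50 epochs, stratified 80/20 holdout with a seeded
shuffle, no augmentation. Batch-norm keeps running moment estimates
(momentum 0.9) for evaluation mode. Per-epoch train/test accuracy and loss
curves are returned for inspection. The CNN is intended to classify the
*selected subset*: on a handful to a few dozen genes the network is small
enough to train on a CPU in seconds, and that is the configuration the
package's own validation exercises.

## The synthetic generator

`generate_synthetic_dataset()` emulates the structure wrapper selectors
exploit, with known ground truth:

* class $c$ shifts each **informative** gene's mean by
  $c \cdot \mathrm{effect} \cdot \sigma$ (a monotone ladder, valid for any
  class count);
* each **redundant** gene is its parent plus Gaussian noise with
  $\tau^2 = \mathrm{Var}(\mathrm{parent})(1-\rho^2)/\rho^2$, computed from
  the parent's realized variance so the parent–copy correlation converges
  to the requested $\rho$ (verified at $n = 5000$ within $\pm 0.05$);
* **noise** genes are label-independent Gaussians;
* class counts follow the requested proportions exactly
  (largest-remainder rounding, every class at least once) and are shuffled
  across samples — multi-run statistics then compare search variability,
  not label-draw variability.

What it does **not** emulate: probe-level noise models, platform/batch
effects, heavy-tailed or count-valued expression, gene–gene correlation
beyond the planted copies, class-conditional covariance. Passing the
planted-recovery tests therefore demonstrates that the machinery finds
strong mean-shift signal among independent noise — not performance on real
microarray data.

## The bundled recovery benchmark

`run_recovery_benchmark()` fixes the package's validation conditions:
60 samples × 500 genes, 5 informative genes at effect 2 with 4 redundant
copies each ($\rho = 0.8$), min–max normalization, mRMR pool of 50, swarm of
20 for 30 generations with 1-NN LOOCV fitness. At this scale the full-size
leader limits could never trigger inside a run, so they are scaled to
engage within 30 generations (global 8, local 15) — chosen once, as part of
the benchmark definition. Recovery is scored by
`planted_recovery_score()`: an informative gene counts as found if it *or
any of its correlated copies* is selected, since the copies carry the same
signal. The test suite requires a hit fraction of at least 0.8 together
with LOOCV accuracy of at least 95 in eight of ten seeds, and that the
hybrid's mean best fitness is not dominated by either standalone baseline;
`scripts/acceptance.R` recomputes the same quantities from scratch.

## Numerical conventions and degenerate inputs

* Positions are clipped to $[0,1]$ after every update; the property tests
  drive random phase sequences and assert bounds, group-partition and
  elitism invariants throughout.
* Greedy acceptance everywhere is *strict*; ties keep the incumbent. This
  makes traces non-decreasing and drives the stagnation counters.
* An empty mask decode is repaired to the top mRMR gene; fitness functions
  reject empty masks outright.
* A constant gene discretizes to a single code and contributes zero
  information; a constant fitness landscape leaves all leaders unchanged.
* The plug-in MI is clamped at 0 against floating-point underflow; the
  selection-probability rule computes the fitness ratio before scaling so
  the best member's probability is exactly 1.

## Limitations

* Wrapper selection with LOOCV-1-NN fitness optimizes an estimate with
  high variance at small $N$; reported accuracies for small studies are
  optimistic by selection. Use the multi-run summaries, not single runs.
* Whole-matrix normalization (above) is a deliberate leakage trade-off.
* The mutual-information estimator is the plug-in on 3 bins; continuous
  estimators are out of scope.
* The CNN is a CPU-scale implementation for final evaluation at subset
  scale, not a general deep-learning framework: single channel, 2×2
  kernels, no padding options, no GPU.
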