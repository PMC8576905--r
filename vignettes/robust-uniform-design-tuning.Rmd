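---
title: "Robust hyperparameter tuning of residual image classifiers by uniform experimental design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust hyperparameter tuning of residual image classifiers by uniform experimental design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uedtune)
```

## The problem

Tuning a convolutional classifier means choosing among hundreds of
hyperparameter combinations, each of which is expensive to evaluate, and a
combination that happens to score well once may do so by luck of the data
split. `uedtune` implements a *robust parameter design* answer to both
problems at once:

1. **Uniform experimental design (UED)** probes a six-factor hyperparameter
   space — kernel count $X_1 \in \{8, 16\}$, kernel size
   $X_2 \in \{3, 5\}$, pooling size $X_3 \in \{4, 8, 16, 32\}$, weighted
   depth $X_4 \in \{14, 20\}$, activation
   $X_5 \in \{\mathrm{Tanh}, \mathrm{SELU}, \mathrm{LeakyReLU},
   \mathrm{ReLU}\}$ and optimizer $X_6 \in \{\mathrm{SGD},
   \mathrm{Adam}\}$ — with only 12 runs instead of the full
   $2\cdot2\cdot4\cdot2\cdot4\cdot2 = 256$ grid, by scattering the runs as
   uniformly as possible over the space.
2. **Taguchi's nominal-the-best signal-to-noise ratio** scores each
   combination over $p$ replicate trainings with *re-randomized data
   groupings*,
   $$\mathrm{SNR}_i = -10 \log_{10}\!\left[(\bar t_i - m)^2 +
   \sigma_i^2\right],$$
   with target $m = 1$ (perfect accuracy), replicate mean $\bar t_i$ and
   sample standard deviation $\sigma_i$. A high SNR demands accuracy that
   is simultaneously *high* and *stable* under replication noise. Training
   and validation SNRs are summed per combination and the largest sum wins.

The motivating application is four-class retinal optical coherence
tomography (OCT) classification — choroidal neovascularization (CNV),
diabetic macular edema (DME), drusen deposits, and normal scans — and the
package ships the published result tables of that reference experiment
(`reference_experiment()`) together with its exact 12-run mixed-level
layout (`reference_design()`), so every printed statistic can be
recomputed.

## Uniform layouts: construction and scoring

`good_lattice_layout(n, s)` constructs $U_n(n^s)$ tables by the
good-lattice-point method: column $j$ is $u_{ij} = (i \cdot h_j) \bmod N$
with generator $h_j$ coprime to the lattice modulus $N$, which makes every
column a permutation of $1..n$. For even $n$ the modulus is $N = n + 1$:
the odd lattice's final row is constant at $n+1$ in every column and is
deleted, leaving permutations of $1..n$.

Which $s$ of the $\varphi(N)$ candidate columns to keep is decided by
**centered $L_2$ discrepancy** (Hickernell's closed form, on levels mapped
to the unit cube via $(\ell - 0.5)/m$): lower discrepancy means a more
uniform scatter. The search is exhaustive up to 2\,000 candidate subsets
and greedy forward selection beyond, with ties always broken toward the
lowest generator index — the construction is deterministic at any scale.
The closed form is verified in the test suite against direct numeric
integration of the defining corner-anchored box-discrepancy integral
(including all coordinate projections), to $10^{-6}$.

Mixed-level tables like the reference design come from **pseudo-level
collapsing** (`collapse_levels`): level $\ell$ of $n$ maps to
$\lceil \ell m / n \rceil$ of $m$, which is balanced whenever $m \mid n$.
The canonical 12-run design is shipped verbatim as a fixture rather than
re-derived, because the generating vector behind the published table is
not recoverable from the published material; the general constructor is
provided alongside and is not required to reproduce it cell-for-cell.

```{r design}
reference_design()
```

## The parametric residual network

`build_resnet()` maps a design row to a concrete architecture:

* a stem convolution ($X_1$ kernels of size $X_2$, stride 2, same padding)
  followed by a fixed $2 \times 2$ average pooling — input images
  (resized to $64 \times 64$ grayscale by default) reach the residual
  trunk at quarter resolution;
* $B = (X_4 - 2)/2$ identity residual blocks of two same-shape
  convolutions, so skip connections add tensors of identical shape and the
  weighted-layer count is exactly $1 + 2B + 1 = X_4$ (6 blocks for depth
  14, 9 for depth 20);
* one average-pooling stage with window $X_3$ (clipped, with a warning, to
  the feature-map size when it exceeds it — at $64 \times 64$ input the
  trunk runs at $16 \times 16$, so $X_3 = 32$ clips to 16);
* a dense softmax output layer trained with categorical cross-entropy.

The trunk places all residual blocks at one resolution because identity
(projection-free) skips require equal shapes; the single stem downsampling
stage is the package's own choice of downsampling schedule, made so that
desk-scale experiments stay tractable while every factor still changes the
computation it is supposed to change. Fixed training constants follow the
reference study: shared learning rate $\eta = 0.001$; Adam
$\epsilon = 10^{-8}$ (reading the published "e−8" as the standard Adam
epsilon); SELU scale 1.050 and $\alpha$ 1.6732 (the standard SELU
parameterization); LeakyReLU slope $\lambda = 0.03$. SGD is plain
stochastic gradient descent without momentum or weight decay, sharing
$\eta$, since nothing beyond $\eta$ is specified for it; Adam's moment
decays use the conventional $\beta_1 = 0.9$, $\beta_2 = 0.999$. Training
epochs (default 10) and batch size (default 32) are declared in
`training_protocol()` and recorded in every result. Weight
initialization is gaussian and activation-matched — He variance
$2/\mathrm{fan}_{in}$ for the rectifiers, LeCun variance
$1/\mathrm{fan}_{in}$ for SELU and Tanh — with each block's second
convolution scaled by 0.1 so residual blocks start near the identity;
without normalization layers this keeps the deep trunks numerically
stable for every activation/optimizer cell of the design. Gradients are
clipped at global $L_2$ norm 5 and a batch with non-finite loss is
skipped without an update, so no single degenerate step can destroy a
replicate. All randomness — initialization, epoch shuffling, data
groupings — derives from the protocol seed, so a run is bit-reproducible
on one platform. The implementation expresses convolutions as
im2col/col2im plus BLAS matrix products (compiled gather/scatter kernels,
R-side GEMM) and runs on a single CPU.

## The experiment loop

`run_uniform_experiment()` realizes each design row
(`realize(design, default_space())`), then for every combination draws $p$
fresh **stratified train/validation groupings** (default 80/20, redrawn
with seed `base_seed + (i-1)p + j` for combination $i$, replicate $j$) and
trains one model per grouping. The published protocol replicates each
combination three times with re-randomized groupings; neither the split
fraction nor stratification is stated there, so the 80/20 stratified
split is the package's explicit, logged default. Per combination the
table records replicate accuracies, mean, standard deviation, train and
validation SNR, and their sum; `select_best()` takes the summed-SNR
argmax with ties to the lowest index and $+\infty$ (zero error, zero
spread) dominating. `evaluate_on_test()` retrains the winner $p$ times on
fresh groupings and reports test accuracy and macro false negative rate
per replicate, mirroring the published test table.

A trainer is just a function
`function(config, train_set, val_set, protocol, info)`; the experiment
loop is exercised in the tests with `accuracy_stub_trainer()`, which
replays the published accuracy tables without any training, keeping the
SNR/selection pipeline verifiable in milliseconds.

## The synthetic data generator

`generate_oct_like()` emulates the *structure* of the four-class OCT task
— not speckle physics. Every image is a pair of bright horizontal retinal
bands over a dark background; DRUSEN adds one-signed low-frequency
sinusoidal bumps that push the upper band boundary downward, DME punches
dark elliptical voids into the band, CNV adds a bright sub-band blob, and
NORMAL is bands only. Class structure scales with `separation` (default
0.8), and multiplicative Gaussian speckle of amplitude `noise_level`
(default 0.1) is applied before a per-image affine rescale onto $[0,1]$
(display normalization). At the default conditions (100 images per class,
$64 \times 64$) a nearest-centroid classifier on raw pixels exceeds 0.9
accuracy, so the classes carry genuinely learnable signal, and accuracy
under that oracle decays as `noise_level` grows — both properties are
asserted in the test suite. `mimic_reference_counts(scale)` reproduces
the reference study's class imbalance (37205/11348/8616/26315 modeling
images, 242 per class for testing) at any scale.

What passing tests on this generator shows is that the *framework* —
design construction, replicate SNR scoring, selection, reporting —
behaves correctly end to end on a learnable four-class image task. It
deliberately shows nothing about clinical OCT performance: real B-scans
have speckle statistics, anatomical variability and label noise the
generator does not attempt.

## Numerical and reporting choices

* **SNR logarithm** is base 10; recomputing all twelve published SNRs
  from their printed means and standard deviations confirms the base.
* **Replicate variance** uses squared deviations with divisor $p - 1$
  (the published variance formula omits the square typographically; the
  printed standard deviations match the squared-deviation sample
  formula).
* **False negative rate** is the macro-averaged per-class miss rate,
  $\frac{1}{q}\sum_i (1 - T_{ii}/\sum_j T_{ij})$; with a balanced test
  set this equals $1 - \mathrm{ACC}$. The reference tables print FNR/ACC
  pairs differing from that identity by $\sim 10^{-4}$, so arithmetic
  checks on FNR are held to printed precision rather than exactness.
* **Report rounding** is half-up: accuracies and means to 4 decimals,
  standard deviations to 6, SNRs to 2 — matching the published tables'
  style. Recomputations from printed (already-rounded) inputs are checked
  to one unit in the last printed digit, since the published tables were
  themselves computed from unrounded accuracies.
* **Degenerate inputs**: a zero SNR argument returns $+\infty$ and
  dominates selection; empty tables, empty splits, classes missing from a
  training split, non-divisor collapsing targets and over-capacity factor
  requests all raise immediate, named errors.

## Problem sizes

The package's own validation runs at desk scale: the full replicated
experiment (12 combinations × 3 replicates) uses 100 synthetic images per
class at $64 \times 64$ and 3 epochs, chosen so the whole uniform
experiment — 36 residual-network trainings — completes in minutes on one
CPU core while still exercising every architecture the design realizes.
Unit tests use smaller sets (down to $16\times16$, a handful of images)
wherever only plumbing, not learning, is under test.

## Limitations

* Accuracy levels reached on the synthetic task at desk scale are not
  comparable to the reference study's full-scale results on 83k real
  images; the package reproduces the published *arithmetic* exactly and
  validates the *framework* behaviorally.
* The good-lattice constructor is not guaranteed (and not required) to
  reproduce the shipped canonical design, whose generating vector is
  unpublished.
* The published prose mentions a regression analysis over the design; no
  regression results are published, and none is implemented.
* Bit-reproducibility holds per platform (BLAS and compiler specifics can
  change floating-point results across machines); all seeds are recorded
  in run manifests.
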