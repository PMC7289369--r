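---
title: "Evolutionary optimization of shallow motor-imagery classifiers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary optimization of shallow motor-imagery classifiers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evobci)
```

## The problem

Motor-imagery (MI) brain-computer interfaces classify which limb movement a
subject imagined from their EEG. The signal is weak and the data regime is
hostile: a session yields a few hundred trials, while even a modest feature
construction produces thousands of dimensions. `evobci` implements a complete
pipeline for this regime built around genetic algorithms (GAs): wavelet-variance
pattern construction, GA wrapper feature selection, a two-step GA search over
the hyperparameters of three deliberately shallow neural classifiers, and a
statistical suite for comparing the resulting models.

## Pattern construction

Each electrode's trial signal is cut into `S` consecutive, partially
overlapping segments; each segment is decomposed with an `L`-level discrete
wavelet transform; and each coefficient set (approximation and detail at every
level) is summarized by its within-set variance. A trial with `E` electrodes
becomes a fixed vector of `2 * S * E * L` variance features.

The defaults encode a concrete geometry: `S = 20` segments of 256 samples
(one second at 256 Hz) stepped by 40 samples — requiring trials of
`256 + 19 * 40 = 1016` samples — with `L = 6` levels over `E = 15` electrodes.
This yields 3,600 coefficient sets (151,200 raw coefficients) per trial and a
3,600-dimensional pattern. Coefficient sets shrink by powers of two
(128, 64, 32, 16, 8, 4 coefficients); by convention the size-128 sets carry
level label 6 and the size-4 sets label 1, and the package stores this mapping
explicitly to avoid off-by-one drift between decomposition depth and level
label.

Design choices a user may care about:

* **Segment geometry.** Segment length and overlap are configurable
  (`mra_config()`); the defaults are the unique small-integer geometry that
  reproduces the printed set sizes with 20 overlapping one-second segments.
* **Wavelet and boundary.** The decomposition uses periodized (circular)
  filtering so set sizes halve exactly. Default filter is the 4-tap Daubechies
  (`daub4`); `haar` and `daub8` are available. The transform is implemented in
  the package (a periodized analysis pyramid is a few lines of filtering) and
  is verified in the test suite against reference coefficients from an
  independent implementation, frozen into the tests.
* **Variance.** Sample variance (denominator `n - 1`); a singleton set would
  be assigned variance 0, though the default geometry never produces one.
* **Normalization.** Per-feature min-max scaling to [0, 1] is fitted on the
  training split only and applied to test data with clipping. Fitting on all
  data would leak test information into the scaling; clipping keeps shifted
  test values inside the unit interval. Constant training columns map to 0.

## The GA engine

All three searches share one engine (`evolve()`): binary tournament selection,
generational offspring production (`population_size` offspring per
generation), crossover with probability 0.9 and mutation with probability 0.1
per offspring (both configurable), and elitist replacement — parents and
offspring are pooled, ranked by fitness and truncated. Fitness is always
stratified k-fold cross-validated accuracy (k = 5 by default).

Two details deserve justification:

* **Fitness caching.** Training a network is stochastic (weight
  initialization, batch order), which would break the elitism invariant that
  the best recorded fitness never decreases. Each distinct genome is therefore
  evaluated exactly once, with an evaluation seed derived deterministically
  from the run seed and the genome itself; the cached value is reused ever
  after. This makes recorded fitness a deterministic function of (seed,
  genome) and the whole run reproducible bit for bit.
* **Offspring count.** The replacement scheme is generational with elitist
  merge-truncate. A steady-state variant (few offspring per generation) fits
  the same engine but is not exposed; the generational choice keeps the
  generation count interpretable as a fixed evaluation budget.

## Feature selection

Feature subsets are binary masks over all features (1 = active). Uniform
crossover passes every bit the parents share and randomizes the rest; bit-flip
mutation inverts one position; and a repair step enforces the constraint that
at most `max_active` features (default 30) are active — surplus active bits
are cleared uniformly at random, and an all-zero mask gets one bit set, since
an empty subset is untrainable. Initial masks draw their active count
uniformly from `[1, max_active]`: initializing anywhere up to the full feature
count would contradict the constraint, so the initialization range is clamped
to the feasible region.

The wrapped classifier defaults to ridge-regularized multinomial logistic
regression (via `glmnet`), a light model that affords thousands of fitness
evaluations; the factory is pluggable. The reference configuration is a
population of 1,000 for 100 generations; the test battery uses much smaller
populations, which already recover planted informative features reliably.

## The three classifier families

All models end in a softmax layer trained by plain stochastic gradient
descent on the multiclass cross-entropy, in shuffled minibatches (default
size 16) at a fixed learning rate, with fan-in-scaled uniform weight
initialization. Backpropagation, including the convolution and the GRU
recurrence, is implemented in the package and verified against numerical
gradients in the tests.

* **FFNN** — one or two dense hidden layers, ELU activation by default
  (rectifiers tend to stall on these small, min-max-scaled inputs), optional
  dropout on hidden activations (inverted dropout, so inference needs no
  rescaling).
* **CNN** — a single valid-mode one-dimensional convolutional layer
  (`n_filters` filters of odd length up to 19, ReLU), flattened directly into
  the output layer. Valid mode discards borders, so a width-`d` input gives
  per-filter maps of length `d - filter_size + 1`. Stride is 1; no pooling
  layer enters the search space (pooling is a described layer type but the
  optimized architecture fixes a single convolutional hidden layer).
* **GRU-RNN** — one recurrent layer of at most 60 gated recurrent units
  reading the feature vector as a univariate sequence (one feature value per
  time step), followed by the configured activation on the final hidden state
  and the softmax head. The candidate-state recurrence applies the recurrent
  bias inside the recurrent product, `tanh(W_h x + U_h (r * h + b_h))`,
  matching the gating equations this implementation follows. Treating the
  feature vector as a sequence is itself a modeling decision; segment-major
  chunking is possible by reordering columns, which the feature names make
  deterministic.

Divergence under an aggressive learning rate raises an error in direct
training (`train_model()`), but inside a GA fitness evaluation a diverged
candidate is simply assigned fitness 0 — a worthless model, not a failed run.

## Two-step hyperparameter optimization

The joint space of structure and learning hyperparameters is split:

1. **Structure step.** Genes are `(n_filters, filter_size)` for the CNN, the
   hidden widths (variable length 1-2) for the FFNN, and the unit count for
   the RNN. Initial genes are drawn from a normal centered at mid-range with
   SD = range/6 (so ±3 SD spans the range), rounded and clamped; filter sizes
   are forced odd. FFNN widths are uncapped in the search but initialized
   with a cap of 200 (an unbounded range has no mid-point). Every candidate
   is trained with fixed baseline learning parameters — 60 epochs at learning
   rate 0.1, the package's unoptimized reference setting.
2. **Learning step.** The best structure is frozen; genes are
   `(learning_rate, epochs)` plus `dropout_rate` for the FFNN (bounds
   (0, 1], 1..200, [0, 0.9]). Crossover is single-point; mutation multiplies
   one gene by a `Normal(1, sigma)` draw (`sigma = 0.1` by default). For the
   FFNN, mutation chooses uniformly between the generic Gaussian move and a
   dropout-specific one. A dropout gene equal to exactly 0 cannot move under
   a multiplicative scheme, so its mutation falls back to a small additive
   perturbation.

Operator-specific decisions: the RNN's structure genome has length 1, making
single-point crossover degenerate — it returns a copy of a uniformly chosen
parent. The FFNN midpoint crossover takes the first half of one parent's
widths and the last half of the other's, truncated to depth 2.

**Incumbent seeding.** Each step's initial population includes one incumbent:
the step-2 population contains the step-1 training parameters, and the
step-1 population can be seeded with a reference structure. With elitist
replacement this makes each step an *improvement operator* in
cross-validated fitness: as measured under that step's own evaluation seeds,
it can never return a configuration scoring below its starting point — the
well-posed reading of "the optimization procedure improves on the default".
(Across steps the measurement seeds differ, so the two steps' reported
fitness values are not directly comparable to each other.) Without it, a small search
whose random initial learning-rate draws all diverge could return a
configuration worse than the baseline.

## Evaluation

Final models are scored by Cohen's Kappa, `(p0 - pc) / (1 - pc)`, with the
chance term `pc` computed by the standard marginal-product convention (the
row and column marginal proportions multiplied per class and summed).
Because training is stochastic, experiments are repeated (15 runs by
default, consecutive seeds) and reported as mean ± SD and best. The
train/test split for synthetic experiments is stratified 70/30.

## Statistical comparison

`compare_methods()` implements an omnibus-gated comparison over a matrix of
per-run Kappa values (observations × methods):

* **Friedman test** on within-observation ranks, with average ranks on ties
  and the tie-corrected statistic; a matrix whose rows are all fully tied
  returns statistic 0 and p = 1 rather than erroring.
* **Wilcoxon signed-rank post-hocs** (only when the omnibus rejects at 0.05),
  two-sided, zeros dropped, average ranks on ties. For n ≤ 25 the p-value is
  exact, computed by convolving the (possibly half-integer) ranks — valid
  under ties, unlike the textbook no-ties recursion; beyond that a normal
  approximation with continuity and tie correction is used. Holm's step-down
  correction controls the family-wise error rate.
* **Bayesian signed-rank with a rope.** Paired differences are counted into
  left / rope / right bins; a Dirichlet posterior is built from the counts
  with one prior pseudocount in the rope and sampled (2,000 triplets by
  default). This count-based formulation is deliberately the simple one: the
  prior pseudocount sits in the rope because practical equivalence is the
  natural skeptical prior and because it prevents degenerate zero-count
  posteriors. Reported probabilities are the fractions of sampled triplets in
  which each coordinate is the maximum (ties split), the convention used for
  simplex heatmaps; the posterior-mean triplet is also returned. The rope
  defaults to ±0.01 on the Kappa scale — a Kappa difference below one
  percentage point of chance-corrected accuracy is rarely of practical
  interest — and every report prints the rope used. Triplets map to an
  equilateral triangle via barycentric coordinates (left vertex = first
  method better, right = second better, top = practical equivalence) for the
  heatmap plot.

## Synthetic data: what it emulates and what it does not

`generate_mi_trials()` emulates the statistical signature the pipeline
assumes: 1/f-colored background noise (spectral shaping of white noise,
exponent 1 by default) plus a band-limited mu-band (8-12 Hz) oscillation on
every electrode, with the oscillation attenuated by a factor `1 - erd_depth`
on class-specific electrode groups during the middle half of the trial —
an event-related desynchronization. Defaults mirror the target recording
setup: 15 electrodes, 256 Hz, 3 balanced classes, 1,016-sample trials. With
`erd_depth = 0` the classes are statistically identical and downstream
accuracy must sit at chance; at `erd_depth = 0.8` the wavelet-variance
features are clearly learnable.

`generate_feature_patterns()` plants class-separable columns directly in a
log-normal (variance-like) feature matrix, min-max normalized to [0, 1]:
`n_informative` columns receive class-dependent mean shifts of `effect_size`
pooled-SD units. `make_benchmark_suite()` freezes three fixtures used by the
test battery, all 178 patterns × 3 balanced classes:

* `null` — no informative columns (chance-level control);
* `strong` — 10 informative of 200 at effect size 0.7. The effect size was
  calibrated so that the default network configuration scores well above
  chance yet clearly below its achievable ceiling (mean Kappa around 0.55 to
  0.6 for the reference FFNN) — the regime the optimization procedure is
  designed for. An easier setting saturates the default and leaves
  hyperparameter search nothing to improve, which would test the fixture
  rather than the method;
* `planted` — 5 informative of 200 at effect size 2, the feature-selection
  recovery target.

None of this reproduces volume conduction, recording artifacts, electrode
correlation structure, or between-subject variability. Passing tests on these
fixtures demonstrates that the algorithms do what they claim on data with the
assumed structure — not that any particular accuracy will be reached on real
recordings.

## Scaled-down experiment sizes

The reference GA configurations (feature selection 1000 × 100; optimization
40 × 10 per step; 15 evaluation repetitions) are what a full study would run.
The package's own test battery and the bundled acceptance script use reduced
sizes chosen as the smallest runs that still exercise the full machinery end
to end: feature-selection recovery at population 100 for 30 generations on
the 200-feature planted fixture; the two-step search at population 10 for 4
generations per step; 5 evaluation repetitions. These sizes are the package's
default demonstration scale; all of them are parameters, not constants.

## Known limitations

* Plain SGD only — no momentum or adaptive optimizers; very aggressive
  learning rates diverge rather than being rescued by gradient clipping.
* The GRU processes one scalar per time step; long feature vectors make
  recurrent training slow in pure R, so RNN experiments are best run on
  selected feature subsets (which is also the configuration of scientific
  interest here).
* Cross-validated fitness is evaluated once per genome; with small data the
  winner's-curse bias of the best CV score relative to true generalization is
  non-negligible, and improvements in CV fitness need not transfer
  monotonically to a held-out test set. The incumbent-seeding guarantee is
  therefore stated in CV fitness, not test Kappa.
* The Bayesian test is the count-based Dirichlet formulation, not the full
  Dirichlet-process signed-rank test; with few paired observations the rope
  pseudocount visibly shapes the posterior.
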