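---
title: "Pathway-sparsified neural networks for exome-based case-control prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-sparsified neural networks for exome-based case-control prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Whole-exome case-control cohorts are heavily underdetermined: each sample
carries tens of thousands of variants drawn from a pool of millions, while
cohorts rarely exceed a few thousand samples (p >> n). Additive models
(penalized logistic regression on individual variants, polygenic scores)
have historically dominated because their high bias is protective at such
n/p ratios — not necessarily because the underlying biology is additive.
`pathnn` implements a family of deliberately small neural networks whose
expressivity is graded, so that the *kind* of gene-gene interaction
(epistasis) a model can represent is an explicit architectural property,
and provides the simulation and evaluation machinery to study when each
level of expressivity pays off.

## Gene-centric encoding

Variants are assumed pre-annotated with a gene assignment and an
Annovar-style functional class. For each sample and gene we count variants
per class, giving a C-dimensional *mutational load* histogram per gene
(`encode_gene_centric()`); a cohort is an `n x |G| x C` tensor. The shipped
default vocabulary has C = 16 classes: the published class list enumerates
17 names, and the 16-dimensional histogram is obtained here by merging the
two rare stop/start-altering classes (`stoploss`, `startloss`) into one —
which two classes were originally collapsed is not documented, so the full
17-name vocabulary is also available (`annovar_classes(17)`) and the
vocabulary is fully configurable.

Counts of each class are z-scored, pooling mean and sd per functional class
across all genes and training samples ("across all genes" taken literally;
a per-(gene, class) mode exists behind `per_gene = TRUE` but produces many
degenerate zero-variance cells at realistic sparsity). Standardization
statistics are always fit on training folds only and applied to test folds;
the evaluation harness enforces this automatically.

## Architectures

A single shared *gene module* (default: 16 inputs, one hidden layer of 50
tanh units, scalar linear output; 850 weights + 51 biases) maps every gene's
histogram to a scalar gene activation G_i, decoupling parameter count from
the number of genes. Heads of increasing expressivity connect the gene
neurons to the sigmoid output:

* `logreg` — gene neurons wired directly to the output: a logistic
  regression on gene activations. No between-gene interaction is possible;
  the model is additive across genes (though nonlinear within a gene).
* `biosparse` — a sparse gene-pathway hidden layer with *exactly one*
  outgoing connection per gene. Two genes can interact in at most one tanh
  neuron: enough for magnitude (positive/negative) epistasis, where a
  saturating monotone response bends the joint effect away from the sum of
  marginal effects, but structurally unable to represent non-monotone joint
  effects.
* `dense` — a fully connected hidden layer; with enough units this can
  compose activations and represent any interaction, including reciprocal
  sign epistasis (the XOR pattern: each variant deleterious alone,
  protective together, or vice versa).
* `linear` — wired like `biosparse` with every activation replaced by the
  identity: an end-to-end affine control that isolates what the gene-centric
  encoding contributes without nonlinearity.
* `multiconnect` — keeps all gene-pathway memberships (degree > 1).
* `stacked_interactome` — a sparse gene-gene interaction layer (from an
  edge list; genes without any edge are given a self-edge so no gene is
  discarded) feeding a sparse gene-pathway layer.

The gene-module activation is not prescribed anywhere authoritative; tanh
is used for its hidden layer (matching the pathway layer) while the gene
output neuron is linear. The linear output matters: a saturating gene
output compresses exactly the high-burden tail that a downstream pathway
neuron must threshold to detect joint-burden (AND-like) epistasis, and in
development that compression made a quarter of sparse-head training runs
stall in a flat region of the loss. Masked-out connections are structurally absent: their weights are
pinned to zero, gradients are masked, and `count_parameters()` counts only
the mask's support. Initialization is fan-in-scaled uniform (per-column
masked fan-in for sparse layers); larger (Glorot-style) scales were tested
during development and saturate the tanh units on standardized count data,
slowing optimization.

## Sparsity masks

Four ways to wire the gene-pathway layer (`sparsity` builders), all
comparable at a fixed connection budget:

* `knowledge_mask()` — one membership pathway per gene, picked uniformly at
  random (seeded); genes without any membership share a single *dummy*
  pathway neuron, so no gene is discarded.
* `random_mask()` — a uniformly chosen fraction of genes, each wired to one
  uniformly chosen hidden neuron; unselected genes are structurally dropped.
* `l1_learned_mask()` — trains a dense layer under a heavy L1 penalty and
  keeps the largest-magnitude connections, capped at one per gene so the
  result is budget-comparable with the degree-1 arrangements. (Whether the
  original comparison enforced the per-gene cap or only the total budget is
  not stated; the cap is this package's choice.)
* `rigl_train()` — dynamic sparse training: at a fixed interval the
  lowest-magnitude active connections are dropped and the same number of
  inactive positions with the largest loss-gradient magnitude are grown, so
  the budget is invariant throughout. The schedule follows the original
  recipe (cosine-annealed drop fraction, default initial 0.3, update every
  100 steps, mask frozen at 75% of training); ties are broken by (gene,
  hidden) index order for determinism.

## Training

A weighted focal binary cross-entropy,
`-w_y (1 - p_t)^gamma log(p_t)` with `w_1 = alpha`, `w_0 = 1 - alpha`,
addresses class imbalance; `alpha` defaults to the control fraction of the
training labels (`focal_alpha_from_counts()`; 480/(480+3318) = 0.12638 for
the motivating cohort, which down-weights the majority cases), and
`gamma = 2`. Optimization is Adam (lr 0.001, batch 128) over seeded
shuffled mini-batches, with optional weight decay and dropout (placed after
the gene-neuron layer and after the hidden layer; exact placement is not
documented upstream and is this package's choice). Probabilities are
clamped 1e-7 from the boundaries. Epoch budgets default per architecture
within 20-75; heads in which each gene has a single path to the output
(logreg, biosparse) converge slowest and get the largest defaults. No early
stopping is used.

The compiled core computes in single precision — the standard working
precision of neural-network frameworks — with the tanh evaluated from a
cubic-Hermite table accurate to ~1e-9. Training is bit-reproducible for a
fixed `(seed, data)` on the same platform; the pure-R forward pass (double
precision) agrees with the compiled one to ~1e-6 and serves as a
cross-check in the test suite.

## Evaluation

`repeated_stratified_cv()` implements the reference protocol: 10
repetitions of stratified 3-fold CV (k is a parameter; the 10-fold variant
needs no separate code path), with standardization refit per training fold
and splits that are a deterministic function of `(y, k, reps, base_seed)` —
hence identical across model factories. `roc_auc()` is the rank
(Mann-Whitney) construction with ties counted 1/2. Model comparisons use
the variance-corrected resampled t-test: on the reps x k paired AUC
differences, `t = mean(d) / sqrt((1/m + n_test/n_train) var(d))` with
`m = reps*k` and a t null with m-1 degrees of freedom; the `n_test/n_train`
inflation (1/2 for 3-fold) accounts for the overlap of training sets across
folds, and under label-permutation nulls the test is conservative (the
acceptance suite verifies a rejection rate at or below nominal).
`learning_curve()` evaluates nested stratified subsets (nesting reduces
variance across fractions; whether the original subsets were nested is not
stated).

## The simulator

`simulate_cohort()` generates cohorts in which the ground truth is known
and every architectural claim is testable:

* counts per (sample, gene, class) are Poisson (rate 0.1 per class by
  default; a negative-binomial switch models overdispersion but Poisson is
  the tested default);
* gene burdens are class-summed counts (unit weights by default), centered
  and scaled by their theoretical moments;
* liability = additive terms `beta * z_g` + magnitude-epistasis terms
  `effect * tanh(kappa (z_i + z_j -/+ shift))` + reciprocal-sign terms
  `effect * XOR(b_i > tau, b_j > tau)` + Gaussian noise;
* labels threshold the realized liability at the quantile matching the
  prevalence target (default 3318/3798, the composition of the motivating
  cohort).

The magnitude-epistasis term is a *ridge* interaction — a tanh of the
summed centered burdens — rather than a transformed product: a ridge
through a saturating monotone function is exactly the function class a
single tanh pathway neuron fed by the two genes can represent, so
detectability tests probe architecture expressivity rather than
misspecification. The shift places the operating point in the convex
(positive, super-additive) or concave (negative, sub-additive) region. The
XOR term with a threshold away from the burden median has asymmetric
indicator prevalences and therefore nonzero marginal effects — the
realistic case; a threshold at the median gives the pure, marginal-free
XOR, which no model learns from 200-gene data at this sample size.

`bayes_score()` returns the noiseless liability, the performance ceiling;
the suite checks that trained networks never beat it by more than sampling
noise. What the simulator deliberately does **not** model: linkage and
haplotype structure, population stratification, variant-level effect
heterogeneity within a (gene, class) bucket, batch effects. Consequently a
passing expressivity ladder shows that the architectures detect what they
are built to detect under burden-mediated signals — not that equivalent
effects are present or detectable in any real cohort.

## The expressivity ladder (desk scale)

The acceptance suite reproduces the architecture-epistasis mapping on
cohorts of n = 4,000 samples x 200 genes, 20 hidden (pathway) units, a
gene-module hidden width of 6, balanced prevalence, evaluated with 10
repetitions of stratified 3-fold CV on identical splits:

* additive-only signal (8 genes, beta 0.8, noise sd 1): logreg, biosparse
  and dense agree within 0.02 mean AUC;
* shared-pathway positive epistasis (10 ridge pairs, effect 2, kappa 3,
  shift 1.5, noise sd 0.3): biosparse beats logreg by at least 0.03;
* reciprocal sign epistasis (8 XOR pairs, effect 2, tau 2.5, noise sd
  0.25): dense beats degree-1 biosparse by at least 0.05 while biosparse
  stays within 0.03 of logreg;
* the linear control never beats the best additive baseline by more than
  0.02.

Effect sizes are not quantitative claims about any disease; they were fixed
once, by design-time pilots, to make each planted pattern detectable at
this scale. Balanced prevalence is used in these experiments to maximize
the information per sample; the imbalanced default (with its matching focal
alpha) is exercised elsewhere in the suite. The XOR thresholds sit away
from the burden median, so the planted indicators have asymmetric
prevalences and hence nonzero marginal effects — the realistic case, and
the only one in which gradient training can localize the interacting genes
(a marginal-free XOR distributed over 200 genes is invisible to every
model, dense included).

Training settings for the ladder, fixed in the same pilots: mini-batches of
64 (the same arithmetic per epoch as the default 128, twice the updates;
the deeper heads occasionally stalled at batch 128), per-architecture and
per-scenario epoch budgets within the 20-75 protocol range chosen so the
compared models are comparably converged, and — for the dense head on the
reciprocal-sign cohort — learning rate 3e-3 with dropout 0.3 and weight
decay 1e-3: without regularization the over-parameterized dense layer
memorizes the training fold instead of discovering the planted
interactions, and per-model hyperparameter grids are part of the reference
protocol. Model factories restart a run whose final training loss is within
5% of its initial value (detected from the training loss only; at most
twice), a rare initialization pathology of the deeper heads. The "best
additive baseline" is the larger mean AUC of a variant-level L1 logistic
regression and an L2 model on per-gene total burden; the burden contender
puts the additive model class on the same gene-centric footing as the
networks, mirroring the practice of benchmarking several additive
alternatives and reporting the best.

The ensemble experiment (25 randomly sparsified members at 75% gene
fraction, the sparsity level found optimal upstream, vs. a single model
wired and seeded exactly like the first member) runs at n = 1,500 samples x
200 genes so the full suite stays within a desktop time budget; the
ensemble's advantage at this scale is large relative to fold noise. The
null-calibration experiment for the corrected t-test uses a deliberately
small cohort (n = 120) and model (gene hidden width 3, 4 epochs):
calibration is a property of the statistic, not of model quality, and
1,000 permutation repetitions matter more than per-model polish.

## Numerical choices and degenerate inputs

* Zero-variance feature classes standardize to 0 and invert to their mean.
* A biosparse/linear head rejects masks with per-gene degree above 1;
  degree-0 genes are allowed and structurally dropped (the random-sparsity
  ladder requires them).
* `corrected_t_test()` with zero variance reports p = 1 when the mean
  difference is 0, and p = 0 with a `degenerate` flag otherwise.
* Probability outputs are clamped to (1e-7, 1 - 1e-7).
* RigL tie-breaks (equal |weight| or |gradient|) resolve by (gene, hidden)
  index order.
* The XOR micro-motif test trains with lr 0.01 and 400 full-batch epochs:
  a 4-parameter-wide toy needs symmetry breaking, not the cohort protocol.

## Known limitations

* The compiled core is single precision; two platforms with different BLAS
  kernels can diverge in late training digits (results are bit-reproducible
  within a platform).
* Checkpoints use R serialization (RDS); they are platform-portable but not
  a cross-language interchange format.
* The real cohort behind the motivating study is access-restricted, so no
  claim about its AUCs is reproduced here; all quantitative checks run on
  synthetic cohorts with known ground truth.
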