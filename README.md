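# pathnn

Pathway-sparsified neural networks for exome-based case-control prediction
— with the simulation and evaluation machinery to study *when* nonlinear
models beat additive ones in heavily underdetermined (p >> n) genetic data.

## The problem and the models

Whole-exome cohorts carry millions of candidate variants but only thousands
of samples, which has historically made high-bias additive models (penalized
logistic regression on variants, polygenic scores) the default. `pathnn`
implements a family of deliberately small neural networks whose building
block is a **shared gene module**: every gene's *mutational load* — the
C-dimensional histogram of its variant counts by functional class (C = 16
by default) — is processed by one network with shared weights (16 inputs,
50 tanh hidden units, scalar output: 850 weights + 51 biases), producing
one activation G_i per gene. Heads of graded expressivity connect the gene
neurons to a sigmoid output:

| head | wiring | can detect |
|---|---|---|
| `logreg` | genes → output | additive effects only |
| `biosparse` | one gene–pathway connection per gene, tanh pathway neurons | + magnitude (positive/negative) epistasis between genes sharing a pathway |
| `dense` | fully connected hidden layer | + reciprocal sign epistasis (XOR-like, non-monotone) |
| `linear` | as `biosparse`, all activations identity | additive control |

Supporting machinery: knowledge-based / random / L1-learned / RigL-learned
sparsity masks for the gene–pathway layer; focal-loss training
(`alpha = n_controls/n_total`, `gamma = 2`) with Adam; repeated stratified
3-fold cross-validation with the variance-corrected resampled t-test
(`t = mean(d)/sqrt((1/m + n_test/n_train) var(d))`); an ensemble of randomly
sparsified networks; additive (glmnet) and random-forest (ranger) baselines;
and a cohort simulator that plants additive, magnitude-epistatic and
reciprocal-sign-epistatic architectures with a known Bayes-optimal score.

## Worked example

```r
library(pathnn)

# simulate a cohort with positive epistasis between same-pathway gene pairs
cfg <- sim_config(n_samples = 2000, n_genes = 100, n_pathways = 10,
                  rate = 0.1, prevalence = 0.5,
                  magnitude_pairs = data.frame(
                    gene_i = c(1, 3), gene_j = c(2, 4), effect = 2,
                    sign = "positive", same_pathway = TRUE),
                  kappa = 3, ridge_shift = 1.5, noise_sd = 0.3, seed = 1)
sim <- simulate_cohort(cfg)

gm <- gene_module_spec(input_dim = 16, hidden_units = 8)
km <- knowledge_mask(sim$pathway_map, sim$tensor$gene_ids, seed = 1)
fac <- list(
  logreg    = nn_factory(gm, head_spec("logreg"),
                         train_config(epochs = 50, batch_size = 64)),
  biosparse = nn_factory(gm, head_spec("biosparse", mask = km),
                         train_config(epochs = 50, batch_size = 64)))
cvs <- repeated_stratified_cv(fac, sim$tensor, sim$labels,
                              k = 3, reps = 3, base_seed = 11)
print(cvs$logreg)
print(cvs$biosparse)
print(corrected_t_test(cvs$biosparse, cvs$logreg)$p)
print(roc_auc(bayes_score(sim$tensor, sim$truth), sim$labels))
```

prints (one CPU, fixed seeds)

```
<cv_result> logreg: mean AUC 0.8022 (sd 0.0262) over 3 x 3-fold CV
<cv_result> biosparse: mean AUC 0.8930 (sd 0.0145) over 3 x 3-fold CV
[1] 0.0002108148
[1] 0.907994
```

read as: on a cohort whose only genetic signal is a saturating interaction
between gene pairs sharing a pathway, the pathway-sparsified network beats
the gene-level logistic regression by ~0.09 mean AUC (p = 2e-4 under the
overlap-corrected resampled t-test), approaching the noiseless Bayes
ceiling of 0.91.

The simulator is also available from a shell:

```sh
Rscript inst/cli/pathnn_simulate.R --config cohort.yaml --seed 1 --out out_dir
```

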