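test_that("null cohorts carry no learnable signal", {
  aucs <- vapply(1:10, function(s) {
    sim <- simulate_cohort(sim_config(2000, 20, n_pathways = 4,
                                      classes = tiny_vocab(), rate = 0.3,
                                      prevalence = 0.5, noise_sd = 1,
                                      seed = 200 + s))
    cv <- repeated_stratified_cv(burden_additive_factory(strength = 0.01),
                                 sim$tensor, sim$labels, k = 3, reps = 1,
                                 base_seed = s)
    cv$mean
  }, numeric(1))
  expect_true(all(aucs > 0.45 & aucs < 0.55))
})

test_that("quantile calibration hits the prevalence target", {
  sim <- simulate_cohort(sim_config(5000, 30, n_pathways = 4,
                                    classes = tiny_vocab(), rate = 0.2,
                                    prevalence = 0.126,
                                    additive = data.frame(gene = 1:3,
                                                          beta = 1),
                                    noise_sd = 1, seed = 7))
  expect_lt(abs(mean(sim$labels) - 0.126), 0.02)
  expect_error(simulate_cohort(sim_config(5, 4, classes = tiny_vocab(),
                                          prevalence = 0.01, seed = 1)),
               "prevalence")
})

test_that("a noiseless reciprocal-sign cohort is labeled by the exact XOR", {
  cfg <- sim_config(800, 10, n_pathways = 4, classes = tiny_vocab(),
                    rate = 0.4, prevalence = 0.6,
                    sign_pairs = data.frame(gene_i = 1, gene_j = 2,
                                            effect = 1, tau = 1.5),
                    noise_sd = 0, seed = 9)
  sim <- simulate_cohort(cfg)
  # end-to-end recount oracle: re-encode the emitted variant table and
  # recompute the XOR of the burden indicators
  X <- encode_gene_centric(sim$table, genes = sim$tensor$gene_ids,
                           vocab = sim$tensor$classes,
                           samples = sim$tensor$sample_ids)
  b <- rowSums(X$counts, dims = 2)
  expect_equal(unname(sim$labels),
               as.integer(xor(b[, 1] > 1.5, b[, 2] > 1.5)))
  # and the emitted table reproduces the tensor exactly
  expect_equal(X$counts, sim$tensor$counts)
})

test_that("the Bayes score is the noiseless liability and an AUC ceiling", {
  cfg <- sim_config(600, 12, n_pathways = 3, classes = tiny_vocab(),
                    rate = 0.3, prevalence = 0.5,
                    additive = data.frame(gene = 1:3, beta = 1),
                    magnitude_pairs = data.frame(gene_i = 4, gene_j = 5,
                                                 effect = 1,
                                                 sign = "positive",
                                                 same_pathway = TRUE),
                    noise_sd = 0, seed = 10)
  sim <- simulate_cohort(cfg)
  sc <- bayes_score(sim$tensor, sim$truth)
  expect_equal(unname(sc), unname(sim$truth$bayes))
  expect_equal(roc_auc(sc, sim$labels), 1.0)
  expect_error(bayes_score(standardize(sim$tensor), sim$truth), "raw")

  # AUC decreases (non-strictly) with the noise level
  mean_auc <- vapply(c(0, 0.5, 1, 2, 4), function(sd) {
    mean(vapply(1:10, function(s) {
      cfg <- sim_config(400, 10, n_pathways = 3, classes = tiny_vocab(),
                        rate = 0.3, prevalence = 0.5,
                        additive = data.frame(gene = 1:3, beta = 1),
                        noise_sd = sd, seed = 300 + s)
      sim <- simulate_cohort(cfg)
      roc_auc(bayes_score(sim$tensor, sim$truth), sim$labels)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_auc) < 0.01))
})

test_that("the Bayes ceiling dominates a trained network", {
  ok <- vapply(1:10, function(s) {
    cfg <- sim_config(4000, 30, n_pathways = 5, classes = tiny_vocab(),
                      rate = 0.3, prevalence = 0.5,
                      additive = data.frame(gene = 1:5, beta = 0.8),
                      noise_sd = 0.8, seed = 400 + s)
    sim <- simulate_cohort(cfg)
    tr <- seq_len(2600); te <- 2601:4000
    Xtr <- pathnn:::subset_samples(sim$tensor, tr)
    st <- fit_standardization(Xtr)
    km <- knowledge_mask(sim$pathway_map, sim$tensor$gene_ids, seed = s)
    m <- build_model(default_gm(), head_spec("biosparse", mask = km),
                     sim$tensor$gene_ids, sim$tensor$classes, seed = s)
    m <- train(m, standardize(Xtr, st), sim$labels[tr],
               train_config(epochs = 20, seed = s))
    Xte <- standardize(pathnn:::subset_samples(sim$tensor, te), st)
    nn <- roc_auc(predict_proba(m, Xte), sim$labels[te])
    bay <- roc_auc(bayes_score(sim$tensor, sim$truth)[te], sim$labels[te])
    bay >= nn - 0.02
  }, logical(1))
  expect_true(all(ok))
})

test_that("simulated pathway maps honor the pair placement rules", {
  cfg <- sim_config(50, 20, n_pathways = 5, classes = tiny_vocab(),
                    rate = 0.3, prevalence = 0.5,
                    magnitude_pairs = data.frame(
                      gene_i = c(1, 3), gene_j = c(2, 4), effect = 1,
                      sign = c("positive", "negative"),
                      same_pathway = c(TRUE, FALSE)),
                    sign_pairs = data.frame(gene_i = 5, gene_j = 6,
                                            effect = 1, tau = 1),
                    noise_sd = 1, seed = 11)
  sim <- simulate_cohort(cfg)
  mem <- sim$pathway_map$memberships
  expect_identical(mem[["g0001"]], mem[["g0002"]])   # same-pathway pair
  expect_false(identical(mem[["g0003"]], mem[["g0004"]]))
  expect_false(identical(mem[["g0005"]], mem[["g0006"]]))
  expect_true(all(lengths(mem) == 1))
})

test_that("negative-binomial counts are supported and overdispersed", {
  cfg <- sim_config(2000, 10, n_pathways = 2, classes = tiny_vocab(),
                    rate = 0.5, prevalence = 0.5, noise_sd = 1,
                    count_model = "nbinom", nb_size = 2, seed = 12)
  sim <- simulate_cohort(cfg)
  x <- as.numeric(sim$tensor$counts)
  expect_gt(var(x) / mean(x), 1.1)
})

test_that("cohorts round-trip through the plain-text export", {
  sim <- simulate_cohort(sim_config(60, 8, n_pathways = 3,
                                    classes = tiny_vocab(), rate = 0.4,
                                    prevalence = 0.5,
                                    additive = data.frame(gene = 1, beta = 1),
                                    noise_sd = 1, seed = 13))
  dir <- withr::local_tempdir()
  write_cohort(sim, dir)
  tab <- read_variant_table(file.path(dir, "variants.tsv"),
                            sim$tensor$classes)
  expect_equal(nrow(tab), nrow(sim$table))
  lab <- utils::read.delim(file.path(dir, "labels.tsv"))
  expect_equal(lab$label, unname(sim$labels))
  pm <- finalize_pathway_map(read_gmt(file.path(dir, "pathways.gmt")),
                             sim$tensor$gene_ids)
  expect_identical(pm$memberships, sim$pathway_map$memberships)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$prevalence_realized, mean(sim$labels))
})
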