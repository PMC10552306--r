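make_pm <- function(sets, genes) finalize_pathway_map(pathway_map(sets), genes)

test_that("knowledge masks pick one membership pathway per gene, seeded", {
  genes <- c("g1", "g2", "g3")
  pm <- make_pm(list(p1 = c("g1", "g2"), p2 = "g2"), genes)
  mk <- knowledge_mask(pm, genes, seed = 1)
  expect_true(all(mk$degree == 1))
  # single-membership gene connects to its pathway
  expect_equal(mk$mask["g1", "p1"], 1)
  # orphan gene connects to the dummy
  expect_equal(mk$mask["g3", pm$dummy_id], 1)
  # reproducible from the seed
  expect_identical(mk$mask, knowledge_mask(pm, genes, seed = 1)$mask)
  # uniform pick among memberships: frequency 0.5 +/- 0.05 over 1000 seeds
  picks <- vapply(1:1000, function(s)
    knowledge_mask(pm, genes, seed = s)$mask["g2", "p1"], numeric(1))
  expect_lt(abs(mean(picks) - 0.5), 0.05)
})

test_that("random masks select the right number of genes, uniformly", {
  mk <- random_mask(100, 10, 1, seed = 1)
  expect_equal(mk$n_connections, 100)
  expect_true(all(mk$degree == 1))
  mk25 <- random_mask(100, 10, 0.25, seed = 2)
  expect_equal(mk25$n_connected_genes, 25)
  expect_equal(sum(mk25$degree == 0), 75)
  expect_error(random_mask(100, 10, 0), "gene_fraction")
  expect_error(random_mask(100, 10, 1.2), "gene_fraction")
  # hidden-neuron occupancy is uniform: 10,000 draws over 10 neurons
  occ <- colSums(random_mask(10000, 10, 1, seed = 3)$mask)
  expect_gt(stats::chisq.test(occ)$p.value, 0.01)
})

test_that("full-membership masks keep every relation; knowledge is a subset", {
  genes <- paste0("g", 1:6)
  pm <- make_pm(list(p1 = genes[1:4], p2 = genes[3:5], p3 = genes[1]), genes)
  fm <- full_membership_mask(pm, genes)
  expect_equal(unname(fm$degree["g1"]), 2)
  expect_equal(unname(fm$degree["g3"]), 2)
  expect_equal(fm$n_connections,
               sum(lengths(pm$memberships[genes])))
  for (s in 1:20) {
    km <- knowledge_mask(pm, genes, seed = s)
    common <- intersect(colnames(km$mask), colnames(fm$mask))
    expect_true(all(km$mask[, common] <= fm$mask[, common]))
    expect_true(all(colnames(km$mask) %in% colnames(fm$mask)))
  }
})

test_that("L1-learned masks respect the budget and recover signal genes", {
  sim <- toy_data(n = 250, G = 8, seed = 11, beta = 3, n_signal = 1,
                  noise = 0.3)
  X <- standardize(sim$tensor)
  expect_error(l1_learned_mask(X, sim$labels, n_hidden = 3, budget = 0),
               "budget")
  hits <- 0
  for (s in 1:10) {
    sim_s <- toy_data(n = 250, G = 8, seed = 10 + s, beta = 3, n_signal = 1,
                      noise = 0.3)
    X_s <- standardize(sim_s$tensor)
    mk <- l1_learned_mask(X_s, sim_s$labels, n_hidden = 3, budget = 4,
                          l1_strength = 2e-3, gm = default_gm(),
                          train_cfg = train_config(epochs = 60,
                                                   batch_size = 32),
                          seed = s)
    expect_equal(mk$n_connections, 4)
    expect_true(all(mk$degree <= 1))
    if (mk$degree["g0001"] == 1) hits <- hits + 1
  }
  # the only signal-carrying gene is retained in at least 9/10 seeds
  expect_gte(hits, 9)
})

test_that("RigL preserves the connection budget and a zero schedule is a no-op", {
  sim <- toy_data(n = 200, G = 10, seed = 12)
  X <- standardize(sim$tensor)
  mk <- random_mask(10, 4, 1, seed = 1, gene_ids = X$gene_ids)
  m <- build_model(default_gm(), head_spec("biosparse", mask = mk),
                   X$gene_ids, X$classes, seed = 1)
  # drop_fraction = 0: final mask equals the initial mask
  out0 <- rigl_train(m, X, sim$labels, train_config(epochs = 3, seed = 1),
                     rigl_config(update_interval = 2, drop_fraction = 0))
  expect_identical(out0$mask$mask, mk$mask)
  # with churn, the connection count is conserved
  out <- rigl_train(m, X, sim$labels, train_config(epochs = 6, seed = 1),
                    rigl_config(update_interval = 2, drop_fraction = 0.4))
  expect_equal(sum(out$mask$mask), sum(mk$mask))
  expect_false(identical(out$mask$mask, mk$mask))
  expect_error(rigl_config(drop_fraction = 1), "drop_fraction")
  # logreg head has no sparse layer to rewire
  ml <- build_model(default_gm(), head_spec("logreg"), X$gene_ids,
                    X$classes, seed = 1)
  expect_error(rigl_train(ml, X, sim$labels), "gene-pathway")
})

test_that("RigL reconnects signal genes that start disconnected", {
  recovered <- vapply(1:10, function(s) {
    cfg <- sim_config(2000, 30, n_pathways = 4, classes = tiny_vocab(),
                      rate = 0.3, prevalence = 0.5,
                      additive = data.frame(gene = 1:5, beta = 1.5),
                      noise_sd = 0.5, seed = 100 + s)
    sim <- simulate_cohort(cfg)
    X <- standardize(sim$tensor)
    # initial mask connects only non-signal genes
    M <- matrix(0, 30, 4, dimnames = list(X$gene_ids, paste0("h", 1:4)))
    set.seed(s)
    M[cbind(6:30, sample.int(4, 25, TRUE))] <- 1
    m <- build_model(default_gm(), head_spec("biosparse",
                                             mask = sparsity_mask(M, "random")),
                     X$gene_ids, X$classes, seed = s)
    out <- rigl_train(m, X, sim$labels,
                      train_config(epochs = 10, seed = s),
                      rigl_config(update_interval = 10, drop_fraction = 0.3))
    mean(rowSums(out$mask$mask[1:5, , drop = FALSE]) > 0)
  }, numeric(1))
  expect_gte(mean(recovered), 0.5)
})

test_that("masks serialize to coordinate TSV + JSON and round-trip", {
  mk <- random_mask(12, 5, 0.5, seed = 9)
  pfx <- file.path(withr::local_tempdir(), "mask")
  write_mask(mk, pfx)
  back <- read_mask(pfx)
  expect_identical(back$mask, mk$mask)
  expect_identical(back$provenance, mk$provenance)
})
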