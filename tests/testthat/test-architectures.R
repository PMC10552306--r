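test_that("heads build, predict probabilities and enforce mask invariants", {
  vocab <- tiny_vocab()
  gm <- default_gm()
  sim <- toy_data(n = 20, G = 4, seed = 2)
  X <- standardize(sim$tensor)
  genes <- X$gene_ids
  m <- build_model(gm, head_spec("logreg"), genes, vocab, seed = 1)
  p <- predict_proba(m, X)
  expect_length(p, 20)
  expect_true(all(p > 0 & p < 1))

  # all-zero input through a fresh model: finite probability in (0,1)
  X0 <- gene_tensor(array(0, c(2, 4, 4)), c("a", "b"), genes, vocab,
                    standardized = TRUE)
  p0 <- predict_proba(m, X0)
  expect_true(all(is.finite(p0) & p0 > 0 & p0 < 1))

  # duplicated sample duplicates its prediction exactly
  Xd <- gene_tensor(X$counts[c(1, 1, 2), , ], c("a", "b", "c"), genes, vocab,
                    standardized = TRUE)
  pd <- predict_proba(m, Xd)
  expect_identical(unname(pd[1]), unname(pd[2]))

  # a biosparse mask with gene degree 2 is a construction error
  M <- matrix(0, 4, 2, dimnames = list(genes, c("h1", "h2")))
  M[1, ] <- 1; M[2:4, 1] <- 1
  expect_error(build_model(gm, head_spec("biosparse",
                                         mask = sparsity_mask(M, "knowledge")),
                           genes, vocab),
               "degree")
  # degree-0 genes are allowed (structurally dropped)
  M2 <- matrix(0, 4, 2, dimnames = list(genes, c("h1", "h2")))
  M2[1:2, 1] <- 1
  m2 <- build_model(gm, head_spec("biosparse",
                                  mask = sparsity_mask(M2, "random")),
                    genes, vocab, seed = 1)
  expect_true(all(m2$params$U[3:4, ] == 0))

  # vocabulary mismatch errors
  expect_error(predict_proba(m, sim$tensor), "standardized")
  Xw <- gene_tensor(X$counts, X$sample_ids, paste0("x", 1:4), vocab,
                    standardized = TRUE)
  expect_error(predict_proba(m, Xw), "mismatch")
})

test_that("compiled and reference forward passes agree on every head", {
  vocab <- tiny_vocab()
  sim <- toy_data(n = 30, G = 6, seed = 3)
  X <- standardize(sim$tensor)
  genes <- X$gene_ids
  gm <- default_gm()
  pm <- finalize_pathway_map(pathway_map(list(p1 = genes[1:3],
                                              p2 = genes[3:5])), genes)
  km <- knowledge_mask(pm, genes, seed = 2)
  ed <- gene_edges(cbind(genes[1:2], genes[3:4]))
  heads <- list(head_spec("logreg"),
                head_spec("biosparse", mask = km),
                head_spec("dense", n_hidden = 3),
                head_spec("linear", mask = km),
                head_spec("multiconnect", mask = full_membership_mask(pm)),
                head_spec("stacked_interactome", mask = km, edges = ed))
  for (h in heads) {
    m <- build_model(gm, h, genes, vocab, seed = 4)
    expect_lt(max(abs(predict_proba(m, X) - pathnn:::nn_forward_r(m, X))),
              2e-6)
  }
})

test_that("the linear head's pre-sigmoid score is affine (superposition)", {
  vocab <- tiny_vocab()
  sim <- toy_data(n = 9, G = 5, seed = 5)
  X <- standardize(sim$tensor)
  genes <- X$gene_ids
  km <- random_mask(5, 3, 1, seed = 1, gene_ids = genes)
  for (seed in 1:5) {
    m <- build_model(default_gm(), head_spec("linear", mask = km),
                     genes, vocab, seed = seed)
    sc <- function(counts) {
      Xi <- gene_tensor(counts, X$sample_ids[seq_len(dim(counts)[1])],
                        genes, vocab, standardized = TRUE)
      logit(pathnn:::nn_forward_r(m, Xi))
    }
    x1 <- X$counts[1, , , drop = FALSE]
    x2 <- X$counts[2, , , drop = FALSE]
    x0 <- array(0, dim(x1))
    lhs <- sc(x1 + x2 - x0)
    rhs <- sc(x1) + sc(x2) - sc(x0)
    expect_lt(abs(lhs - rhs), 1e-6)
  }
  # tanh model violates superposition (sanity that the check has teeth)
  mt <- build_model(default_gm(), head_spec("biosparse", mask = km),
                    genes, vocab, seed = 1)
  sct <- function(counts) {
    Xi <- gene_tensor(counts, "s", genes, vocab, standardized = TRUE)
    logit(pathnn:::nn_forward_r(mt, Xi))
  }
  x1 <- X$counts[1, , , drop = FALSE]; x2 <- X$counts[2, , , drop = FALSE]
  expect_gt(abs(sct(x1 + x2) - (sct(x1) + sct(x2) - sct(array(0, dim(x1))))),
            1e-4)
})

test_that("predictions are equivariant to a joint gene permutation", {
  vocab <- tiny_vocab()
  sim <- toy_data(n = 15, G = 6, seed = 6)
  X <- standardize(sim$tensor)
  genes <- X$gene_ids
  km <- random_mask(6, 3, 1, seed = 3, gene_ids = genes)
  m <- build_model(default_gm(), head_spec("biosparse", mask = km),
                   genes, vocab, seed = 7)
  perm <- c(4, 1, 6, 2, 5, 3)
  Mp <- m$M[perm, ]
  m2 <- m
  m2$gene_ids <- genes[perm]
  m2$M <- Mp
  m2$params$U <- m$params$U[perm, ]
  Xp <- gene_tensor(X$counts[, perm, ], X$sample_ids, genes[perm], vocab,
                    standardized = TRUE)
  expect_lt(max(abs(predict_proba(m, X) - predict_proba(m2, Xp))), 1e-6)
})

test_that("parameter counts match closed forms and an independent walk", {
  vocab16 <- annovar_classes(16)
  genes <- paste0("g", 1:5)
  m <- build_model(gene_module_spec(16, 50), head_spec("logreg"),
                   genes, vocab16, seed = 1)
  expect_equal(unname(count_parameters(m, "gene_module")), c(850L, 51L))
  expect_equal(unname(count_parameters(m, "head")), c(5L, 1L))

  m2 <- build_model(gene_module_spec(2, 3), head_spec("logreg"),
                    genes, tiny_vocab(2), seed = 1)
  expect_equal(unname(count_parameters(m2, "gene_module")), c(9L, 4L))

  # independent enumeration oracle over the parameter store
  walk <- function(model) {
    p <- model$params
    w <- length(p$W1) + length(p$w2)
    b <- length(p$b1) + 1L
    if (!is.null(p$v)) { w <- w + length(p$v); b <- b + 1L }
    if (!is.null(p$U)) {
      w <- w + sum(model$M != 0) + length(p$w)
      b <- b + length(p$bh) + 1L
    }
    if (!is.null(p$Ugg)) {
      w <- w + sum(model$Mgg != 0)
      b <- b + length(p$bgg)
    }
    c(weights = w, biases = b)
  }
  sim <- toy_data(n = 10, G = 5, seed = 2)
  pm <- finalize_pathway_map(pathway_map(list(p1 = genes[1:2],
                                              p2 = genes[2:4])), genes)
  heads <- list(head_spec("logreg"),
                head_spec("biosparse",
                          mask = knowledge_mask(pm, genes, seed = 1)),
                head_spec("dense", n_hidden = 7),
                head_spec("multiconnect", mask = full_membership_mask(pm)),
                head_spec("stacked_interactome",
                          mask = knowledge_mask(pm, genes, seed = 1),
                          edges = gene_edges(cbind("g1", "g2"))))
  for (h in heads) {
    m <- build_model(default_gm(), h, genes, tiny_vocab(), seed = 3)
    expect_equal(count_parameters(m), walk(m))
  }
  # masked-out connections contribute no parameters
  mk <- random_mask(5, 4, 0.4, seed = 5, gene_ids = genes)
  mm <- build_model(default_gm(), head_spec("biosparse", mask = mk),
                    genes, tiny_vocab(), seed = 1)
  expect_equal(unname(count_parameters(mm, "head")[1]), 2L + 4L)
})

test_that("checkpoints reload with bit-identical predictions", {
  sim <- toy_data(n = 25, G = 5, seed = 9)
  X <- standardize(sim$tensor)
  m <- build_model(default_gm(), head_spec("dense", n_hidden = 3),
                   X$gene_ids, X$classes, seed = 2)
  m <- train_quick(m, X, sim$labels)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  expect_identical(predict_proba(load_model(f), X), predict_proba(m, X))
})

test_that("the stacked interactome head adds self-edges only for isolated genes", {
  genes <- paste0("g", 1:4)
  km <- random_mask(4, 2, 1, seed = 1, gene_ids = genes)
  ed <- gene_edges(cbind("g1", "g2"))
  m <- build_model(default_gm(), head_spec("stacked_interactome", mask = km,
                                           edges = ed),
                   genes, tiny_vocab(), seed = 1)
  expect_equal(unname(diag(m$Mgg)), c(0, 0, 1, 1))
  expect_equal(m$Mgg["g1", "g2"], 1)
  expect_equal(m$Mgg["g2", "g1"], 1)
})
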