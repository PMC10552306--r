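test_that("variant tables parse, validate their schema and vocabulary", {
  vocab <- tiny_vocab()
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tgene_id\tfunctional_class",
               "s1\tg1\tc1", "s1\tg2\tc2", "s2\tg1\tc3"), f)
  tab <- read_variant_table(f, vocab)
  expect_equal(nrow(tab), 3L)

  writeLines(c("sample_id\tgene_id\tfunctional_class",
               "s1\tg1\texonic_nonsense"), f)
  expect_error(read_variant_table(f, vocab), "exonic_nonsense")

  writeLines("sample_id\tgene_id\tfunctional_class", f)
  expect_equal(nrow(read_variant_table(f, vocab)), 0L)

  writeLines(c("sample_id\tgene_id", "s1\tg1"), f)
  expect_error(read_variant_table(f, vocab), "schema")

  # round trip
  tab <- tiny_table()
  write_variant_table(tab, f)
  expect_equal(nrow(read_variant_table(f, vocab)), nrow(tab))
})

test_that("gene-centric encoding counts variants per (sample, gene, class)", {
  vocab <- tiny_vocab()
  tab <- tiny_table()
  X <- encode_gene_centric(tab, genes = c("g1", "g2", "g3"))
  # s1 x g1: two c1 records
  expect_equal(X$counts[1, 1, ], c(2, 0, 0, 0))
  # s2 x g1: one c3
  expect_equal(X$counts[2, 1, ], c(0, 0, 1, 0))
  # sample with no record on a gene is all zero
  expect_equal(X$counts[3, 1, ], rep(0, 4))
  # samples argument adds an all-zero slice
  X2 <- encode_gene_centric(tab, genes = c("g1", "g2", "g3"),
                            samples = c("s1", "s2", "s3", "s4"))
  expect_equal(X2$counts[4, , ], matrix(0, 3, 4))
  # unknown gene handling
  bad <- variant_table(data.frame(sample_id = "s1", gene_id = "gX",
                                  functional_class = "c1"), vocab)
  expect_error(encode_gene_centric(bad, genes = "g1"), "gX")
  expect_equal(sum(encode_gene_centric(bad, genes = "g1",
                                       drop_unknown_genes = TRUE)$counts), 0)
})

test_that("encoding agrees with an independent groupby-count oracle", {
  for (seed in 1:3) {
    tab <- random_table(seed = seed)
    genes <- paste0("g", 1:5)
    X <- encode_gene_centric(tab, genes = genes)
    # oracle: base-R three-way contingency table from the raw records
    oracle <- table(factor(tab$sample_id, X$sample_ids),
                    factor(tab$gene_id, genes),
                    factor(tab$functional_class, unclass(X$classes)))
    expect_equal(unname(X$counts), unname(array(oracle, dim(oracle))))
    # conservation: total counts = number of records
    expect_equal(sum(X$counts), nrow(tab))
    # permuting record order never changes the tensor
    perm <- tab[sample.int(nrow(tab)), ]
    Xp <- encode_gene_centric(variant_table(perm, X$classes), genes = genes)
    expect_identical(X$counts, Xp$counts)
  }
})

test_that("standardization pools per class, is invertible and leak-safe", {
  sim <- toy_data(n = 50, G = 6, seed = 3)
  X <- sim$tensor
  Xs <- standardize(X)
  d <- dim(X$counts)
  # recompute moments from scratch: pooled per-class mean 0, sd 1
  flat <- matrix(Xs$counts, d[1] * d[2], d[3])
  expect_lt(max(abs(colMeans(flat))), 1e-6)
  expect_lt(max(abs(apply(flat, 2, sd) - 1)), 1e-6)
  # applying the stored stats to the same tensor is idempotent
  Xs2 <- standardize(X, stats = Xs$stats)
  expect_equal(Xs$counts, Xs2$counts)
  # inverse transform recovers raw counts
  back <- inverse_standardize(Xs)
  expect_lt(max(abs(back$counts - X$counts)), 1e-9)
  # constant-count class maps to zero
  Xc <- X
  Xc$counts[, , 2] <- 7
  Xc <- gene_tensor(Xc$counts, X$sample_ids, X$gene_ids, X$classes)
  expect_true(all(standardize(Xc)$counts[, , 2] == 0))
  # vocabulary mismatch is an error
  other <- gene_tensor(X$counts, X$sample_ids, X$gene_ids,
                       class_vocabulary(paste0("z", 1:4)))
  expect_error(standardize(other, stats = Xs$stats), "mismatch")
  # double standardization is refused
  expect_error(standardize(Xs), "already")
})

test_that("per-(gene,class) standardization mode works and round-trips", {
  sim <- toy_data(n = 40, G = 5, seed = 4)
  Xs <- standardize(sim$tensor, per_gene = TRUE)
  back <- inverse_standardize(Xs)
  expect_lt(max(abs(back$counts - sim$tensor$counts)), 1e-9)
})

test_that("tensors persist to the documented two-file layout", {
  sim <- toy_data(n = 20, G = 4, seed = 5)
  Xs <- standardize(sim$tensor)
  pfx <- file.path(withr::local_tempdir(), "tensor")
  save_tensor(Xs, pfx)
  back <- load_tensor(pfx)
  expect_equal(back$counts, Xs$counts)
  expect_identical(back$sample_ids, Xs$sample_ids)
  expect_true(back$standardized)
  expect_equal(back$stats$mean, unname(Xs$stats$mean))
})

test_that("GMT parsing inverts memberships and the dummy pathway is total", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("pw1\tdesc\tg1\tg2", "pw2\tdesc\tg2\tg3"), f)
  pm <- read_gmt(f)
  expect_setequal(pm$memberships[["g2"]], c("pw1", "pw2"))
  fin <- finalize_pathway_map(pm, genes = c("g1", "g2", "g3", "g4"))
  expect_equal(fin$memberships[["g4"]], fin$dummy_id)
  expect_true(all(lengths(fin$memberships) >= 1))
  # empty GMT: every gene goes to the dummy
  writeLines(character(0), f)
  fin0 <- finalize_pathway_map(read_gmt(f), genes = paste0("g", 1:5))
  expect_true(all(vapply(fin0$memberships, identical, TRUE, fin0$dummy_id)))
  # duplicate pathway names are rejected
  writeLines(c("pw1\td\tg1", "pw1\td\tg2"), f)
  expect_error(read_gmt(f), "duplicate")
})

test_that("gene-gene edge lists reject self-loops and deduplicate", {
  expect_error(gene_edges(cbind(c("g1", "g2"), c("g1", "g3"))), "self-loop")
  e <- gene_edges(cbind(c("g1", "g2", "g2"), c("g2", "g1", "g3")))
  expect_equal(nrow(e), 2L)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b", "g1\tg2"), f)
  expect_equal(nrow(read_gene_edges(f)), 1L)
})
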