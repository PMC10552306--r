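#' Sparsity masks for the gene-pathway layer
#'
#' A sparsity mask is the binary connectivity between the gene neurons and
#' the hidden (pathway) neurons of the next layer. Four builders are
#' provided: knowledge-based ([knowledge_mask()], one membership pathway per
#' gene), random ([random_mask()]), L1-learned ([l1_learned_mask()]) and
#' RigL-learned ([rigl_train()]); [full_membership_mask()] keeps all
#' gene-pathway relations.
#'
#' @param mask Binary matrix (genes x hidden units) with dimnames.
#' @param provenance One of `knowledge`, `random`, `l1_learned`, `rigl`,
#'   `full_membership`.
#' @param seed Seed used to build the mask, if any.
#' @return A `sparsity_mask`.
#' @export
sparsity_mask <- function(mask, provenance, seed = NA_integer_) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "double"
  assert_that(all(mask %in% c(0, 1)), "mask entries must be 0/1")
  assert_that(!is.null(rownames(mask)) && !is.null(colnames(mask)),
              "mask needs gene rownames and hidden-unit colnames")
  structure(list(mask = mask,
                 gene_ids = rownames(mask),
                 hidden_ids = colnames(mask),
                 degree = rowSums(mask),
                 n_connections = sum(mask),
                 n_connected_genes = sum(rowSums(mask) > 0),
                 provenance = provenance,
                 seed = seed),
            class = "sparsity_mask")
}

#' @export
print.sparsity_mask <- function(x, ...) {
  cat(sprintf(
    "<sparsity_mask> %s: %d genes x %d hidden, %d connections (%d genes connected)\n",
    x$provenance, nrow(x$mask), ncol(x$mask), x$n_connections,
    x$n_connected_genes))
  invisible(x)
}

#' Knowledge-based sparsification: one membership pathway per gene
#'
#' For each gene, one of its member pathways is picked uniformly at random
#' (seeded); genes without any membership are connected to the shared dummy
#' pathway neuron. Every gene ends up with degree exactly 1.
#'
#' @param pm A finalized [pathway_map()].
#' @param genes Gene vocabulary (defaults to the map's).
#' @param seed Integer seed for the uniform pathway picks.
#' @return A `sparsity_mask` with provenance `"knowledge"`. Hidden units are
#'   the pathways receiving at least one connection, plus the dummy pathway.
#' @export
knowledge_mask <- function(pm, genes = pm$genes, seed = 1) {
  stopifnot(inherits(pm, "pathway_map"), pm$finalized)
  genes <- as.character(genes)
  picks <- with_seed(seed, vapply(genes, function(g) {
    mem <- pm$memberships[[g]] %||% pm$dummy_id
    if (length(mem) == 1) mem else mem[sample.int(length(mem), 1)]
  }, character(1)))
  hidden <- unique(c(intersect(pm$pathway_ids, picks), pm$dummy_id))
  M <- matrix(0, length(genes), length(hidden),
              dimnames = list(genes, hidden))
  M[cbind(seq_along(genes), match(picks, hidden))] <- 1
  sparsity_mask(M, "knowledge", seed)
}

#' Random degree-1 sparsification
#'
#' Selects `round(gene_fraction * n_genes)` genes uniformly without
#' replacement and connects each to one uniformly chosen hidden neuron;
#' unselected genes have degree 0 and are structurally dropped from the
#' model.
#'
#' @param n_genes,n_hidden Layer dimensions.
#' @param gene_fraction Fraction of genes connected, in (0, 1].
#' @param seed Integer seed.
#' @param gene_ids,hidden_ids Optional identifiers (defaults `g1..`, `h1..`).
#' @return A `sparsity_mask` with provenance `"random"`.
#' @export
random_mask <- function(n_genes, n_hidden, gene_fraction = 1, seed = 1,
                        gene_ids = NULL, hidden_ids = NULL) {
  if (!is.numeric(gene_fraction) || gene_fraction <= 0 || gene_fraction > 1)
    stop("gene_fraction must be in (0, 1]", call. = FALSE)
  stopifnot(n_hidden >= 1, n_genes >= 1)
  gene_ids <- gene_ids %||% paste0("g", seq_len(n_genes))
  hidden_ids <- hidden_ids %||% paste0("h", seq_len(n_hidden))
  k <- round(gene_fraction * n_genes)
  M <- matrix(0, n_genes, n_hidden, dimnames = list(gene_ids, hidden_ids))
  with_seed(seed, {
    sel <- sample.int(n_genes, k)
    M[cbind(sel, sample.int(n_hidden, k, replace = TRUE))] <- 1
  })
  sparsity_mask(M, "random", seed)
}

#' Full-membership sparsification
#'
#' Keeps every gene-pathway relation of the map (genes may have degree > 1);
#' orphan genes connect to the dummy pathway.
#'
#' @inheritParams knowledge_mask
#' @return A `sparsity_mask` with provenance `"full_membership"`.
#' @export
full_membership_mask <- function(pm, genes = pm$genes) {
  stopifnot(inherits(pm, "pathway_map"), pm$finalized)
  genes <- as.character(genes)
  hidden <- pm$pathway_ids
  M <- matrix(0, length(genes), length(hidden),
              dimnames = list(genes, hidden))
  for (i in seq_along(genes)) {
    mem <- pm$memberships[[genes[i]]] %||% pm$dummy_id
    M[i, match(mem, hidden)] <- 1
  }
  # only keep hidden units that receive a connection, plus the dummy
  keep <- colSums(M) > 0 | colnames(M) == pm$dummy_id
  sparsity_mask(M[, keep, drop = FALSE], "full_membership")
}

#' L1-learned sparsification
#'
#' Trains a model with a dense gene-pathway layer under a heavy L1 penalty
#' on the layer's weights, then keeps the `budget` largest-magnitude
#' connections subject to at most one connection per gene (so the resulting
#' mask is comparable, connection-for-connection, with the degree-1
#' arrangements).
#'
#' @param X Standardized training `gene_tensor`.
#' @param y Binary labels.
#' @param n_hidden Number of hidden units of the dense layer.
#' @param budget Number of connections to keep (1..n_genes).
#' @param l1_strength L1 penalty weight on the gene-pathway layer.
#' @param gm Gene-module spec, see [gene_module_spec()].
#' @param train_cfg Training configuration, see [train_config()].
#' @param seed Integer seed (initialization and shuffling).
#' @return A `sparsity_mask` with provenance `"l1_learned"`.
#' @export
l1_learned_mask <- function(X, y, n_hidden, budget,
                            l1_strength = 1e-3,
                            gm = gene_module_spec(input_dim =
                                                    length(X$classes)),
                            train_cfg = train_config(), seed = 1) {
  G <- length(X$gene_ids)
  if (!is.numeric(budget) || budget < 1 || budget > G)
    stop("budget must be in 1..n_genes", call. = FALSE)
  model <- build_model(gm, head_spec("dense", n_hidden = n_hidden),
                       gene_ids = X$gene_ids, classes = X$classes,
                       seed = seed)
  train_cfg$seed <- seed
  model <- train(model, X, y, train_cfg, l1_head = l1_strength)
  U <- model$params$U
  # greedy: largest |U| first, at most one connection per gene
  ord <- order(-abs(U), row(U), col(U))
  M <- matrix(0, nrow(U), ncol(U),
              dimnames = list(X$gene_ids, colnames(U) %||%
                                paste0("h", seq_len(ncol(U)))))
  taken <- logical(nrow(U))
  kept <- 0
  for (j in ord) {
    g <- (j - 1) %% nrow(U) + 1
    if (!taken[g]) {
      M[j] <- 1
      taken[g] <- TRUE
      kept <- kept + 1
      if (kept == budget) break
    }
  }
  sparsity_mask(M, "l1_learned", seed)
}

#' Serialize / read a sparsity mask
#'
#' Layout: a sparse coordinate TSV (`gene_id<TAB>hidden_id`) at `<path>.tsv`
#' plus a JSON header `<path>.json` (provenance, seed, dimensions, full
#' gene/hidden vocabularies so degree-0 rows survive the round trip).
#'
#' @param x A `sparsity_mask`.
#' @param path Path prefix.
#' @export
write_mask <- function(x, path) {
  stopifnot(inherits(x, "sparsity_mask"))
  idx <- which(x$mask == 1, arr.ind = TRUE)
  dt <- data.table::data.table(gene_id = x$gene_ids[idx[, 1]],
                               hidden_id = x$hidden_ids[idx[, 2]])
  data.table::fwrite(dt[base::order(dt$gene_id, dt$hidden_id), ],
                     paste0(path, ".tsv"), sep = "\t")
  jsonlite::write_json(list(provenance = x$provenance, seed = x$seed,
                            gene_ids = x$gene_ids,
                            hidden_ids = x$hidden_ids,
                            n_connections = x$n_connections),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dt <- data.table::fread(paste0(path, ".tsv"), sep = "\t",
                          colClasses = "character", showProgress = FALSE)
  M <- matrix(0, length(hdr$gene_ids), length(hdr$hidden_ids),
              dimnames = list(hdr$gene_ids, hdr$hidden_ids))
  if (nrow(dt))
    M[cbind(match(dt$gene_id, hdr$gene_ids),
            match(dt$hidden_id, hdr$hidden_ids))] <- 1
  sparsity_mask(M, hdr$provenance, hdr$seed %||% NA_integer_)
}
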