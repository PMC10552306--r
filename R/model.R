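#' Shared gene-module specification
#'
#' One small network applied with shared weights to every gene's C-dimensional
#' mutational-load histogram, producing a scalar gene activation G_i. With the
#' defaults (16 inputs, one hidden layer of 50 neurons, scalar output) the
#' module has 16*50 + 50*1 = 850 weights and 50 + 1 = 51 biases.
#'
#' @param input_dim Number of functional classes C (default 16).
#' @param hidden_units Hidden-layer width (default 50).
#' @param activation `"tanh"` (default) or `"identity"`; applied to the
#'   module's hidden layer.
#' @param output_activation Activation of the gene output neuron G_i;
#'   `"identity"` (default) preserves the dynamic range of the mutational
#'   load for the saturating units downstream, which matters when those
#'   units must threshold a joint burden; `"tanh"` yields bounded gene
#'   neurons (useful for small didactic motifs).
#' @return A `gene_module_spec`.
#' @export
gene_module_spec <- function(input_dim = 16, hidden_units = 50,
                             activation = c("tanh", "identity"),
                             output_activation = c("identity", "tanh")) {
  activation <- match.arg(activation)
  output_activation <- match.arg(output_activation)
  stopifnot(input_dim >= 1, hidden_units >= 1)
  structure(list(input_dim = as.integer(input_dim),
                 hidden_units = as.integer(hidden_units),
                 activation = activation,
                 output_activation = output_activation),
            class = "gene_module_spec")
}

#' Head specification: how gene neurons reach the output
#'
#' Six heads of graded expressivity:
#' * `logreg` - gene neurons connect directly to the output (a logistic
#'   regression of the gene activations; no between-gene interactions).
#' * `biosparse` - a sparse gene-pathway hidden layer in which every
#'   connected gene has exactly one outgoing connection, so two genes can
#'   interact in at most one tanh neuron (magnitude epistasis, not XOR).
#' * `dense` - a fully connected hidden layer (universal approximator;
#'   can model reciprocal sign epistasis).
#' * `linear` - wired like `biosparse` but with every activation replaced by
#'   the identity; an additive control.
#' * `multiconnect` - the mask keeps all gene-pathway memberships (genes may
#'   have degree > 1).
#' * `stacked_interactome` - a sparse gene-gene interaction layer (from an
#'   edge list) feeding a sparse gene-pathway layer.
#'
#' @param kind Head kind (see above).
#' @param n_hidden Hidden-layer width (required for `dense`; otherwise taken
#'   from the mask).
#' @param mask A [sparsity_mask()] for the sparse kinds.
#' @param edges A [gene_edges()] object (only `stacked_interactome`).
#' @param activation Hidden activation, `"tanh"` or `"identity"`.
#' @param dropout Named numeric: rates for `gene` (after the gene-neuron
#'   layer) and `hidden` (after the hidden layer).
#' @return A `head_spec`.
#' @export
head_spec <- function(kind = c("logreg", "biosparse", "dense", "linear",
                               "multiconnect", "stacked_interactome"),
                      n_hidden = NULL, mask = NULL, edges = NULL,
                      activation = c("tanh", "identity"),
                      dropout = c(gene = 0, hidden = 0)) {
  kind <- match.arg(kind)
  activation <- match.arg(activation)
  dropout <- c(gene = unname(dropout["gene"] %||% 0),
               hidden = unname(dropout["hidden"] %||% 0))
  dropout[is.na(dropout)] <- 0
  if (kind %in% c("biosparse", "linear", "multiconnect"))
    assert_that(inherits(mask, "sparsity_mask"),
                paste0("head kind '", kind, "' requires a sparsity mask"))
  if (kind == "stacked_interactome")
    assert_that(inherits(mask, "sparsity_mask") &&
                  inherits(edges, "gene_edges"),
                "stacked_interactome requires a mask and a gene edge list")
  if (kind == "dense")
    assert_that(is.numeric(n_hidden) && n_hidden >= 1,
                "dense head requires n_hidden")
  structure(list(kind = kind, n_hidden = n_hidden, mask = mask,
                 edges = edges, activation = activation, dropout = dropout),
            class = "head_spec")
}

head_kind_code <- function(kind) {
  switch(kind, logreg = 0L, stacked_interactome = 2L, 1L)
}

#' Build a trainable model from a gene module and a head
#'
#' Parameters are initialized with fan-in-scaled uniform draws under `seed`.
#' Masked-out connections are structurally absent: they carry no trainable
#' parameter (weights are pinned at zero, their gradients are masked, and
#' [count_parameters()] does not count them).
#'
#' @param gm A [gene_module_spec()].
#' @param head A [head_spec()].
#' @param gene_ids Gene vocabulary (tensor gene order).
#' @param classes A [class_vocabulary()]; its length must equal
#'   `gm$input_dim`.
#' @param seed Integer initialization seed.
#' @return A `pathnn_model` with a forward pass mapping an
#'   `n x |G| x C` tensor to `n` case probabilities.
#' @export
build_model <- function(gm, head, gene_ids, classes, seed = 1) {
  stopifnot(inherits(gm, "gene_module_spec"), inherits(head, "head_spec"),
            inherits(classes, "class_vocab"))
  gene_ids <- as.character(gene_ids)
  G <- length(gene_ids)
  C <- length(classes)
  assert_that(C == gm$input_dim,
              "class vocabulary length must equal the gene module input_dim")

  linear_all <- head$kind == "linear"
  act_gene <- if (linear_all) 0L else as.integer(gm$activation == "tanh")
  act_gene_out <- if (linear_all) 0L else
    as.integer((gm$output_activation %||% "identity") == "tanh")
  act_hidden <- if (linear_all) 0L else as.integer(head$activation == "tanh")

  M <- NULL
  if (head$kind %in% c("biosparse", "linear", "multiconnect",
                       "stacked_interactome")) {
    mk <- head$mask
    assert_that(identical(mk$gene_ids, gene_ids),
                "mask gene vocabulary does not match the model's gene_ids")
    M <- mk$mask
    if (head$kind %in% c("biosparse", "linear") && any(mk$degree > 1))
      stop("biosparse/linear head requires per-gene degree <= 1 (got a gene ",
           "with degree ", max(mk$degree), ")", call. = FALSE)
  } else if (head$kind == "dense") {
    M <- matrix(1, G, head$n_hidden,
                dimnames = list(gene_ids, paste0("h", seq_len(head$n_hidden))))
  }

  Mgg <- NULL
  if (head$kind == "stacked_interactome") {
    Mgg <- matrix(0, G, G, dimnames = list(gene_ids, gene_ids))
    e <- head$edges
    keep <- e[, 1] %in% gene_ids & e[, 2] %in% gene_ids
    e <- e[keep, , drop = FALSE]
    if (nrow(e)) {
      Mgg[cbind(match(e[, 1], gene_ids), match(e[, 2], gene_ids))] <- 1
      Mgg[cbind(match(e[, 2], gene_ids), match(e[, 1], gene_ids))] <- 1
    }
    # genes without any interactome edge pass through via a self-edge
    isolated <- rowSums(Mgg) == 0
    diag(Mgg)[isolated] <- 1
  }

  params <- with_seed(seed, {
    p <- list(W1 = init_uniform(C, gm$hidden_units, C),
              b1 = rep(0, gm$hidden_units),
              w2 = as.numeric(init_uniform(gm$hidden_units, 1,
                                           gm$hidden_units)),
              b2 = 0)
    if (head$kind == "logreg") {
      p$v <- as.numeric(init_uniform(G, 1, G))
      p$c <- 0
    } else {
      if (!is.null(Mgg)) {
        p$Ugg <- init_masked(Mgg)
        p$bgg <- rep(0, G)
      }
      p$U <- init_masked(M)
      p$bh <- rep(0, ncol(M))
      p$w <- as.numeric(init_uniform(ncol(M), 1, ncol(M)))
      p$c <- 0
    }
    p
  })

  structure(list(gm = gm, head = head,
                 gene_ids = gene_ids, classes = classes,
                 act_gene = act_gene, act_gene_out = act_gene_out,
                 act_hidden = act_hidden,
                 head_kind = head_kind_code(head$kind),
                 M = M, Mgg = Mgg,
                 params = params,
                 seed = seed,
                 trained = FALSE,
                 history = NULL),
            class = "pathnn_model")
}

#' @export
print.pathnn_model <- function(x, ...) {
  pc <- count_parameters(x)
  cat(sprintf(
    "<pathnn_model> head=%s, |G|=%d, C=%d, gene hidden=%d%s; %d weights + %d biases%s\n",
    x$head$kind, length(x$gene_ids), length(x$classes), x$gm$hidden_units,
    if (!is.null(x$M)) sprintf(", |P|=%d", ncol(x$M)) else "",
    pc["weights"], pc["biases"], if (x$trained) " (trained)" else ""))
  invisible(x)
}

arch_list <- function(model) {
  list(head_kind = model$head_kind,
       act_gene = model$act_gene,
       act_gene_out = model$act_gene_out %||% 0L,
       act_hidden = model$act_hidden,
       M = model$M %||% matrix(0, 0, 0),
       Mgg = model$Mgg %||% matrix(0, 0, 0))
}

check_tensor_for_model <- function(model, X) {
  stopifnot(inherits(X, "gene_tensor"))
  if (!identical(X$gene_ids, model$gene_ids))
    stop("gene vocabulary mismatch between tensor and model", call. = FALSE)
  if (!identical(unclass(X$classes), unclass(model$classes)))
    stop("class vocabulary mismatch between tensor and model", call. = FALSE)
  if (!X$standardized)
    stop("tensor must be standardized (with training-fold statistics) ",
         "before prediction/training", call. = FALSE)
  invisible(TRUE)
}

tensor_to_mat <- function(X) {
  d <- dim(X$counts)
  matrix(as.numeric(X$counts), d[1] * d[2], d[3])
}

#' Predicted case probability per sample
#'
#' @param model A `pathnn_model` (or ensemble / baseline; this is a generic).
#' @param X A standardized `gene_tensor` with matching vocabularies.
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1), named by sample id.
#' @export
predict_proba <- function(model, X, ...) UseMethod("predict_proba")

#' @rdname predict_proba
#' @export
predict_proba.pathnn_model <- function(model, X, ...) {
  check_tensor_for_model(model, X)
  n <- dim(X$counts)[1]
  p <- nn_forward_cpp(tensor_to_mat(X), n, length(model$gene_ids),
                      model$params, arch_list(model))
  p <- pmin(pmax(as.numeric(p), 1e-7), 1 - 1e-7)
  names(p) <- X$sample_ids
  p
}

# pure-R forward pass; mirrors the compiled one and serves as its
# cross-check in the test suite
nn_forward_r <- function(model, X, return_gene_acts = FALSE) {
  check_tensor_for_model(model, X)
  d <- dim(X$counts)
  n <- d[1]; G <- d[2]
  act <- function(z, on) if (on) tanh(z) else z
  p <- model$params
  Xmat <- tensor_to_mat(X)
  A1 <- act(sweep(Xmat %*% p$W1, 2, p$b1, "+"), model$act_gene)
  gact <- act(drop(A1 %*% p$w2) + p$b2, model$act_gene_out %||% 0L)
  Ag <- matrix(gact, n, G)
  if (return_gene_acts) {
    dimnames(Ag) <- list(X$sample_ids, model$gene_ids)
    return(Ag)
  }
  if (model$head_kind == 0L) {
    score <- drop(Ag %*% p$v) + p$c
  } else {
    input <- Ag
    if (model$head_kind == 2L) {
      input <- act(sweep(Ag %*% (model$Mgg * p$Ugg), 2, p$bgg, "+"),
                   model$act_hidden)
    }
    H <- act(sweep(input %*% (model$M * p$U), 2, p$bh, "+"),
             model$act_hidden)
    score <- drop(H %*% p$w) + p$c
  }
  stats::setNames(1 / (1 + exp(-score)), X$sample_ids)
}

#' Per-gene activations G_i of the shared gene module
#'
#' @param model A `pathnn_model`.
#' @param X A standardized `gene_tensor`.
#' @return An `n x |G|` matrix of gene-neuron outputs.
#' @export
gene_activations <- function(model, X) nn_forward_r(model, X, TRUE)

#' Count trainable parameters
#'
#' Walks the parameter store and reports weights and biases separately.
#' Masked-out connections are excluded: a sparse layer contributes only its
#' mask's support.
#'
#' @param model A `pathnn_model`.
#' @param component `"all"`, `"gene_module"` or `"head"`.
#' @return Named integer vector `c(weights = ..., biases = ...)`.
#' @export
count_parameters <- function(model, component = c("all", "gene_module",
                                                  "head")) {
  component <- match.arg(component)
  p <- model$params
  gm_w <- length(p$W1) + length(p$w2)
  gm_b <- length(p$b1) + 1L  # b2
  hd_w <- 0L; hd_b <- 0L
  if (model$head_kind == 0L) {
    hd_w <- length(p$v)
    hd_b <- 1L
  } else {
    hd_w <- sum(model$M)
    hd_b <- length(p$bh) + 1L
    hd_w <- hd_w + length(p$w)
    if (model$head_kind == 2L) {
      hd_w <- hd_w + sum(model$Mgg)
      hd_b <- hd_b + length(p$bgg)
    }
  }
  out <- switch(component,
                all = c(weights = gm_w + hd_w, biases = gm_b + hd_b),
                gene_module = c(weights = gm_w, biases = gm_b),
                head = c(weights = hd_w, biases = hd_b))
  out[] <- as.integer(out)
  out
}

#' Save / load a model checkpoint
#'
#' A single-file archive holding parameters, specs, vocabularies, masks and
#' (if attached) standardization statistics; reloading reproduces
#' predictions bit-identically on the same platform.
#'
#' @param model A `pathnn_model`.
#' @param path File path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
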