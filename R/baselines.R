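#' Variant-granularity design matrix
#'
#' Builds the `n_samples x n_variants` count matrix the additive and
#' variants-mode random-forest baselines consume. Columns are the distinct
#' variant keys emitted by the table: `(gene, class, variant_id)` when a
#' `variant_id` column is present, `(gene, class)` otherwise.
#'
#' @param table A `variant_table`.
#' @param samples Optional sample order (defaults to sorted unique ids).
#' @return A sparse `dgCMatrix` with sample rownames and key colnames.
#' @export
variant_matrix <- function(table, samples = NULL) {
  dt <- data.table::as.data.table(unclass(table))
  if (is.null(samples)) samples <- sort(unique(dt$sample_id))
  key <- if ("variant_id" %in% names(dt)) {
    paste(dt$gene_id, dt$functional_class, dt$variant_id, sep = ":")
  } else {
    paste(dt$gene_id, dt$functional_class, sep = ":")
  }
  cols <- sort(unique(key))
  Matrix::sparseMatrix(i = match(dt$sample_id, samples),
                       j = match(key, cols),
                       x = 1,
                       dims = c(length(samples), length(cols)),
                       dimnames = list(samples, cols))
}

#' Additive baseline: penalized logistic regression on individual variants
#'
#' A regularized logistic model over the variant matrix (L1 or L2 penalty),
#' fitted at a single penalty strength. Its decision score is affine in the
#' input, so it represents additive genetic architectures only.
#'
#' @param X Variant matrix (`dgCMatrix` or matrix), binary or count-valued.
#' @param y Binary labels.
#' @param penalty `"L2"` (default) or `"L1"`.
#' @param strength Penalty weight (glmnet `lambda`).
#' @param seed Unused by the deterministic fit; kept for the factory
#'   contract.
#' @return A `pathnn_baseline` supporting [predict_proba()];
#'   `$n_parameters` is `n_variants + 1`.
#' @export
additive_baseline <- function(X, y, penalty = c("L2", "L1"), strength = 0.01,
                              seed = 1) {
  penalty <- match.arg(penalty)
  y <- as.numeric(y)
  if (length(unique(y)) < 2)
    stop("both classes must be present", call. = FALSE)
  fit <- glmnet::glmnet(X, y, family = "binomial",
                        alpha = if (penalty == "L1") 1 else 0,
                        lambda = strength, standardize = TRUE)
  structure(list(fit = fit, penalty = penalty, strength = strength,
                 n_parameters = ncol(X) + 1L, kind = "additive",
                 colnames = colnames(X)),
            class = "pathnn_baseline")
}

#' Random-forest baseline
#'
#' Three input modes following the comparison suite: the raw variant matrix
#' (`"variants"`), the per-gene total mutational load (`"summed_gene_vectors"`,
#' an `n x n_genes` matrix of class-summed counts; set
#' `flatten_histograms = TRUE` for the `n x (n_genes*C)` per-class variant),
#' or the gene activations G_i extracted from a trained network
#' (`"learned_gene_activations"`).
#'
#' @param input_mode One of the three modes above.
#' @param X `variants`: a variant matrix; `summed_gene_vectors`: a raw-count
#'   `gene_tensor`; `learned_gene_activations`: a standardized
#'   `gene_tensor`.
#' @param y Binary labels.
#' @param model A trained `pathnn_model` (required for
#'   `learned_gene_activations`).
#' @param num_trees,max_depth Forest size and depth (defaults follow the
#'   comparison protocol: 1000/1000 for variants, 10000/3 otherwise; scale
#'   down for desk work).
#' @param flatten_histograms Keep the per-class histograms instead of
#'   summing them (only `summed_gene_vectors`).
#' @param seed Integer seed.
#' @return A `pathnn_baseline` supporting [predict_proba()].
#' @export
rf_baseline <- function(input_mode = c("variants", "summed_gene_vectors",
                                       "learned_gene_activations"),
                        X, y, model = NULL,
                        num_trees = NULL, max_depth = NULL,
                        flatten_histograms = FALSE, seed = 1) {
  input_mode <- match.arg(input_mode)
  feats <- rf_features(input_mode, X, model, flatten_histograms)
  num_trees <- num_trees %||% if (input_mode == "variants") 1000 else 10000
  max_depth <- max_depth %||% if (input_mode == "variants") 1000 else 3
  df <- as.data.frame(as.matrix(feats))
  names(df) <- paste0("f", seq_along(df))
  df$.y <- factor(y, levels = c(0, 1))
  fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                        num.trees = num_trees, max.depth = max_depth,
                        probability = TRUE, seed = seed,
                        num.threads = 1)
  structure(list(fit = fit, input_mode = input_mode, model = model,
                 flatten_histograms = flatten_histograms, kind = "rf"),
            class = "pathnn_baseline")
}

rf_features <- function(input_mode, X, model, flatten_histograms) {
  switch(input_mode,
    variants = {
      if (inherits(X, "gene_tensor"))
        stop("variants mode expects a variant matrix, not a gene tensor",
             call. = FALSE)
      X
    },
    summed_gene_vectors = {
      if (!inherits(X, "gene_tensor"))
        stop("summed_gene_vectors mode expects a gene_tensor", call. = FALSE)
      d <- dim(X$counts)
      if (flatten_histograms) matrix(X$counts, d[1], d[2] * d[3])
      else rowSums(X$counts, dims = 2)
    },
    learned_gene_activations = {
      if (!inherits(model, "pathnn_model"))
        stop("learned_gene_activations mode needs a trained model",
             call. = FALSE)
      gene_activations(model, X)
    })
}

#' @rdname predict_proba
#' @export
predict_proba.pathnn_baseline <- function(model, X, ...) {
  if (model$kind == "additive") {
    p <- predict(model$fit, newx = X, type = "response")[, 1]
  } else {
    feats <- rf_features(model$input_mode, X, model$model,
                         model$flatten_histograms)
    df <- as.data.frame(as.matrix(feats))
    names(df) <- paste0("f", seq_along(df))
    p <- predict(model$fit, data = df,
                 num.threads = 1)$predictions[, "1"]
  }
  p <- pmin(pmax(as.numeric(p), 1e-7), 1 - 1e-7)
  nms <- if (inherits(X, "gene_tensor")) X$sample_ids else rownames(X)
  if (!is.null(nms)) names(p) <- nms
  p
}

#' @export
print.pathnn_baseline <- function(x, ...) {
  cat(sprintf("<pathnn_baseline> %s\n",
              if (x$kind == "additive")
                sprintf("%s-penalized logistic regression (%d parameters)",
                        x$penalty, x$n_parameters)
              else sprintf("random forest on %s", x$input_mode)))
  invisible(x)
}

#' Factory wrapper for the additive baseline over a gene tensor
#'
#' Lets the CV harness evaluate the additive variant-level baseline on the
#' same splits as the networks: the factory receives the fold's
#' (standardized) tensor but fits on the corresponding rows of the
#' precomputed variant matrix.
#'
#' @param V Variant matrix for the full cohort (rows = samples).
#' @param penalty,strength See [additive_baseline()].
#' @return A model factory closure.
#' @export
additive_factory <- function(V, penalty = "L2", strength = 0.01) {
  force(V)
  function(X_train, y_train, seed) {
    ids <- if (inherits(X_train, "gene_tensor")) X_train$sample_ids
           else rownames(X_train)
    fit <- additive_baseline(V[ids, , drop = FALSE], y_train,
                             penalty = penalty, strength = strength,
                             seed = seed)
    structure(list(fit = fit, V = V), class = "additive_on_tensor")
  }
}

#' @rdname predict_proba
#' @export
predict_proba.additive_on_tensor <- function(model, X, ...) {
  ids <- if (inherits(X, "gene_tensor")) X$sample_ids else rownames(X)
  predict_proba(model$fit, model$V[ids, , drop = FALSE])
}

#' Factory wrapper for an additive baseline on per-gene total burden
#'
#' An alternative additive contender fit on the `n x n_genes` matrix of
#' class-summed variant counts (the per-gene total mutational load), so the
#' additive model class is compared on the same gene-centric footing as the
#' networks.
#'
#' @param penalty,strength See [additive_baseline()].
#' @return A model factory closure.
#' @export
burden_additive_factory <- function(penalty = "L2", strength = 0.01) {
  function(X_train, y_train, seed) {
    stopifnot(inherits(X_train, "gene_tensor"))
    raw <- if (X_train$standardized) inverse_standardize(X_train) else X_train
    b <- rowSums(raw$counts, dims = 2)
    colnames(b) <- raw$gene_ids
    fit <- additive_baseline(b, y_train, penalty = penalty,
                             strength = strength, seed = seed)
    structure(list(fit = fit), class = "burden_additive")
  }
}

#' @rdname predict_proba
#' @export
predict_proba.burden_additive <- function(model, X, ...) {
  raw <- if (X$standardized) inverse_standardize(X) else X
  b <- rowSums(raw$counts, dims = 2)
  colnames(b) <- raw$gene_ids
  predict_proba(model$fit, b)
}
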