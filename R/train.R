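#' Training configuration
#'
#' Defaults follow the study protocol for this model family: Adam with
#' learning rate 0.001, batch size 128, a weighted focal binary
#' cross-entropy loss with gamma = 2 and alpha computed from the class
#' counts of the training labels, and a fixed epoch budget (per-architecture
#' defaults within 20-75 when `epochs = NULL`).
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param epochs Number of epochs (`NULL` = per-architecture default).
#' @param focal_alpha Case-term weight in (0,1); `NULL` = computed from the
#'   training label counts via [focal_alpha_from_counts()].
#' @param focal_gamma Focusing exponent (>= 0).
#' @param weight_decay L2 penalty on weights.
#' @param dropout_gene,dropout_hidden Dropout rates after the gene-neuron
#'   layer and after the hidden layer.
#' @param seed Integer seed (initial shuffle order and dropout).
#' @param log_path Optional path for a JSON-lines training log (one record
#'   per epoch).
#' @return A `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 128,
                         epochs = NULL, focal_alpha = NULL, focal_gamma = 2,
                         weight_decay = 0, dropout_gene = 0,
                         dropout_hidden = 0, seed = 1, log_path = NULL) {
  if (!is.null(focal_alpha))
    assert_that(focal_alpha > 0 && focal_alpha < 1,
                "focal_alpha must be in (0,1)")
  assert_that(focal_gamma >= 0, "focal_gamma must be >= 0")
  if (!is.null(epochs)) assert_that(epochs >= 1, "epochs must be >= 1")
  assert_that(batch_size >= 1, "batch_size must be >= 1")
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 epochs = epochs, focal_alpha = focal_alpha,
                 focal_gamma = focal_gamma, weight_decay = weight_decay,
                 dropout_gene = dropout_gene, dropout_hidden = dropout_hidden,
                 seed = as.integer(seed), log_path = log_path),
            class = "train_config")
}

# per-architecture epoch budgets (within the 20-75 range of the training
# protocol); heads with a single path from each gene to the output converge
# slowest and get the largest budgets
default_epochs <- function(kind) {
  switch(kind, logreg = 50L, biosparse = 50L, linear = 30L, dense = 30L,
         multiconnect = 50L, stacked_interactome = 50L, 30L)
}

#' Focal-loss alpha from cohort composition
#'
#' The case-term weight is the control fraction of the cohort,
#' `alpha = n_controls / (n_controls + n_cases)`, so the majority class
#' (cases, in an enriched case-control cohort) is down-weighted. For the
#' motivating cohort composition of 480 controls and 3318 cases this gives
#' 0.12638 (to 5 decimals).
#'
#' @param n_controls,n_cases Positive class counts.
#' @return `alpha` in (0,1) at full precision (display rounds to 5 decimals).
#' @export
focal_alpha_from_counts <- function(n_controls, n_cases) {
  if (!(n_controls > 0 && n_cases > 0))
    stop("both class counts must be positive", call. = FALSE)
  structure(n_controls / (n_controls + n_cases), class = "focal_alpha")
}

#' @export
print.focal_alpha <- function(x, ...) {
  cat(sprintf("focal alpha = %.5f\n", unclass(x)))
  invisible(x)
}

#' Weighted focal binary cross-entropy
#'
#' Per-sample loss `-w_y * (1 - p_t)^gamma * log(p_t)` with `p_t = p` for
#' cases and `1 - p` for controls, and class weights `w_1 = alpha`,
#' `w_0 = 1 - alpha`; returns the mean over samples. Probabilities are
#' clamped 1e-7 away from the boundaries for numerical stability. With
#' `gamma = 0` and `alpha = 0.5` this is exactly half the standard binary
#' cross-entropy.
#'
#' @param p Predicted case probabilities.
#' @param y Labels in \{0, 1\}.
#' @param alpha Case-term weight in (0,1).
#' @param gamma Focusing exponent (>= 0).
#' @return Mean scalar loss.
#' @export
focal_loss <- function(p, y, alpha, gamma = 2) {
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  stopifnot(length(p) == length(y))
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  pt <- ifelse(y == 1, p, 1 - p)
  w <- ifelse(y == 1, alpha, 1 - alpha)
  mean(-w * (1 - pt)^gamma * log(pt))
}

resolve_cfg <- function(cfg, model, y) {
  epochs <- cfg$epochs %||% default_epochs(model$head$kind)
  alpha <- cfg$focal_alpha %||%
    as.numeric(focal_alpha_from_counts(sum(y == 0), sum(y == 1)))
  list(learning_rate = cfg$learning_rate,
       batch_size = as.integer(min(cfg$batch_size, length(y))),
       epochs = as.integer(epochs),
       focal_alpha = alpha, focal_gamma = cfg$focal_gamma,
       weight_decay = cfg$weight_decay,
       dropout_gene = cfg$dropout_gene, dropout_hidden = cfg$dropout_hidden,
       l1_head = 0, clamp = 1e-7, seed = cfg$seed)
}

#' Train a model with Adam and the focal loss
#'
#' Runs `epochs` passes over seeded shuffled mini-batches; standardization
#' must have been fit on the training data only. Fixed `(seed, data)` gives
#' an identical loss history on the same platform. Epoch `e` with batch size
#' `b` performs exactly `ceiling(n / b)` optimizer steps.
#'
#' @param model A `pathnn_model`.
#' @param X Standardized training `gene_tensor`.
#' @param y Binary labels (0 = control, 1 = case).
#' @param cfg A [train_config()].
#' @param l1_head Internal: L1 penalty on the gene-pathway layer weights
#'   (used by [l1_learned_mask()]).
#' @param rigl Internal: RigL configuration (used by [rigl_train()]).
#' @return The trained model; the per-epoch mean training loss is in
#'   `$history` and the optimizer step count in `$n_steps`.
#' @export
train <- function(model, X, y, cfg = train_config(), l1_head = 0,
                  rigl = NULL) {
  stopifnot(inherits(model, "pathnn_model"), inherits(cfg, "train_config"))
  check_tensor_for_model(model, X)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  n <- dim(X$counts)[1]
  stopifnot(length(y) == n)
  ccfg <- resolve_cfg(cfg, model, y)
  ccfg$l1_head <- l1_head
  perm <- with_seed(ccfg$seed, {
    t(vapply(seq_len(ccfg$epochs), function(e) sample.int(n) - 1L,
             integer(n)))
  })
  riglcfg <- rigl %||% list(enabled = FALSE)
  # genes with mask degree 0 are structurally dropped: their gene-pathway
  # weights are pinned at zero, so they cannot influence the score and are
  # excluded from the computation (not from the model's vocabulary)
  active <- NULL
  params <- model$params
  arch <- arch_list(model)
  Xc <- X$counts
  if (model$head_kind == 1L && !isTRUE(riglcfg$enabled) && l1_head == 0) {
    deg <- rowSums(model$M)
    if (any(deg == 0) && any(deg > 0)) {
      active <- which(deg > 0)
      arch$M <- model$M[active, , drop = FALSE]
      params$U <- params$U[active, , drop = FALSE]
      Xc <- Xc[, active, , drop = FALSE]
    }
  }
  d <- dim(Xc)
  Xmat <- matrix(as.numeric(Xc), d[1] * d[2], d[3])
  fit <- nn_train_cpp(Xmat, y, n, d[2], params, arch, ccfg, perm, riglcfg)
  # vector-shaped parameters come back as one-column matrices
  for (nm in intersect(names(fit$params), c("b1", "w2", "v", "bh", "w",
                                            "bgg")))
    fit$params[[nm]] <- as.numeric(fit$params[[nm]])
  if (!is.null(active)) {
    full <- model$params
    full$W1 <- fit$params$W1; full$b1 <- fit$params$b1
    full$w2 <- fit$params$w2; full$b2 <- fit$params$b2
    full$U[active, ] <- fit$params$U
    full$U[-active, ] <- 0
    full$bh <- fit$params$bh; full$w <- fit$params$w; full$c <- fit$params$c
    model$params <- full
  } else {
    model$params <- fit$params
  }
  model$history <- as.numeric(fit$history)
  model$n_steps <- fit$n_steps
  if (isTRUE(riglcfg$enabled)) {
    M <- fit$mask
    dimnames(M) <- dimnames(model$M)
    model$M <- M
  }
  model$trained <- TRUE
  model$train_cfg <- ccfg
  if (!is.null(cfg$log_path)) {
    con <- file(cfg$log_path, open = "w")
    on.exit(close(con))
    t0 <- Sys.time()
    for (e in seq_along(model$history))
      writeLines(jsonlite::toJSON(list(epoch = e,
                                       mean_loss = model$history[e],
                                       wall_time = as.numeric(Sys.time() - t0)),
                                  auto_unbox = TRUE, digits = NA), con)
  }
  model
}

#' RigL configuration
#'
#' Dynamic sparse training of the gene-pathway layer: at fixed intervals the
#' lowest-magnitude fraction of active connections is dropped and the same
#' number of inactive connections with the largest loss-gradient magnitude
#' is grown, so the connection count is invariant throughout. Defaults follow
#' the original recipe: cosine-annealed drop fraction (initial 0.3), an
#' update every 100 steps, updates stopping at 75% of training.
#'
#' @param update_interval Optimizer steps between mask updates.
#' @param drop_fraction Initial drop fraction in \[0, 1).
#' @param stop_iteration Step after which the mask is frozen (`NULL` = 75%
#'   of the total step budget).
#' @return A `rigl_config`.
#' @export
rigl_config <- function(update_interval = 100, drop_fraction = 0.3,
                        stop_iteration = NULL) {
  if (!(drop_fraction >= 0 && drop_fraction < 1))
    stop("drop_fraction must be in [0, 1)", call. = FALSE)
  structure(list(update_interval = as.integer(update_interval),
                 drop_fraction = drop_fraction,
                 stop_iteration = stop_iteration),
            class = "rigl_config")
}

#' Train with RigL mask learning
#'
#' @param model A `pathnn_model` with a sparse gene-pathway layer carrying an
#'   initial mask.
#' @param X Standardized training `gene_tensor`.
#' @param y Binary labels.
#' @param cfg A [train_config()].
#' @param rigl A [rigl_config()].
#' @return `list(model = trained model, mask = final sparsity_mask)`.
#' @export
rigl_train <- function(model, X, y, cfg = train_config(),
                       rigl = rigl_config()) {
  stopifnot(inherits(rigl, "rigl_config"))
  if (model$head_kind == 0L)
    stop("RigL needs a model with a gene-pathway layer", call. = FALSE)
  n <- dim(X$counts)[1]
  epochs <- cfg$epochs %||% default_epochs(model$head$kind)
  total_steps <- epochs * ceiling(n / min(cfg$batch_size, n))
  stop_it <- rigl$stop_iteration %||% floor(0.75 * total_steps)
  riglcfg <- list(enabled = TRUE, update_interval = rigl$update_interval,
                  stop_iteration = as.integer(stop_it),
                  drop_fraction = rigl$drop_fraction)
  model <- train(model, X, y, cfg, rigl = riglcfg)
  list(model = model,
       mask = sparsity_mask(model$M, "rigl", cfg$seed))
}
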