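#' ROC AUC by the rank (Mann-Whitney) construction
#'
#' Equals the probability that a random case scores above a random control,
#' with ties counted 1/2; invariant under strictly increasing transforms of
#' the scores.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (both classes must be present).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present to compute ROC AUC", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified fold assignments for repeated k-fold cross-validation
#'
#' Deterministic in `(y, k, reps, base_seed)`: two model factories evaluated
#' with the same arguments receive identical splits. Per class, a seeded
#' permutation is dealt round-robin over folds, so each test fold's class
#' proportions are within one sample of the global proportions.
#'
#' @param y Binary labels.
#' @param k Folds.
#' @param reps Repetitions.
#' @param base_seed Repetition `r` uses seed `base_seed + r - 1`.
#' @return List of `reps` integer vectors of fold ids in `1..k`.
#' @export
make_cv_splits <- function(y, k = 3, reps = 10, base_seed = 1) {
  y <- as.numeric(y)
  if (min(sum(y == 0), sum(y == 1)) < k)
    stop("each class needs at least k samples to stratify", call. = FALSE)
  lapply(seq_len(reps), function(r) {
    folds <- integer(length(y))
    with_seed(base_seed + r - 1, {
      for (cl in c(0, 1)) {
        idx <- which(y == cl)
        idx <- idx[sample.int(length(idx))]
        folds[idx] <- rep_len(seq_len(k), length(idx))
      }
    })
    folds
  })
}

prepare_fold <- function(X, tr, te) {
  if (inherits(X, "gene_tensor")) {
    Xtr <- subset_samples(X, tr)
    st <- fit_standardization(Xtr)
    list(train = standardize(Xtr, st),
         test = standardize(subset_samples(X, te), st))
  } else {
    list(train = X[tr, , drop = FALSE], test = X[te, , drop = FALSE])
  }
}

#' Repeated stratified k-fold cross-validation
#'
#' The protocol used throughout: `reps` repetitions of stratified k-fold CV
#' with per-training-fold refitting of the standardization statistics, and
#' splits that are identical across model factories for a given
#' `(y, k, reps, base_seed)`.
#'
#' @param model_factory `function(X_train, y_train, seed)` returning a
#'   fitted object that supports [predict_proba()], or a named list of such
#'   factories. For `gene_tensor` input each factory receives a tensor
#'   standardized with training-fold statistics; matrix input is passed
#'   through unchanged. Supplying a list evaluates every factory on the
#'   same folds (and the same per-fold standardization), which is also how
#'   identical splits across models are guaranteed.
#' @param X A `gene_tensor`, matrix or `Matrix` of predictors
#'   (unstandardized).
#' @param y Binary labels.
#' @param k,reps,base_seed See [make_cv_splits()].
#' @param tag Optional model label carried into the result.
#' @return A `cv_result` (or, for a factory list, a named list of them):
#'   the `reps x k` matrix of test-fold AUCs with its mean and sd, the
#'   split seeds, and the fold sizes used by [corrected_t_test()].
#' @export
repeated_stratified_cv <- function(model_factory, X, y, k = 3, reps = 10,
                                   base_seed = 1, tag = NULL) {
  y <- as.numeric(y)
  listed <- is.list(model_factory) && !is.function(model_factory)
  factories <- if (listed) model_factory else list(model = model_factory)
  if (listed) stopifnot(!is.null(names(factories)))
  splits <- make_cv_splits(y, k, reps, base_seed)
  n <- length(y)
  auc <- lapply(factories, function(.) matrix(NA_real_, reps, k))
  for (r in seq_len(reps)) {
    folds <- splits[[r]]
    for (f in seq_len(k)) {
      te <- which(folds == f)
      tr <- which(folds != f)
      fold <- prepare_fold(X, tr, te)
      for (nm in names(factories)) {
        fit <- factories[[nm]](fold$train, y[tr],
                               seed = base_seed + (r - 1) * k + f - 1)
        auc[[nm]][r, f] <- roc_auc(predict_proba(fit, fold$test), y[te])
      }
    }
  }
  out <- lapply(names(factories), function(nm)
    structure(list(auc = auc[[nm]], mean = mean(auc[[nm]]),
                   sd = sd(as.numeric(auc[[nm]])),
                   k = k, reps = reps, base_seed = base_seed,
                   n_train = n - floor(n / k), n_test = floor(n / k),
                   model = if (listed) nm else tag %||% "model"),
              class = "cv_result"))
  names(out) <- names(factories)
  if (listed) out else out[[1]]
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: mean AUC %.4f (sd %.4f) over %d x %d-fold CV\n",
              x$model, x$mean, x$sd, x$reps, x$k))
  invisible(x)
}

#' @export
as.data.frame.cv_result <- function(x, ...) {
  data.frame(model = x$model,
             rep = rep(seq_len(x$reps), x$k),
             fold = rep(seq_len(x$k), each = x$reps),
             auc = as.numeric(x$auc))
}

#' Variance-corrected resampled t-test for cross-validated AUCs
#'
#' Paired two-sided t-test on the `reps x k` AUC differences, with the
#' variance inflated by the train/test overlap correction: with `m = reps*k`
#' measurements, `t = mean(d) / sqrt((1/m + n_test/n_train) * var(d))` and a
#' Student-t null with `m - 1` degrees of freedom. This counteracts the
#' optimistic variance of naive resampled t-tests whose folds share training
#' samples.
#'
#' @param auc_a,auc_b `cv_result`s (or plain matrices) produced on identical
#'   splits.
#' @param n_train,n_test Fold sizes; taken from `auc_a` when it is a
#'   `cv_result`.
#' @return List with `t`, two-sided `p`, `df`, the correction factor and a
#'   `degenerate` flag (variance zero with nonzero mean is reported as
#'   `p = 0` with the flag set).
#' @export
corrected_t_test <- function(auc_a, auc_b, n_train = NULL, n_test = NULL) {
  if (inherits(auc_a, "cv_result")) {
    n_train <- n_train %||% auc_a$n_train
    n_test <- n_test %||% auc_a$n_test
    auc_a <- auc_a$auc
  }
  if (inherits(auc_b, "cv_result")) auc_b <- auc_b$auc
  if (!all(dim(auc_a) == dim(auc_b)))
    stop("AUC matrices must have identical shape", call. = FALSE)
  stopifnot(!is.null(n_train), !is.null(n_test))
  d <- as.numeric(auc_a) - as.numeric(auc_b)
  m <- length(d)
  corr <- 1 / m + n_test / n_train
  v <- var(d)
  if (v == 0) {
    if (mean(d) == 0)
      return(list(t = 0, p = 1, df = m - 1, correction = corr,
                  degenerate = FALSE))
    return(list(t = sign(mean(d)) * Inf, p = 0, df = m - 1,
                correction = corr, degenerate = TRUE))
  }
  tstat <- mean(d) / sqrt(corr * v)
  list(t = tstat, p = 2 * pt(-abs(tstat), df = m - 1), df = m - 1,
       correction = corr, degenerate = FALSE)
}

#' Learning curve over nested stratified subsets
#'
#' Per fraction, draws a stratified subset of the data (subsets are nested
#' across fractions for a given seed: the 20% subset is contained in the
#' 40% one) and runs [repeated_stratified_cv()] with identical splits for
#' every factory. Fraction 1.0 reproduces CV on the full data exactly.
#'
#' @param model_factories Named list of factories (see
#'   [repeated_stratified_cv()]).
#' @param X Predictors (`gene_tensor` or matrix).
#' @param y Binary labels.
#' @param fractions Increasing fractions in (0, 1].
#' @param k,reps,base_seed CV parameters.
#' @return A `learning_curve`: per-fraction, per-model `cv_result`s plus a
#'   long-format data frame (`model`, `fraction`, `rep`, `fold`, `auc`) and
#'   the subset indices.
#' @export
learning_curve <- function(model_factories, X, y,
                           fractions = c(0.1, 0.2, 0.4, 0.6, 0.8, 1.0),
                           k = 3, reps = 10, base_seed = 1) {
  stopifnot(is.list(model_factories), length(names(model_factories)) ==
              length(model_factories))
  y <- as.numeric(y)
  ord0 <- with_seed(base_seed, which(y == 0)[sample.int(sum(y == 0))])
  ord1 <- with_seed(base_seed + 1, which(y == 1)[sample.int(sum(y == 1))])
  subset_idx <- function(frac) {
    sort(c(ord0[seq_len(ceiling(frac * length(ord0)))],
           ord1[seq_len(ceiling(frac * length(ord1)))]))
  }
  if (min(ceiling(min(fractions) * c(length(ord0), length(ord1)))) < k)
    stop("smallest fraction leaves fewer than k samples in a class",
         call. = FALSE)
  results <- list()
  rows <- list()
  subsets <- list()
  for (fr in fractions) {
    idx <- subset_idx(fr)
    subsets[[as.character(fr)]] <- idx
    Xs <- if (inherits(X, "gene_tensor")) subset_samples(X, idx)
          else X[idx, , drop = FALSE]
    ys <- y[idx]
    cvs <- repeated_stratified_cv(model_factories, Xs, ys, k = k,
                                  reps = reps, base_seed = base_seed)
    for (nm in names(model_factories)) {
      results[[as.character(fr)]][[nm]] <- cvs[[nm]]
      df <- as.data.frame(cvs[[nm]])
      df$fraction <- fr
      rows[[length(rows) + 1]] <- df
    }
  }
  structure(list(fractions = fractions, results = results,
                 table = do.call(rbind, rows), subsets = subsets),
            class = "learning_curve")
}

#' @export
print.learning_curve <- function(x, ...) {
  cat("<learning_curve>\n")
  agg <- stats::aggregate(auc ~ model + fraction, data = x$table, FUN = mean)
  print(utils::type.convert(agg, as.is = TRUE))
  invisible(x)
}

#' Write a CV result or learning curve as long-format TSV
#' @param x A `cv_result` or `learning_curve`.
#' @param path Output path.
#' @export
write_result_tsv <- function(x, path) {
  df <- if (inherits(x, "learning_curve")) x$table else as.data.frame(x)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Convenience model factory for the neural architectures
#'
#' Wraps a gene-module spec, a head spec and a training configuration into
#' the `function(X_train, y_train, seed)` contract used by the CV harness;
#' `seed` controls both initialization and shuffling for that fold.
#'
#' @param gm A [gene_module_spec()].
#' @param head A [head_spec()] (shared across folds; for mask-based heads
#'   the mask is fixed, as the wiring is part of the architecture).
#' @param cfg A [train_config()].
#' @param max_retries A run whose final training loss is within 5% of its
#'   initial loss has not left its starting basin (a rare initialization
#'   pathology of the deeper heads); such runs are restarted with a shifted
#'   seed, at most this many times. Detection uses the training loss only.
#' @return A model factory closure.
#' @export
nn_factory <- function(gm, head, cfg = train_config(), max_retries = 2) {
  force(gm); force(head); force(cfg); force(max_retries)
  function(X_train, y_train, seed) {
    for (try in 0:max_retries) {
      s <- as.integer(seed + try * 9973L)
      model <- build_model(gm, head, gene_ids = X_train$gene_ids,
                           classes = X_train$classes, seed = s)
      cfg$seed <- s
      model <- train(model, X_train, y_train, cfg)
      h <- model$history
      if (tail(h, 1) < 0.95 * h[1] || try == max_retries) return(model)
    }
  }
}
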