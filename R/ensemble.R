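#' Ensemble of randomly sparsified networks
#'
#' Trains `n_members` networks that differ only in their random degree-1
#' gene-pathway wiring (member `i` uses `random_mask(seed = base_seed + i)`)
#' and in their initialization/shuffle seeds; all members are trained on the
#' identical training set and their predicted probabilities are averaged.
#'
#' @param X Standardized training `gene_tensor`.
#' @param y Binary labels.
#' @param n_members Number of members (default 100).
#' @param gene_fraction Fraction of genes connected in each member's mask.
#' @param n_hidden Hidden units per member.
#' @param gm A [gene_module_spec()].
#' @param train_cfg A [train_config()].
#' @param base_seed Member `i` uses seed `base_seed + i`.
#' @param aggregate `"probability"` (default: arithmetic mean of member
#'   probabilities) or `"logit"` (mean on the logit scale).
#' @return A `pathnn_ensemble`.
#' @export
train_ensemble <- function(X, y, n_members = 100, gene_fraction = 1,
                           n_hidden = 20,
                           gm = gene_module_spec(input_dim =
                                                   length(X$classes)),
                           train_cfg = train_config(),
                           base_seed = 1,
                           aggregate = c("probability", "logit")) {
  aggregate <- match.arg(aggregate)
  stopifnot(n_members >= 1)
  G <- length(X$gene_ids)
  members <- vector("list", n_members)
  for (i in seq_len(n_members)) {
    seed_i <- base_seed + i
    mask <- random_mask(G, n_hidden, gene_fraction, seed = seed_i,
                        gene_ids = X$gene_ids)
    model <- build_model(gm, head_spec("biosparse", mask = mask),
                         gene_ids = X$gene_ids, classes = X$classes,
                         seed = seed_i)
    cfg <- train_cfg
    cfg$seed <- as.integer(seed_i)
    members[[i]] <- tryCatch(train(model, X, y, cfg),
                             error = function(e)
                               stop("ensemble member ", i, " failed: ",
                                    conditionMessage(e), call. = FALSE))
  }
  structure(list(members = members, n_members = n_members,
                 gene_fraction = gene_fraction, n_hidden = n_hidden,
                 base_seed = base_seed, aggregate = aggregate,
                 gene_ids = X$gene_ids, classes = X$classes),
            class = "pathnn_ensemble")
}

#' @export
print.pathnn_ensemble <- function(x, ...) {
  cat(sprintf(
    "<pathnn_ensemble> %d randomly sparsified members (%.0f%% genes, %d hidden)\n",
    x$n_members, 100 * x$gene_fraction, x$n_hidden))
  invisible(x)
}

#' @rdname predict_proba
#' @export
predict_proba.pathnn_ensemble <- function(model, X, ...) {
  preds <- vapply(model$members, function(m) predict_proba(m, X),
                  numeric(dim(X$counts)[1]))
  preds <- matrix(preds, nrow = dim(X$counts)[1])
  out <- if (model$aggregate == "logit") {
    1 / (1 + exp(-rowMeans(log(preds / (1 - preds)))))
  } else {
    rowMeans(preds)
  }
  stats::setNames(out, X$sample_ids)
}

#' Average the member predictions of an ensemble
#' @param ens A `pathnn_ensemble`.
#' @param X A standardized `gene_tensor`.
#' @return Probabilities per sample.
#' @export
predict_ensemble <- function(ens, X) predict_proba(ens, X)

#' Save / load an ensemble checkpoint
#'
#' A directory of member checkpoints (`member_<i>.rds`) plus a
#' `manifest.json` with seeds, gene fraction and hidden width.
#'
#' @param ens A `pathnn_ensemble`.
#' @param dir Directory path (created if needed).
#' @export
save_ensemble <- function(ens, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(ens$n_members))
    save_model(ens$members[[i]], file.path(dir, sprintf("member_%03d.rds", i)))
  jsonlite::write_json(list(n_members = ens$n_members,
                            gene_fraction = ens$gene_fraction,
                            n_hidden = ens$n_hidden,
                            base_seed = ens$base_seed,
                            aggregate = ens$aggregate,
                            gene_ids = ens$gene_ids,
                            classes = unclass(ens$classes)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  members <- lapply(seq_len(man$n_members), function(i)
    load_model(file.path(dir, sprintf("member_%03d.rds", i))))
  structure(list(members = members, n_members = man$n_members,
                 gene_fraction = man$gene_fraction, n_hidden = man$n_hidden,
                 base_seed = man$base_seed, aggregate = man$aggregate,
                 gene_ids = man$gene_ids,
                 classes = class_vocabulary(man$classes)),
            class = "pathnn_ensemble")
}
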