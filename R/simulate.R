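#' Simulator configuration for synthetic case-control cohorts
#'
#' Generates cohorts with the statistical structure the architecture family
#' is designed to probe: per-gene mutational-load counts with an additive
#' liability component plus two kinds of pairwise epistasis.
#'
#' * **Additive**: each listed gene contributes `beta * z_g`, with `z_g` the
#'   gene burden centered/scaled by its theoretical count moments.
#' * **Magnitude (positive/negative) epistasis**: a saturating ridge
#'   interaction `effect * tanh(kappa * (z_i + z_j -/+ ridge_shift))`,
#'   monotone in both burdens and exactly representable by a single tanh
#'   hidden neuron fed by the two genes; the shift places the pair in the
#'   convex (`positive`, superadditive) or concave (`negative`, subadditive)
#'   region of the tanh.
#' * **Reciprocal sign epistasis**: `effect * XOR(b_i > tau, b_j > tau)`, a
#'   nonlinearly separable pattern no single monotone ridge unit can model.
#'
#' Liability = sum of the terms + Gaussian noise; case labels are assigned by
#' thresholding the realized liability at the quantile matching the
#' prevalence target.
#'
#' @param n_samples,n_genes Cohort dimensions.
#' @param n_pathways Number of real pathways (>= 1; the dummy is extra).
#' @param classes Functional-class vocabulary (default C = 16).
#' @param rate Poisson rate per (gene, class): scalar or `n_genes x C`
#'   matrix.
#' @param prevalence Case-fraction target in (0, 1); the default mirrors an
#'   enriched case-control cohort of 3318 cases among 3798 samples where
#'   *controls* are the minority (labels are 1 = case = above-threshold
#'   liability; set `prevalence = 480/3798` to make cases the minority
#'   instead - the simulator is agnostic).
#' @param additive Data frame `gene`, `beta` (gene by id or index).
#' @param magnitude_pairs Data frame `gene_i`, `gene_j`, `effect`,
#'   `sign` (`"positive"`/`"negative"`), `same_pathway` (logical).
#' @param sign_pairs Data frame `gene_i`, `gene_j`, `effect`, `tau`
#'   (burden threshold).
#' @param noise_sd Liability noise standard deviation.
#' @param kappa,ridge_shift Sharpness and shift of the magnitude-epistasis
#'   ridge.
#' @param count_model `"poisson"` (default) or `"nbinom"` (overdispersed).
#' @param nb_size Negative-binomial size when `count_model = "nbinom"`.
#' @param seed Integer seed.
#' @return A `sim_config`.
#' @export
sim_config <- function(n_samples, n_genes, n_pathways = 10,
                       classes = annovar_classes(16), rate = 0.1,
                       prevalence = 3318 / 3798,
                       additive = NULL, magnitude_pairs = NULL,
                       sign_pairs = NULL, noise_sd = 1,
                       kappa = 2, ridge_shift = 1,
                       count_model = c("poisson", "nbinom"), nb_size = 10,
                       seed = 1) {
  count_model <- match.arg(count_model)
  assert_that(prevalence > 0 && prevalence < 1, "prevalence must be in (0,1)")
  assert_that(n_pathways >= 1, "need at least one real pathway")
  stopifnot(inherits(classes, "class_vocab"))
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  resolve <- function(ref) {
    if (is.numeric(ref)) {
      assert_that(all(ref >= 1 & ref <= n_genes), "gene index out of range")
      as.integer(ref)
    } else {
      i <- match(as.character(ref), gene_ids)
      assert_that(!anyNA(i), "effect references an unknown gene id")
      i
    }
  }
  if (!is.null(additive)) {
    additive <- data.frame(gene = resolve(additive$gene),
                           beta = as.numeric(additive$beta))
  }
  if (!is.null(magnitude_pairs)) {
    assert_that(all(magnitude_pairs$sign %in% c("positive", "negative")),
                "magnitude-pair sign must be 'positive' or 'negative'")
    magnitude_pairs <- data.frame(
      gene_i = resolve(magnitude_pairs$gene_i),
      gene_j = resolve(magnitude_pairs$gene_j),
      effect = as.numeric(magnitude_pairs$effect),
      sign = as.character(magnitude_pairs$sign),
      same_pathway = as.logical(magnitude_pairs$same_pathway))
  }
  if (!is.null(sign_pairs)) {
    sign_pairs <- data.frame(gene_i = resolve(sign_pairs$gene_i),
                             gene_j = resolve(sign_pairs$gene_j),
                             effect = as.numeric(sign_pairs$effect),
                             tau = as.numeric(sign_pairs$tau))
  }
  if (is.matrix(rate)) {
    stopifnot(nrow(rate) == n_genes, ncol(rate) == length(classes))
  } else {
    stopifnot(length(rate) == 1, rate > 0)
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 n_pathways = as.integer(n_pathways),
                 classes = classes, rate = rate, prevalence = prevalence,
                 additive = additive, magnitude_pairs = magnitude_pairs,
                 sign_pairs = sign_pairs, noise_sd = noise_sd,
                 kappa = kappa, ridge_shift = ridge_shift,
                 count_model = count_model, nb_size = nb_size,
                 seed = as.integer(seed), gene_ids = gene_ids),
            class = "sim_config")
}

rate_matrix <- function(cfg) {
  if (is.matrix(cfg$rate)) cfg$rate
  else matrix(cfg$rate, cfg$n_genes, length(cfg$classes))
}

burden_moments <- function(cfg) {
  R <- rate_matrix(cfg)
  mu <- rowSums(R)
  v <- if (cfg$count_model == "poisson") rowSums(R)
       else rowSums(R + R^2 / cfg$nb_size)
  list(mean = mu, sd = sqrt(v))
}

# noiseless liability from an n x G burden matrix
liability_from_burden <- function(b, cfg) {
  mom <- burden_moments(cfg)
  z <- sweep(sweep(b, 2, mom$mean, "-"), 2, mom$sd, "/")
  score <- numeric(nrow(b))
  if (!is.null(cfg$additive) && nrow(cfg$additive))
    score <- score + as.numeric(z[, cfg$additive$gene, drop = FALSE] %*%
                                  cfg$additive$beta)
  mp <- cfg$magnitude_pairs
  if (!is.null(mp) && nrow(mp)) {
    for (r in seq_len(nrow(mp))) {
      shift <- if (mp$sign[r] == "positive") cfg$ridge_shift else
        -cfg$ridge_shift
      score <- score + mp$effect[r] *
        tanh(cfg$kappa * (z[, mp$gene_i[r]] + z[, mp$gene_j[r]] - shift))
    }
  }
  sp <- cfg$sign_pairs
  if (!is.null(sp) && nrow(sp)) {
    for (r in seq_len(nrow(sp))) {
      score <- score + sp$effect[r] *
        as.numeric(xor(b[, sp$gene_i[r]] > sp$tau[r],
                       b[, sp$gene_j[r]] > sp$tau[r]))
    }
  }
  score
}

build_sim_pathways <- function(cfg) {
  P <- cfg$n_pathways
  pw <- sprintf("pw%02d", seq_len(P))
  assign <- integer(cfg$n_genes) # 0 = unassigned
  nxt <- 1
  take_pw <- function() {
    p <- nxt
    nxt <<- (nxt %% P) + 1
    p
  }
  mp <- cfg$magnitude_pairs
  if (!is.null(mp) && nrow(mp)) {
    for (r in seq_len(nrow(mp))) {
      if (isTRUE(mp$same_pathway[r])) {
        p <- take_pw()
        assign[mp$gene_i[r]] <- p
        assign[mp$gene_j[r]] <- p
      } else {
        assign[mp$gene_i[r]] <- take_pw()
        assign[mp$gene_j[r]] <- take_pw()
      }
    }
  }
  sp <- cfg$sign_pairs
  if (!is.null(sp) && nrow(sp)) {
    for (r in seq_len(nrow(sp))) {
      if (assign[sp$gene_i[r]] == 0) assign[sp$gene_i[r]] <- take_pw()
      if (assign[sp$gene_j[r]] == 0) {
        p <- take_pw()
        if (p == assign[sp$gene_i[r]]) p <- take_pw()
        assign[sp$gene_j[r]] <- p
      }
    }
  }
  for (g in which(assign == 0)) assign[g] <- take_pw()
  sets <- lapply(seq_len(P), function(p) cfg$gene_ids[assign == p])
  names(sets) <- pw
  sets <- sets[vapply(sets, length, integer(1)) > 0]
  finalize_pathway_map(pathway_map(sets), cfg$gene_ids)
}

#' Simulate a case-control cohort
#'
#' @param cfg A [sim_config()].
#' @return A list with the materialized `variant_table`, a named 0/1 `labels`
#'   vector, the simulated `pathway_map` (finalized; one membership per
#'   gene), the `sim_truth` oracle (realized config, liability, noiseless
#'   Bayes score, threshold), and the raw count `tensor`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_samples; G <- cfg$n_genes; C <- length(cfg$classes)
  if (n * min(cfg$prevalence, 1 - cfg$prevalence) < 1)
    stop("prevalence target infeasible at this sample size", call. = FALSE)
  sample_ids <- sprintf("s%05d", seq_len(n))
  R <- rate_matrix(cfg)
  sim <- with_seed(cfg$seed, {
    # counts[s, g, c] ~ Poisson(R[g, c]); same rate for every sample
    lam <- aperm(array(t(R), dim = c(C, G, n)), c(3, 2, 1))
    counts <- if (cfg$count_model == "poisson") {
      array(rpois(n * G * C, lambda = lam), dim = c(n, G, C))
    } else {
      array(stats::rnbinom(n * G * C, mu = lam, size = cfg$nb_size),
            dim = c(n, G, C))
    }
    noise <- rnorm(n, 0, cfg$noise_sd)
    list(counts = counts, noise = noise)
  })
  b <- rowSums(sim$counts, dims = 2)
  bayes <- liability_from_burden(b, cfg)
  liab <- bayes + sim$noise
  thr <- quantile(liab, 1 - cfg$prevalence, type = 1, names = FALSE)
  labels <- as.integer(liab > thr)
  if (all(labels == 0) || all(labels == 1))
    stop("degenerate labeling: prevalence target infeasible for the ",
         "realized liability distribution", call. = FALSE)
  names(labels) <- sample_ids
  tensor <- gene_tensor(sim$counts, sample_ids, cfg$gene_ids, cfg$classes)
  pm <- build_sim_pathways(cfg)
  idx <- which(sim$counts > 0, arr.ind = TRUE)
  reps <- sim$counts[idx]
  table <- variant_table(
    data.frame(sample_id = rep(sample_ids[idx[, 1]], reps),
               gene_id = rep(cfg$gene_ids[idx[, 2]], reps),
               functional_class = rep(unclass(cfg$classes)[idx[, 3]], reps)),
    cfg$classes)
  truth <- structure(list(config = cfg, liability = liab, bayes = bayes,
                          threshold = thr, pathway_map = pm,
                          sample_ids = sample_ids, gene_ids = cfg$gene_ids,
                          prevalence_realized = mean(labels)),
                     class = "sim_truth")
  list(table = table, labels = labels, pathway_map = pm, truth = truth,
       tensor = tensor)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "<sim_truth> %d samples x %d genes; realized prevalence %.3f\n",
    length(x$sample_ids), length(x$gene_ids), x$prevalence_realized))
  invisible(x)
}

#' Oracle (Bayes) score for simulated genotypes
#'
#' The noiseless liability recomputed from the genotypes under the
#' generating architecture; its AUC upper-bounds (in expectation) the AUC
#' any learned model can reach on these labels.
#'
#' @param X A raw-count `gene_tensor` generated under `truth` (or any tensor
#'   with the same gene vocabulary).
#' @param truth A `sim_truth`.
#' @return Per-sample score, named by sample id.
#' @export
bayes_score <- function(X, truth) {
  stopifnot(inherits(X, "gene_tensor"), inherits(truth, "sim_truth"))
  if (X$standardized)
    stop("bayes_score expects raw counts, not a standardized tensor",
         call. = FALSE)
  if (!identical(X$gene_ids, truth$gene_ids))
    stop("gene vocabulary mismatch between tensor and truth", call. = FALSE)
  b <- rowSums(X$counts, dims = 2)
  stats::setNames(liability_from_burden(b, truth$config), X$sample_ids)
}

#' Write a simulated cohort to plain-text files
#'
#' Emits the variant table TSV, a labels TSV (`sample_id`, `label`), a GMT
#' of the simulated pathways and a truth JSON (generating parameters,
#' threshold, realized prevalence).
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_variant_table(sim$table, file.path(dir, "variants.tsv"))
  data.table::fwrite(data.table::data.table(sample_id = names(sim$labels),
                                            label = sim$labels),
                     file.path(dir, "labels.tsv"), sep = "\t")
  write_gmt(sim$pathway_map, file.path(dir, "pathways.gmt"))
  cfg <- sim$truth$config
  jsonlite::write_json(
    list(n_samples = cfg$n_samples, n_genes = cfg$n_genes,
         n_pathways = cfg$n_pathways, rate = cfg$rate,
         prevalence_target = cfg$prevalence,
         prevalence_realized = sim$truth$prevalence_realized,
         noise_sd = cfg$noise_sd, kappa = cfg$kappa,
         ridge_shift = cfg$ridge_shift, seed = cfg$seed,
         threshold = sim$truth$threshold,
         additive = cfg$additive, magnitude_pairs = cfg$magnitude_pairs,
         sign_pairs = cfg$sign_pairs),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
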