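#' Read an annotated variant table
#'
#' Reads a tab-separated table with one row per variant, carrying the sample
#' it was observed in, the gene it was assigned to and its functional class.
#' Repeated (sample, gene, class) rows are legitimate: they are distinct
#' variants that accumulate in the mutational-load histogram.
#'
#' @param path Path to a TSV file with header columns `sample_id`, `gene_id`,
#'   `functional_class`.
#' @param vocab A [class_vocabulary()]; every `functional_class` in the file
#'   must belong to it.
#' @return A `variant_table`: a `data.table` with the three columns above and
#'   the vocabulary attached as attribute `vocab`.
#' @export
read_variant_table <- function(path, vocab) {
  stopifnot(inherits(vocab, "class_vocab"))
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", showProgress = FALSE)
  need <- c("sample_id", "gene_id", "functional_class")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols))
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  dt <- dt[, need, with = FALSE]
  variant_table(dt, vocab)
}

#' Construct a variant table from a data frame
#'
#' @param records Data frame with columns `sample_id`, `gene_id`,
#'   `functional_class`.
#' @param vocab A [class_vocabulary()].
#' @return A `variant_table`.
#' @export
variant_table <- function(records, vocab) {
  stopifnot(inherits(vocab, "class_vocab"))
  dt <- data.table::as.data.table(records)
  need <- c("sample_id", "gene_id", "functional_class")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols))
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(dt$functional_class), unclass(vocab))
  if (length(bad))
    stop("vocabulary error: unknown functional class(es): ",
         paste(bad, collapse = ", "), call. = FALSE)
  data.table::setattr(dt, "vocab", vocab)
  data.table::setattr(dt, "class", c("variant_table", class(dt)))
  dt
}

#' Write a variant table to TSV
#' @param table A `variant_table`.
#' @param path Output path.
#' @export
write_variant_table <- function(table, path) {
  data.table::fwrite(data.table::as.data.table(unclass(table)), path,
                     sep = "\t")
  invisible(path)
}

#' Encode a variant table into the gene-centric mutational-load tensor
#'
#' For each sample and gene, counts how many variants of each functional
#' class map to that gene, yielding an `n_samples x n_genes x C` count array
#' (per sample, each gene is a C-dimensional histogram).
#'
#' @param table A `variant_table`.
#' @param genes Character vector: the gene vocabulary (tensor gene order).
#' @param vocab Class vocabulary; defaults to the table's.
#' @param samples Optional character vector fixing the sample order (samples
#'   with no records get all-zero slices). Defaults to the sorted unique
#'   sample ids in the table.
#' @param drop_unknown_genes If `TRUE`, records for genes outside `genes` are
#'   dropped; otherwise they are an error.
#' @return A `gene_tensor` (see [gene_tensor()]).
#' @export
encode_gene_centric <- function(table, genes, vocab = attr(table, "vocab"),
                                samples = NULL, drop_unknown_genes = FALSE) {
  stopifnot(inherits(vocab, "class_vocab"))
  genes <- as.character(genes)
  dt <- data.table::as.data.table(unclass(table))
  if (is.null(samples)) samples <- sort(unique(dt$sample_id))
  if (nrow(dt)) {
    unknown <- setdiff(unique(dt$gene_id), genes)
    if (length(unknown)) {
      if (!drop_unknown_genes)
        stop("gene(s) not in vocabulary: ",
             paste(head(unknown, 5), collapse = ", "),
             if (length(unknown) > 5) ", ...", call. = FALSE)
      dt <- dt[dt$gene_id %in% genes, ]
    }
    extra_samples <- setdiff(unique(dt$sample_id), samples)
    if (length(extra_samples))
      stop("sample(s) not in the supplied sample list: ",
           paste(head(extra_samples, 5), collapse = ", "), call. = FALSE)
  }
  n <- length(samples); G <- length(genes); C <- length(vocab)
  counts <- array(0L, dim = c(n, G, C))
  if (nrow(dt)) {
    si <- match(dt$sample_id, samples)
    gi <- match(dt$gene_id, genes)
    ci <- match(dt$functional_class, unclass(vocab))
    li <- si + n * (gi - 1L) + as.integer(n) * G * (ci - 1L)
    counts <- array(tabulate(li, nbins = as.double(n) * G * C),
                    dim = c(n, G, C))
  }
  gene_tensor(counts, samples, genes, vocab)
}

#' Construct a gene-centric tensor
#'
#' @param counts Numeric `n x G x C` array.
#' @param sample_ids,gene_ids Dimension identifiers.
#' @param classes A [class_vocabulary()].
#' @param standardized Whether the counts have already been z-scored.
#' @param stats Standardization statistics (see [fit_standardization()]).
#' @return A `gene_tensor` object.
#' @export
gene_tensor <- function(counts, sample_ids, gene_ids, classes,
                        standardized = FALSE, stats = NULL) {
  stopifnot(length(dim(counts)) == 3, inherits(classes, "class_vocab"))
  stopifnot(dim(counts)[1] == length(sample_ids),
            dim(counts)[2] == length(gene_ids),
            dim(counts)[3] == length(classes))
  if (!standardized && any(counts < -1e-6))
    stop("unstandardized counts must be non-negative")
  structure(list(counts = counts,
                 sample_ids = as.character(sample_ids),
                 gene_ids = as.character(gene_ids),
                 classes = classes,
                 standardized = isTRUE(standardized),
                 stats = stats),
            class = "gene_tensor")
}

#' @export
print.gene_tensor <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<gene_tensor> %d samples x %d genes x %d classes (%s)\n",
              d[1], d[2], d[3],
              if (x$standardized) "standardized" else "raw counts"))
  invisible(x)
}

#' @export
dim.gene_tensor <- function(x) dim(x$counts)

# row-subset a tensor by sample index
subset_samples <- function(x, idx) {
  gene_tensor(x$counts[idx, , , drop = FALSE], x$sample_ids[idx], x$gene_ids,
              x$classes, x$standardized, x$stats)
}

#' Fit standardization statistics on a (training) tensor
#'
#' Counts of each functional class are pooled across all genes and samples,
#' giving one mean/sd per class (the default). `per_gene = TRUE` instead fits
#' one mean/sd per (gene, class) cell.
#'
#' @param x An unstandardized `gene_tensor`.
#' @param per_gene Fit per-(gene, class) statistics instead of pooled.
#' @return A `std_stats` object.
#' @export
fit_standardization <- function(x, per_gene = FALSE) {
  stopifnot(inherits(x, "gene_tensor"))
  if (x$standardized) stop("tensor is already standardized")
  d <- dim(x$counts)
  if (per_gene) {
    m <- apply(x$counts, c(2, 3), mean)
    s <- apply(x$counts, c(2, 3), sd)
  } else {
    flat <- matrix(x$counts, d[1] * d[2], d[3])
    m <- colMeans(flat)
    s <- apply(flat, 2, sd)
  }
  structure(list(mean = m, sd = s, per_gene = per_gene,
                 classes = x$classes, gene_ids = x$gene_ids),
            class = "std_stats")
}

#' Standardize a gene-centric tensor
#'
#' Z-scores the counts using statistics pooled per functional class across
#' genes and samples. When `stats` is supplied (test-set use) those training
#' statistics are applied instead of refitting, so no test information leaks
#' into the transform. Classes with zero variance map to 0.
#'
#' @param x An unstandardized `gene_tensor`.
#' @param stats Optional precomputed [fit_standardization()] statistics.
#' @param per_gene Used only when `stats` is `NULL`.
#' @return A standardized `gene_tensor` with the statistics recorded.
#' @export
standardize <- function(x, stats = NULL, per_gene = FALSE) {
  stopifnot(inherits(x, "gene_tensor"))
  if (x$standardized) stop("tensor is already standardized")
  if (is.null(stats)) stats <- fit_standardization(x, per_gene = per_gene)
  stopifnot(inherits(stats, "std_stats"))
  if (!identical(unclass(stats$classes), unclass(x$classes)))
    stop("class vocabulary mismatch between tensor and standardization stats")
  if (stats$per_gene && !identical(stats$gene_ids, x$gene_ids))
    stop("gene vocabulary mismatch between tensor and standardization stats")
  d <- dim(x$counts)
  out <- x$counts
  if (stats$per_gene) {
    for (ci in seq_len(d[3])) {
      s <- stats$sd[, ci]
      z <- sweep(out[, , ci, drop = FALSE], 2, stats$mean[, ci], "-")
      z <- sweep(z, 2, ifelse(s > 0, s, 1), "/")
      z[, s == 0, 1] <- 0
      out[, , ci] <- z
    }
  } else {
    for (ci in seq_len(d[3])) {
      if (stats$sd[ci] > 0) {
        out[, , ci] <- (out[, , ci] - stats$mean[ci]) / stats$sd[ci]
      } else {
        out[, , ci] <- 0
      }
    }
  }
  gene_tensor(out, x$sample_ids, x$gene_ids, x$classes,
              standardized = TRUE, stats = stats)
}

#' Invert the standardization of a tensor
#'
#' Recovers raw counts from a standardized tensor using its stored statistics
#' (exact up to floating point for classes with positive variance; zero-
#' variance classes are constant and recovered from their stored mean).
#'
#' @param x A standardized `gene_tensor`.
#' @return An unstandardized `gene_tensor`.
#' @export
inverse_standardize <- function(x) {
  stopifnot(inherits(x, "gene_tensor"), x$standardized,
            !is.null(x$stats))
  st <- x$stats
  out <- x$counts
  d <- dim(out)
  if (st$per_gene) {
    for (ci in seq_len(d[3])) {
      z <- sweep(out[, , ci, drop = FALSE], 2, st$sd[, ci], "*")
      out[, , ci] <- sweep(z, 2, st$mean[, ci], "+")
    }
  } else {
    for (ci in seq_len(d[3]))
      out[, , ci] <- out[, , ci] * st$sd[ci] + st$mean[ci]
  }
  gene_tensor(out, x$sample_ids, x$gene_ids, x$classes,
              standardized = FALSE, stats = NULL)
}

#' Persist / restore a gene tensor
#'
#' The on-disk layout is a serialized count array at `<path>.counts.rds`
#' (compressed) plus a JSON sidecar `<path>.json` holding the sample, gene
#' and class vocabularies, the standardization flag and statistics.
#'
#' @param x A `gene_tensor`.
#' @param path Path prefix.
#' @return `save_tensor` the prefix, invisibly; `load_tensor` the tensor.
#' @export
save_tensor <- function(x, path) {
  stopifnot(inherits(x, "gene_tensor"))
  saveRDS(x$counts, paste0(path, ".counts.rds"), compress = "gzip")
  side <- list(sample_ids = x$sample_ids, gene_ids = x$gene_ids,
               classes = unclass(x$classes), standardized = x$standardized)
  if (!is.null(x$stats))
    side$stats <- list(mean = x$stats$mean, sd = x$stats$sd,
                       per_gene = x$stats$per_gene)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_tensor
#' @export
load_tensor <- function(path) {
  counts <- readRDS(paste0(path, ".counts.rds"))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  classes <- class_vocabulary(side$classes)
  stats <- NULL
  if (!is.null(side$stats)) {
    stats <- structure(list(mean = side$stats$mean, sd = side$stats$sd,
                            per_gene = isTRUE(side$stats$per_gene),
                            classes = classes, gene_ids = side$gene_ids),
                       class = "std_stats")
    if (stats$per_gene) {
      stats$mean <- matrix(stats$mean, ncol = length(classes))
      stats$sd <- matrix(stats$sd, ncol = length(classes))
    }
  }
  gene_tensor(counts, side$sample_ids, side$gene_ids, classes,
              standardized = isTRUE(side$standardized), stats = stats)
}
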