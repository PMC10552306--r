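#' Read pathway membership from a GMT file
#'
#' Standard GMT lines: set name, description, then tab-separated member gene
#' ids. The memberships are inverted to gene -> pathways. Genes of the model
#' vocabulary that appear in no line are later connected to a single shared
#' *dummy* pathway (see [finalize_pathway_map()]), so no gene is discarded.
#'
#' @param path GMT file path.
#' @param dummy_id Reserved identifier for the dummy pathway.
#' @return An unfinalized `pathway_map`.
#' @export
read_gmt <- function(path, dummy_id = ".dummy") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2)
      stop("malformed GMT line (need name, description, genes...): ", ln,
           call. = FALSE)
    nm <- parts[1]
    if (nm %in% names(sets))
      stop("duplicate pathway name in GMT: ", nm, call. = FALSE)
    sets[[nm]] <- unique(parts[-(1:2)])
  }
  pathway_map(sets, dummy_id = dummy_id)
}

#' Construct a pathway map from a list of gene sets
#'
#' @param sets Named list: pathway id -> character vector of member genes.
#' @param dummy_id Reserved dummy pathway id (must not collide with a set).
#' @return A `pathway_map`.
#' @export
pathway_map <- function(sets, dummy_id = ".dummy") {
  assert_that(is.list(sets), "sets must be a named list")
  if (length(sets)) assert_that(!is.null(names(sets)) && all(nzchar(names(sets))),
                                "every pathway needs a name")
  assert_that(!anyDuplicated(names(sets)), "duplicate pathway names")
  assert_that(!(dummy_id %in% names(sets)),
              "dummy_id collides with a pathway name")
  genes <- unique(unlist(sets, use.names = FALSE))
  memberships <- list()
  for (p in names(sets))
    for (g in sets[[p]]) memberships[[g]] <- c(memberships[[g]], p)
  structure(list(sets = sets,
                 memberships = memberships,
                 pathway_ids = names(sets),
                 dummy_id = dummy_id,
                 finalized = FALSE,
                 genes = genes),
            class = "pathway_map")
}

#' Finalize a pathway map against a gene vocabulary
#'
#' Restricts memberships to the model's genes and assigns every gene without
#' any membership to the single shared dummy pathway, so the map is total:
#' after finalization every gene maps to at least one pathway.
#'
#' @param pm A `pathway_map`.
#' @param genes Character vector: the model's gene vocabulary.
#' @return A finalized `pathway_map` whose `genes` equal `genes`.
#' @export
finalize_pathway_map <- function(pm, genes) {
  stopifnot(inherits(pm, "pathway_map"))
  genes <- as.character(genes)
  memberships <- pm$memberships[intersect(names(pm$memberships), genes)]
  orphans <- setdiff(genes, names(memberships))
  for (g in orphans) memberships[[g]] <- pm$dummy_id
  used <- unique(unlist(memberships, use.names = FALSE))
  pathway_ids <- c(intersect(pm$pathway_ids, used), pm$dummy_id)
  structure(list(sets = pm$sets,
                 memberships = memberships[genes],
                 pathway_ids = unique(pathway_ids),
                 dummy_id = pm$dummy_id,
                 finalized = TRUE,
                 genes = genes),
            class = "pathway_map")
}

#' @export
print.pathway_map <- function(x, ...) {
  cat(sprintf("<pathway_map> %d pathways, %d genes%s\n",
              length(setdiff(x$pathway_ids, x$dummy_id)), length(x$genes),
              if (x$finalized) " (finalized)" else ""))
  invisible(x)
}

#' Write a pathway map to GMT
#' @param pm A `pathway_map`.
#' @param path Output path.
#' @export
write_gmt <- function(pm, path) {
  stopifnot(inherits(pm, "pathway_map"))
  lines <- vapply(names(pm$sets), function(p)
    paste(c(p, "na", pm$sets[[p]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-gene edge list (two-column TSV)
#'
#' @param path TSV with two columns of gene ids (no header required; a header
#'   line `gene_a<TAB>gene_b` is tolerated).
#' @return A `gene_edges` object: a two-column character matrix of unordered
#'   pairs with self-loops rejected.
#' @export
read_gene_edges <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = "auto",
                          colClasses = "character", showProgress = FALSE)
  if (ncol(dt) < 2) stop("edge list needs two columns", call. = FALSE)
  gene_edges(as.matrix(dt[, 1:2]))
}

#' Construct a gene-gene edge set
#' @param pairs Two-column matrix/data.frame of gene id pairs.
#' @return A `gene_edges` object.
#' @export
gene_edges <- function(pairs) {
  m <- as.matrix(pairs)
  storage.mode(m) <- "character"
  if (nrow(m) && any(m[, 1] == m[, 2]))
    stop("self-loops are not allowed in the gene-gene edge list",
         call. = FALSE)
  # canonical unordered representation, deduplicated
  key <- ifelse(m[, 1] < m[, 2], paste(m[, 1], m[, 2], sep = "\r"),
                paste(m[, 2], m[, 1], sep = "\r"))
  m <- m[!duplicated(key), , drop = FALSE]
  colnames(m) <- c("gene_a", "gene_b")
  structure(m, class = c("gene_edges", "matrix", "array"))
}
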