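# Core domain containers and their validators.
#
# Expression is a plain numeric matrix (genes in rows, samples in columns,
# both dimnames set) -- the convention limma users expect. Phenotypes are a
# two-column tibble. The interaction network is an undirected simple igraph
# graph. A pathway collection is a named list of character vectors.

#' Validate a gene-by-sample expression matrix
#'
#' Checks the invariants every pipeline stage relies on: a numeric matrix
#' with unique, non-empty gene rownames and sample colnames, all values
#' finite, and at least 2 genes and 4 samples.
#'
#' @param expr Numeric matrix, genes in rows and samples in columns.
#' @return `expr`, invisibly, if valid; otherwise an error.
#' @export
validate_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    abort("`expr` must be a numeric matrix (genes x samples).")
  }
  genes <- rownames(expr)
  samples <- colnames(expr)
  if (is.null(genes) || is.null(samples)) {
    abort("`expr` must have gene rownames and sample colnames.")
  }
  if (anyDuplicated(genes)) {
    abort(paste0("Duplicate gene ID: ", genes[duplicated(genes)][1]))
  }
  if (anyDuplicated(samples)) {
    abort(paste0("Duplicate sample ID: ", samples[duplicated(samples)][1]))
  }
  if (!all(is.finite(expr))) {
    abort("`expr` contains non-finite values.")
  }
  if (nrow(expr) < 2 || ncol(expr) < 4) {
    abort("`expr` needs at least 2 genes and 4 samples.")
  }
  invisible(expr)
}

#' Construct phenotype labels
#'
#' @param sample_id Character vector of sample IDs.
#' @param label Character vector of labels, each `"NORMAL"` or `"CASE"`.
#' @return A tibble with columns `sample_id` and `label`.
#' @export
phenotype_labels <- function(sample_id, label) {
  out <- tibble(sample_id = as.character(sample_id),
                label = as.character(label))
  validate_phenotypes(out)
  out
}

#' Validate phenotype labels
#'
#' @param labels Tibble with columns `sample_id`, `label`.
#' @param expr Optional expression matrix to cross-check sample IDs against.
#' @return `labels`, invisibly.
#' @export
validate_phenotypes <- function(labels, expr = NULL) {
  if (!is.data.frame(labels) || !all(c("sample_id", "label") %in% names(labels))) {
    abort("`labels` must be a data frame with columns `sample_id` and `label`.")
  }
  if (anyDuplicated(labels$sample_id)) {
    abort("Duplicate sample ID in phenotype labels.")
  }
  bad <- setdiff(unique(labels$label), c("NORMAL", "CASE"))
  if (length(bad)) {
    abort(paste0("Unknown phenotype label(s): ", paste(bad, collapse = ", "),
                 ". Labels must be NORMAL or CASE (see `read_phenotypes()` aliases)."))
  }
  counts <- table(factor(labels$label, levels = c("NORMAL", "CASE")))
  if (any(counts < 2)) {
    abort("Each phenotype group needs at least 2 samples (a variance must be estimable).")
  }
  if (!is.null(expr)) {
    missing <- setdiff(labels$sample_id, colnames(expr))
    if (length(missing)) {
      abort(paste0("Labelled sample(s) absent from expression matrix: ",
                   paste(head(missing, 5), collapse = ", ")))
    }
  }
  invisible(labels)
}

# sample ids per group, in expression column order when expr given
split_samples <- function(labels, expr = NULL) {
  ids <- list(
    normal = labels$sample_id[labels$label == "NORMAL"],
    case = labels$sample_id[labels$label == "CASE"]
  )
  if (!is.null(expr)) {
    ids <- lapply(ids, function(s) intersect(colnames(expr), s))
  }
  ids
}

#' Construct an interaction network from an edge list
#'
#' Builds an undirected simple graph: self-loops are dropped and duplicate
#' (including reversed) edges collapsed.
#'
#' @param edges Two-column data frame or matrix of gene-ID pairs.
#' @param nodes Optional character vector of additional isolated nodes.
#' @return An undirected simple [igraph::graph] with gene-ID vertex names.
#' @export
ppi_network <- function(edges, nodes = NULL) {
  em <- as.matrix(edges)[, 1:2, drop = FALSE]
  mode(em) <- "character"
  keep <- em[, 1] != em[, 2]
  dropped_loops <- sum(!keep)
  em <- em[keep, , drop = FALSE]
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  if (!is.null(nodes)) {
    extra <- setdiff(as.character(nodes), igraph::V(g)$name)
    g <- igraph::add_vertices(g, length(extra), name = extra)
  }
  before <- igraph::ecount(g)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  dropped_dups <- before - igraph::ecount(g)
  if (dropped_loops + dropped_dups > 0) {
    message(sprintf("ppi_network: dropped %d self-loop(s) and %d duplicate edge(s)",
                    dropped_loops, dropped_dups))
  }
  g
}

#' Construct a pathway collection
#'
#' @param sets Named list of character vectors (gene sets).
#' @param descriptions Optional character vector of per-pathway descriptions.
#' @return A named list of unique gene-ID vectors with a `description`
#'   attribute; pathway names are unique and every set non-empty.
#' @export
pathway_collection <- function(sets, descriptions = NULL) {
  if (length(sets) == 0) return(structure(list(), class = "list"))
  nm <- names(sets)
  if (is.null(nm) || any(nm == "")) abort("Every pathway must be named.")
  if (anyDuplicated(nm)) {
    abort(paste0("Duplicate pathway name: ", nm[duplicated(nm)][1]))
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) == 0)) {
    abort(paste0("Empty gene set for pathway: ",
                 nm[which(lengths(sets) == 0)[1]]))
  }
  if (!is.null(descriptions)) {
    attr(sets, "description") <- stats::setNames(as.character(descriptions), nm)
  }
  sets
}
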