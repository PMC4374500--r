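# Per-gene z-scoring and restriction of matrix + network to the genes they
# share. Both are run before seed selection and module growth.

#' Z-score each gene row
#'
#' Transforms every row to `(x - mean(x)) / sd(x)` with the sample standard
#' deviation (denominator `n - ddof`). Each output row then has mean 0 and
#' (for `ddof = 1`) sample SD 1. Z-scoring is computed across all samples
#' pooled; downstream group statistics are unaffected by this common affine
#' transform.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param ddof Degrees-of-freedom correction for the SD denominator
#'   (`n - ddof`); default 1, the sample SD.
#' @return Matrix of the same shape and dimnames, z-scored by row.
#' @export
zscore_rows <- function(expr, ddof = 1) {
  validate_expression(expr)
  mu <- rowMeans(expr)
  n <- ncol(expr)
  ss <- rowSums((expr - mu)^2)
  sigma <- sqrt(ss / (n - ddof))
  if (any(sigma == 0)) {
    abort(paste0("Constant expression row (z-score undefined) for gene: ",
                 rownames(expr)[which(sigma == 0)[1]]))
  }
  (expr - mu) / sigma
}

#' Restrict network and expression to their common gene universe
#'
#' Drops network nodes (and incident edges) without an expression row, and
#' expression rows absent from the network, so that every downstream gene
#' lives in both. Counts of dropped nodes, edges and rows are messaged.
#'
#' @param net An [igraph::graph] over gene IDs.
#' @param expr Numeric matrix, genes x samples.
#' @return List with elements `net` and `expr`, both restricted to the
#'   intersection (expression row order preserved).
#' @export
restrict_to_common_genes <- function(net, expr) {
  validate_expression(expr)
  common <- intersect(igraph::V(net)$name, rownames(expr))
  if (!length(common)) abort("Network and expression matrix share no genes.")
  e0 <- igraph::ecount(net)
  net2 <- igraph::induced_subgraph(net, intersect(igraph::V(net)$name, common))
  dropped_nodes <- igraph::vcount(net) - igraph::vcount(net2)
  dropped_rows <- nrow(expr) - length(common)
  if (dropped_nodes || dropped_rows) {
    message(sprintf(
      "restrict_to_common_genes: dropped %d node(s), %d edge(s), %d expression row(s)",
      dropped_nodes, e0 - igraph::ecount(net2), dropped_rows))
  }
  list(net = net2, expr = expr[rownames(expr)[rownames(expr) %in% common], , drop = FALSE])
}
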