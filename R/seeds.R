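# Seed selection: per-gene two-sample t-tests, Benjamini-Hochberg
# adjustment, and the adjusted-p threshold that defines growth seeds.

#' Per-gene two-sample t-tests between phenotype groups
#'
#' Runs a two-sided two-sample t-test (Welch by default) of NORMAL vs CASE
#' for every gene row and adjusts the p-values with [adjust_bh()] across all
#' tested genes. A gene with zero variance in both groups gets `p_value = 1`
#' with a warning rather than a division-by-zero failure.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param labels Phenotype tibble (`sample_id`, `label`).
#' @param equal_var Use the pooled-variance test instead of Welch's.
#' @return A tibble with columns `gene_id`, `t_stat`, `p_value`,
#'   `p_adjusted`, one row per gene in input order.
#' @export
gene_t_tests <- function(expr, labels, equal_var = FALSE) {
  validate_expression(expr)
  validate_phenotypes(labels, expr)
  grp <- split_samples(labels, expr)
  xn <- expr[, grp$normal, drop = FALSE]
  xc <- expr[, grp$case, drop = FALSE]
  res <- purrr::map(seq_len(nrow(expr)), function(i) {
    a <- xn[i, ]; b <- xc[i, ]
    if (var(a) == 0 && var(b) == 0) {
      warn(paste0("Gene with zero variance in both groups: ", rownames(expr)[i]))
      return(list(t_stat = 0, p_value = 1))
    }
    tt <- t.test(a, b, var.equal = equal_var)
    list(t_stat = unname(tt$statistic), p_value = tt$p.value)
  })
  out <- tibble(
    gene_id = rownames(expr),
    t_stat = purrr::map_dbl(res, "t_stat"),
    p_value = purrr::map_dbl(res, "p_value")
  )
  out$p_adjusted <- adjust_bh(out$p_value)
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, order-aligned with the input, each clipped to 1.
#' @export
adjust_bh <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) || anyNA(p_values)) {
    abort("All p-values must lie in [0, 1].")
  }
  p.adjust(p_values, method = "BH")
}

#' Select seed genes at an adjusted-p threshold
#'
#' @param results Tibble from [gene_t_tests()].
#' @param alpha Adjusted-p threshold; genes with `p_adjusted < alpha` become
#'   seeds. Default 0.01.
#' @return Character vector of seed gene IDs, ordered by `p_adjusted` then
#'   gene ID (deterministic across runs).
#' @export
select_seeds <- function(results, alpha = 0.01) {
  stopifnot(is.numeric(alpha), alpha > 0, alpha <= 1)
  hit <- results[results$p_adjusted < alpha, , drop = FALSE]
  hit <- hit[order(hit$p_adjusted, hit$gene_id), , drop = FALSE]
  hit$gene_id
}
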