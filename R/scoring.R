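# Biomarker selection among surviving modules: hypergeometric pathway
# enrichment defines each module's enriched pathway set (MF), and the
# bidirectional best-match Jaccard similarity between MF and a
# disease-background pathway set (DMF) ranks the modules.

#' Hypergeometric over-representation test
#'
#' Upper-tail probability `P(X >= s)` of observing at least the realized
#' overlap `s = |module . pathway . universe|` when `|module|` genes are
#' drawn without replacement from a universe of `n` genes containing
#' `|pathway . universe|` pathway genes. `s = 0` gives p = 1 exactly.
#'
#' @param module_genes Character vector of module gene IDs (subset of
#'   `universe`).
#' @param pathway_genes Character vector of pathway gene IDs (intersected
#'   with `universe` before testing).
#' @param universe Character vector: the analysis gene universe, typically
#'   the post-restriction network node set.
#' @return One-row tibble: `overlap_s`, `p_value`.
#' @export
enrichment_test <- function(module_genes, pathway_genes, universe) {
  universe <- unique(as.character(universe))
  module_genes <- unique(as.character(module_genes))
  if (length(setdiff(module_genes, universe))) {
    abort("Module genes must be a subset of the universe.")
  }
  if (length(module_genes) > length(universe)) {
    abort("Module larger than universe.")
  }
  path_u <- intersect(unique(as.character(pathway_genes)), universe)
  s <- length(intersect(module_genes, path_u))
  p <- if (s == 0) 1 else
    phyper(s - 1, length(path_u), length(universe) - length(path_u),
           length(module_genes), lower.tail = FALSE)
  tibble(overlap_s = s, p_value = min(max(p, 0), 1))
}

#' Enrichment table of a module against a pathway catalogue
#'
#' @param module_genes Character vector of module gene IDs.
#' @param catalogue A [pathway_collection()].
#' @param universe Analysis gene universe.
#' @return Tibble with one row per pathway: `pathway`, `overlap_s`,
#'   `p_value`, `p_adjusted` (Benjamini-Hochberg across the catalogue).
#' @export
enrichment_table <- function(module_genes, catalogue, universe) {
  if (!length(catalogue)) abort("Empty pathway catalogue.")
  rows <- purrr::imap(catalogue, function(genes, nm) {
    dplyr::mutate(enrichment_test(module_genes, genes, universe),
                  pathway = nm, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- adjust_bh(out$p_value)
  out
}

#' Enriched pathways (MF) of a module
#'
#' @param module_genes Character vector of module gene IDs.
#' @param catalogue A [pathway_collection()].
#' @param universe Analysis gene universe.
#' @param alpha_enrich Enrichment threshold on the BH-adjusted p-value
#'   (default 0.05); set `adjust = FALSE` to threshold the raw p-value.
#' @param adjust Threshold adjusted (default) or raw p-values.
#' @return The sub-collection of enriched pathways, with the full
#'   [enrichment_table()] attached as attribute `"enrichment"`.
#' @export
enriched_pathways <- function(module_genes, catalogue, universe,
                              alpha_enrich = 0.05, adjust = TRUE) {
  stopifnot(alpha_enrich > 0, alpha_enrich < 1)
  tab <- enrichment_table(module_genes, catalogue, universe)
  p <- if (adjust) tab$p_adjusted else tab$p_value
  hits <- tab$pathway[p < alpha_enrich]
  out <- catalogue[hits]
  attr(out, "description") <- attr(catalogue, "description")[hits]
  attr(out, "enrichment") <- tab
  out
}

#' Jaccard index of two gene sets
#'
#' @param ps1,ps2 Character vectors; not both empty.
#' @return `|ps1 . ps2| / |ps1 u ps2|` in `[0, 1]`.
#' @export
set_jaccard <- function(ps1, ps2) {
  ps1 <- unique(as.character(ps1)); ps2 <- unique(as.character(ps2))
  u <- length(union(ps1, ps2))
  if (u == 0) abort("Jaccard undefined for two empty sets.")
  length(intersect(ps1, ps2)) / u
}

#' Similarity of two pathway collections
#'
#' Bidirectional best-match average: each pathway is matched to its most
#' similar (Jaccard) counterpart in the other collection, and all best-match
#' scores are averaged over the `m + n` pathways. Identical collections
#' score 1; collections with pairwise disjoint pathways score 0.
#'
#' @param ps1,ps2 [pathway_collection()]s.
#' @return Similarity in `[0, 1]`; an empty collection returns 0 with a
#'   warning (a module with no enriched pathways ranks last rather than
#'   failing).
#' @export
pathway_set_similarity <- function(ps1, ps2) {
  if (!length(ps1) || !length(ps2)) {
    warn("Empty pathway collection: similarity set to 0.")
    return(0)
  }
  best <- function(a, coll) max(vapply(coll, set_jaccard, numeric(1), ps2 = a))
  s12 <- vapply(ps1, best, numeric(1), coll = ps2)
  s21 <- vapply(ps2, best, numeric(1), coll = ps1)
  (sum(s12) + sum(s21)) / (length(ps1) + length(ps2))
}

#' Score and rank modules by functional similarity to a disease background
#'
#' For each module, the enriched pathways (MF) are computed against
#' `catalogue` and the module's score is the pathway-set similarity between
#' MF and the disease background DMF. Modules are ranked by descending
#' score; ties break by smaller discriminative area, then seed ID. The top
#' row is the candidate module biomarker.
#'
#' @param modules Module tibble from [discover_modules()].
#' @param catalogue Generic pathway catalogue ([pathway_collection()]).
#' @param background Disease-background collection (DMF).
#' @param universe Analysis gene universe.
#' @param alpha_enrich Enrichment threshold (see [enriched_pathways()]).
#' @param intersect_background Intersect DMF gene sets with the universe
#'   before similarity (default `TRUE`); background pathways left empty by
#'   the intersection are dropped.
#' @return The module tibble with columns `score` and list-column
#'   `enriched_pathways` added, ranked by score.
#' @export
score_modules <- function(modules, catalogue, background, universe,
                          alpha_enrich = 0.05, intersect_background = TRUE) {
  if (!nrow(modules)) abort("`modules` must be non-empty.")
  dmf <- background
  if (intersect_background) {
    dmf <- lapply(background, intersect, y = universe)
    dmf <- dmf[lengths(dmf) > 0]
  }
  mf <- purrr::map(modules$members, enriched_pathways, catalogue = catalogue,
                   universe = universe, alpha_enrich = alpha_enrich)
  score <- purrr::map_dbl(mf, function(m) {
    if (!length(m) || !length(dmf)) 0
    else pathway_set_similarity(m, dmf)
  })
  out <- dplyr::mutate(modules, score = score,
                       enriched_pathways = purrr::map(mf, names))
  out[order(-out$score, out$disa, out$seed), , drop = FALSE]
}
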