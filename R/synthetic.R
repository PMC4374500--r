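# Synthetic benchmark generator: a random background interaction network
# with a planted connected module whose genes are mean-shifted between
# groups, plus pathway catalogues that partially annotate the planted
# genes. Every stage of the pipeline is testable against the known truth.

#' Synthetic instance specification
#'
#' Defaults describe the benchmark conditions used throughout the package's
#' tests: 300 genes, 60 samples per group, a connected 10-gene planted
#' module whose genes are shifted by 1.5 within-group SDs in CASE samples,
#' a sparse Erdos-Renyi background (mean degree ~6), and a 30-pathway
#' catalogue of which 10 form the disease background, half of those seeded
#' with planted genes.
#'
#' @param n_genes Total number of genes.
#' @param n_per_group Samples per phenotype group (>= 5).
#' @param planted_size Number of planted module genes (< `n_genes`).
#' @param effect Mean shift of each planted gene in CASE samples, in units
#'   of the within-group SD (>= 0; 0 gives a null instance).
#' @param background_edge_prob Erdos-Renyi edge probability in `(0, 1)`.
#' @param n_pathways Catalogue size.
#' @param pathway_size_range Integer pair: min/max pathway size.
#' @param n_dmf Number of catalogue pathways forming the disease background.
#' @param dmf_overlap Fraction of background pathways forced to contain at
#'   least 50% planted genes.
#' @param rng_seed Integer seed; the instance is fully determined by it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 300, n_per_group = 60, planted_size = 10,
                           effect = 1.5, background_edge_prob = 0.02,
                           n_pathways = 30, pathway_size_range = c(8, 15),
                           n_dmf = 10, dmf_overlap = 0.5, rng_seed = 1) {
  spec <- list(n_genes = as.integer(n_genes),
               n_per_group = as.integer(n_per_group),
               planted_size = as.integer(planted_size), effect = effect,
               background_edge_prob = background_edge_prob,
               n_pathways = as.integer(n_pathways),
               pathway_size_range = as.integer(pathway_size_range),
               n_dmf = as.integer(n_dmf), dmf_overlap = dmf_overlap,
               rng_seed = as.integer(rng_seed))
  if (spec$planted_size >= spec$n_genes) abort("planted_size must be < n_genes.")
  if (spec$n_per_group < 5) abort("n_per_group must be >= 5.")
  if (spec$effect < 0) abort("effect must be >= 0.")
  if (spec$background_edge_prob <= 0 || spec$background_edge_prob >= 1) {
    abort("background_edge_prob must lie in (0, 1).")
  }
  if (spec$n_dmf > spec$n_pathways) abort("n_dmf must be <= n_pathways.")
  if (spec$dmf_overlap < 0 || spec$dmf_overlap > 1) {
    abort("dmf_overlap must lie in [0, 1].")
  }
  if (max(spec$pathway_size_range) > spec$n_genes ||
      min(spec$pathway_size_range) < 1) {
    abort("Infeasible pathway_size_range for this n_genes.")
  }
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic instance with a planted discriminative module
#'
#' The network is an Erdos-Renyi background graph plus a random spanning
#' tree over the planted genes (guaranteeing their connectivity) and extra
#' random edges among them. Background genes are i.i.d. standard normal in
#' both groups; planted genes gain a mean shift of `effect` in CASE
#' samples. The pathway catalogue consists of random gene sets; `n_dmf` of
#' them form the disease background (DMF), a `dmf_overlap` fraction of
#' which is forced to contain at least 50% planted genes. Everything is
#' determined by `spec$rng_seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `synthetic_instance` with elements `expr`
#'   (matrix), `labels` (tibble), `net` (igraph), `catalogue`,
#'   `background` (pathway collections), `truth` (list: `planted_genes`,
#'   `dmf_pathway_names`), and `spec`.
#' @export
generate_instance <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$rng_seed, {
    genes <- sprintf("g%04d", seq_len(spec$n_genes))
    samples <- c(sprintf("n%03d", seq_len(spec$n_per_group)),
                 sprintf("c%03d", seq_len(spec$n_per_group)))
    labels <- phenotype_labels(samples, rep(c("NORMAL", "CASE"),
                                            each = spec$n_per_group))

    planted <- sort(sample(genes, spec$planted_size))

    # background graph + spanning tree over the planted genes + extra
    # internal planted-planted edges
    g <- igraph::sample_gnp(spec$n_genes, spec$background_edge_prob)
    igraph::V(g)$name <- genes
    if (spec$planted_size >= 2) {
      perm <- sample(planted)
      tree <- cbind(perm[-1],
                    vapply(seq_len(spec$planted_size - 1),
                           function(i) perm[sample.int(i, 1)], character(1)))
      extra <- t(utils::combn(planted, 2))
      extra <- extra[stats::runif(nrow(extra)) < 0.3, , drop = FALSE]
      g <- igraph::add_edges(g, t(rbind(tree, extra)))
    }
    g <- igraph::simplify(g)

    expr <- matrix(stats::rnorm(spec$n_genes * length(samples)),
                   nrow = spec$n_genes, dimnames = list(genes, samples))
    if (spec$effect > 0) {
      expr[planted, labels$sample_id[labels$label == "CASE"]] <-
        expr[planted, labels$sample_id[labels$label == "CASE"]] + spec$effect
    }

    sizes <- sample(seq(spec$pathway_size_range[1], spec$pathway_size_range[2]),
                    spec$n_pathways, replace = TRUE)
    sets <- lapply(sizes, function(k) sample(genes, k))
    names(sets) <- sprintf("PW%03d", seq_len(spec$n_pathways))
    dmf_names <- sort(sample(names(sets), spec$n_dmf))
    n_seeded <- ceiling(spec$dmf_overlap * spec$n_dmf)
    for (nm in head(dmf_names, n_seeded)) {
      k <- length(sets[[nm]])
      n_pl <- min(spec$planted_size, ceiling(k / 2))
      fill <- sample(setdiff(genes, planted), k - n_pl)
      sets[[nm]] <- sample(c(sample(planted, n_pl), fill))
    }
    catalogue <- pathway_collection(
      sets, descriptions = rep("synthetic pathway", length(sets)))
    background <- catalogue[dmf_names]
    attr(background, "description") <-
      attr(catalogue, "description")[dmf_names]

    structure(
      list(expr = expr, labels = labels, net = g, catalogue = catalogue,
           background = background,
           truth = list(planted_genes = planted,
                        dmf_pathway_names = dmf_names),
           spec = spec),
      class = "synthetic_instance")
  })
}

#' Generate a null instance (no planted signal)
#'
#' Identical to [generate_instance()] with `effect` forced to 0; the
#' planted gene set is still recorded in `truth` so false-positive checks
#' can reference it.
#'
#' @param spec A [synthetic_spec()].
#' @return A `synthetic_instance`; see [generate_instance()].
#' @export
generate_null_instance <- function(spec = synthetic_spec()) {
  spec$effect <- 0
  generate_instance(spec)
}

#' @export
print.synthetic_instance <- function(x, ...) {
  cat(sprintf(
    "Synthetic instance: %d genes x %d samples, %d-gene planted module (effect %.2g), %d edges\n",
    nrow(x$expr), ncol(x$expr), length(x$truth$planted_genes),
    x$spec$effect, igraph::ecount(x$net)))
  invisible(x)
}

#' Write a synthetic instance to the pipeline's file formats
#'
#' Writes `expression.tsv`, `phenotypes.tsv`, `network.tsv`,
#' `catalogue.gmt`, `background.gmt` and `truth.json` under `dir`, so
#' integration tests exercise the same readers a real analysis would.
#'
#' @param inst A `synthetic_instance`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_instance <- function(inst, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    network = file.path(dir, "network.tsv"),
    catalogue = file.path(dir, "catalogue.gmt"),
    background = file.path(dir, "background.gmt"),
    truth = file.path(dir, "truth.json"))
  write_expression(inst$expr, paths["expression"])
  write_phenotypes(inst$labels, paths["phenotypes"])
  write_network(inst$net, paths["network"])
  write_gene_sets(inst$catalogue, paths["catalogue"])
  write_gene_sets(inst$background, paths["background"])
  jsonlite::write_json(inst$truth, paths["truth"], auto_unbox = FALSE)
  invisible(paths)
}
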