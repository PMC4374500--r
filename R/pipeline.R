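# End-to-end orchestration: preprocess -> seeds -> discover -> score ->
# evaluate, with a run manifest for reproducibility.

#' Pipeline configuration
#'
#' All thresholds of the full run in one validated object.
#'
#' @param alpha_seed Adjusted-p threshold for seed selection (default 0.01).
#' @param delta Growth termination threshold (default 0.001).
#' @param disa_filter Post-growth discriminative-area filter (default 0.2).
#' @param max_module_size,require_improvement See [discovery_config()].
#' @param alpha_enrich Enrichment threshold defining MF (default 0.05).
#' @param n_folds Cross-validation folds (default 10).
#' @param noise_fractions Label-noise fractions for the robustness stage;
#'   `NULL` (default) skips that stage (it multiplies runtime by
#'   `length(fractions) * noise_reps`).
#' @param noise_reps Repetitions per noise fraction (default 100).
#' @param rng_seed Seed for every stochastic stage.
#' @param zscore Z-score expression rows before analysis (default `TRUE`).
#' @param equal_var Pooled-variance t-test instead of Welch (default `FALSE`).
#' @param cost SVM regularization constant (default 1).
#' @return A list of class `run_config`.
#' @export
run_config <- function(alpha_seed = 0.01, delta = 0.001, disa_filter = 0.2,
                       max_module_size = 50, require_improvement = TRUE,
                       alpha_enrich = 0.05, n_folds = 10,
                       noise_fractions = NULL, noise_reps = 100,
                       rng_seed = 1, zscore = TRUE, equal_var = FALSE,
                       cost = 1) {
  stopifnot(alpha_seed > 0, alpha_seed < 1, alpha_enrich > 0, alpha_enrich < 1,
            n_folds >= 2, noise_reps >= 1, cost > 0)
  discovery <- discovery_config(delta, disa_filter, max_module_size,
                                require_improvement)
  structure(list(alpha_seed = alpha_seed, discovery = discovery,
                 alpha_enrich = alpha_enrich, n_folds = n_folds,
                 noise_fractions = noise_fractions, noise_reps = noise_reps,
                 rng_seed = as.integer(rng_seed), zscore = isTRUE(zscore),
                 equal_var = isTRUE(equal_var), cost = cost),
            class = "run_config")
}

#' Run the full module-biomarker pipeline
#'
#' Z-scores the expression rows, restricts matrix and network to their
#' common genes, selects differentially expressed seeds, grows and filters
#' discriminative modules, ranks them by functional similarity to the
#' disease background, and cross-validates the top-ranked module. If
#' `config$noise_fractions` is set, the label-noise robustness stage runs
#' on the biomarker as well.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param labels Phenotype tibble.
#' @param net An [igraph::graph] over gene IDs.
#' @param catalogue Generic pathway catalogue.
#' @param background Disease-background pathway collection (DMF).
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, stage outputs (seed
#'   table, module JSON + TSV, score table, CV/noise reports) and a run
#'   manifest are written there.
#' @return A list of class `modisa_run`: `biomarker` (top-ranked module
#'   row), `scores` (ranked module tibble), `modules`, `seeds`, `tests`,
#'   `cv` ([crossvalidate()] report), `noise` (or `NULL`), `universe`, and
#'   `manifest`. Zero seeds or zero surviving modules raise conditions of
#'   class `modisa_no_seeds` / `modisa_no_modules`.
#' @export
run_pipeline <- function(expr, labels, net, catalogue, background,
                         config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  counters <- list(genes_in = nrow(expr), samples = ncol(expr))
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  validate_phenotypes(labels, expr)
  expr <- expr[, labels$sample_id, drop = FALSE]
  if (config$zscore) expr <- zscore_rows(expr)
  restricted <- restrict_to_common_genes(net, expr)
  expr <- restricted$expr
  net <- restricted$net
  universe <- igraph::V(net)$name
  counters$genes_analyzed <- length(universe)

  tests <- gene_t_tests(expr, labels, equal_var = config$equal_var)
  seeds <- select_seeds(tests, alpha = config$alpha_seed)
  counters$n_seeds <- length(seeds)
  if (!is.null(out_dir)) {
    seed_tab <- dplyr::mutate(tests, is_seed = .data$gene_id %in% seeds)
    utils::write.table(seed_tab, file.path(out_dir, "seeds.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!length(seeds)) {
    abort(sprintf("No gene passed the seed threshold (adjusted p < %g).",
                  config$alpha_seed),
          class = "modisa_no_seeds")
  }

  modules <- discover_modules(seeds, net, expr, labels, cfg = config$discovery)
  counters$n_modules_surviving <- nrow(modules)
  if (!is.null(out_dir)) {
    write_modules(if (nrow(modules)) modules else modules,
                  json_path = file.path(out_dir, "modules.json"),
                  tsv_path = file.path(out_dir, "modules.tsv"))
  }
  if (!nrow(modules)) {
    abort(sprintf("No module survived the discriminative-area filter (<= %g).",
                  config$discovery$disa_filter),
          class = "modisa_no_modules")
  }

  scores <- score_modules(modules, catalogue, background, universe,
                          alpha_enrich = config$alpha_enrich)
  biomarker <- scores[1, , drop = FALSE]
  counters$top_score <- biomarker$score
  if (!is.null(out_dir)) {
    write_modules(scores, json_path = file.path(out_dir, "scored_modules.json"),
                  tsv_path = file.path(out_dir, "scored_modules.tsv"))
  }

  cv <- crossvalidate(expr, labels, biomarker$members[[1]],
                      n_folds = config$n_folds, rng_seed = config$rng_seed,
                      cost = config$cost)
  noise <- NULL
  if (length(config$noise_fractions)) {
    noise <- noise_robustness(expr, labels, biomarker$members[[1]],
                              fractions = config$noise_fractions,
                              n_reps = config$noise_reps,
                              n_folds = config$n_folds,
                              rng_seed = config$rng_seed, cost = config$cost)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("modisa")),
    r_version = as.character(getRversion()),
    rng_seed = config$rng_seed,
    config = unclass_config(config),
    counters = counters,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(mean_accuracy = cv$mean_accuracy, auc = cv$auc,
           fold_accuracies = cv$fold_accuracies,
           feature_genes = cv$feature_genes),
      file.path(out_dir, "cv_report.json"), auto_unbox = TRUE, digits = NA)
    if (!is.null(noise)) {
      jsonlite::write_json(noise$summary, file.path(out_dir, "noise_report.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  structure(list(biomarker = biomarker, scores = scores, modules = modules,
                 seeds = seeds, tests = tests, cv = cv, noise = noise,
                 universe = universe, manifest = manifest),
            class = "modisa_run")
}

unclass_config <- function(config) {
  out <- unclass(config)
  out$discovery <- unclass(out$discovery)
  out
}

#' @export
print.modisa_run <- function(x, ...) {
  cat("Module biomarker pipeline run\n")
  cat(sprintf("  genes analyzed: %d; seeds: %d; modules surviving: %d\n",
              x$manifest$counters$genes_analyzed, length(x$seeds),
              nrow(x$modules)))
  cat(sprintf("  biomarker: %s (%d genes), disa = %.4g, score = %.4g\n",
              x$biomarker$module_id, x$biomarker$size, x$biomarker$disa,
              x$biomarker$score))
  cat(sprintf("  %d-fold CV: mean accuracy %.4f, AUC %.4f\n",
              x$cv$n_folds, x$cv$mean_accuracy, x$cv$auc))
  invisible(x)
}
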