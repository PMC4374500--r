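# broom-style tidiers for the report objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @describeIn crossvalidate `tidy()`: one row per fold (`fold`, `accuracy`).
#' @param x A `cv_report`.
#' @param ... Unused.
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) {
  tibble(fold = seq_len(x$n_folds), accuracy = x$fold_accuracies)
}

#' @describeIn crossvalidate `glance()`: one-row summary (`mean_accuracy`,
#'   `sd_accuracy`, `auc`, `n_folds`, `n_features`, `cost`).
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  tibble(mean_accuracy = x$mean_accuracy,
         sd_accuracy = sd(x$fold_accuracies), auc = x$auc,
         n_folds = x$n_folds, n_features = length(x$feature_genes),
         cost = x$cost)
}

#' @describeIn noise_robustness `tidy()`: the per-fraction summary tibble.
#' @param x A `noise_report`.
#' @param ... Unused.
#' @method tidy noise_report
#' @export
tidy.noise_report <- function(x, ...) x$summary

#' @describeIn noise_robustness `glance()`: one-row summary with the
#'   accuracy at the smallest and largest fraction and their difference.
#' @method glance noise_report
#' @export
glance.noise_report <- function(x, ...) {
  s <- x$summary[order(x$summary$fraction), ]
  tibble(n_fractions = nrow(s), n_repetitions = x$n_repetitions,
         accuracy_low_noise = s$mean_accuracy[1],
         accuracy_high_noise = s$mean_accuracy[nrow(s)],
         accuracy_drop = s$mean_accuracy[1] - s$mean_accuracy[nrow(s)])
}

#' @describeIn run_pipeline `tidy()`: the ranked module score table
#'   (without list-columns).
#' @param x A `modisa_run`.
#' @param ... Unused.
#' @method tidy modisa_run
#' @export
tidy.modisa_run <- function(x, ...) {
  dplyr::select(x$scores, dplyr::any_of(c("module_id", "seed", "size",
                                          "disa", "score")))
}

#' @describeIn run_pipeline `glance()`: one-row run summary.
#' @method glance modisa_run
#' @export
glance.modisa_run <- function(x, ...) {
  tibble(n_seeds = length(x$seeds), n_modules = nrow(x$modules),
         biomarker_size = x$biomarker$size, biomarker_disa = x$biomarker$disa,
         biomarker_score = x$biomarker$score,
         cv_mean_accuracy = x$cv$mean_accuracy, cv_auc = x$cv$auc)
}
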