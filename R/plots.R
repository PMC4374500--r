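# ggplot2 graphics for the result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   geom_abline labs theme_minimal
#' @export
ggplot2::autoplot

roc_points <- function(scores, truth) {
  pos <- truth == "CASE"
  ord <- order(scores, decreasing = TRUE)
  tibble(fpr = c(0, cumsum(!pos[ord]) / sum(!pos)),
         tpr = c(0, cumsum(pos[ord]) / sum(pos)))
}

#' @describeIn crossvalidate `autoplot()`: ROC curve of the pooled
#'   held-out decision scores.
#' @param object A `cv_report`.
#' @method autoplot cv_report
#' @export
autoplot.cv_report <- function(object, ...) {
  pts <- roc_points(object$scores$score, object$scores$truth)
  ggplot(pts, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_line(colour = "#2166ac", linewidth = 0.8) +
    labs(x = "False positive rate", y = "True positive rate",
         title = sprintf("ROC, pooled %d-fold CV (AUC = %.3f)",
                         object$n_folds, object$auc)) +
    theme_minimal()
}

#' @describeIn noise_robustness `autoplot()`: mean accuracy against the
#'   noise fraction with the empirical 95% band.
#' @param object A `noise_report`.
#' @method autoplot noise_report
#' @export
autoplot.noise_report <- function(object, ...) {
  ggplot(object$summary, aes(x = .data$fraction, y = .data$mean_accuracy)) +
    geom_ribbon(aes(ymin = .data$q025, ymax = .data$q975),
                fill = "#2166ac", alpha = 0.15) +
    geom_line(colour = "#2166ac") +
    geom_point(colour = "#2166ac") +
    labs(x = "Training label noise fraction", y = "Mean CV accuracy",
         title = sprintf("Label-noise robustness (%d repetitions)",
                         object$n_repetitions)) +
    theme_minimal()
}

#' Plot a module's growth trace
#'
#' Discriminative area after each accepted addition, starting at the seed.
#'
#' @param module A `disa_module` from [grow_module()].
#' @return A ggplot object.
#' @export
plot_growth_trace <- function(module) {
  stopifnot(inherits(module, "disa_module"))
  tr <- tibble(step = seq_len(nrow(module$trace) + 1),
               gene = c(module$seed, module$trace$gene),
               disa = c(module$seed_disa, module$trace$disa))
  ggplot(tr, aes(x = .data$step, y = .data$disa)) +
    geom_line(colour = "#b2182b") +
    geom_point(colour = "#b2182b") +
    labs(x = "Growth step", y = "Discriminative area",
         title = sprintf("Greedy growth from seed %s", module$seed)) +
    theme_minimal()
}
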