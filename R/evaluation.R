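# Biomarker validation: stratified k-fold cross-validation of a
# linear-kernel maximum-margin classifier on the feature genes, ROC/AUC
# from pooled held-out decision scores, and label-noise robustness.

# stratified fold assignment, named by sample id
make_folds <- function(labels, n_folds, rng_seed) {
  counts <- table(labels$label)
  if (any(counts < n_folds)) {
    abort(sprintf(
      "Smallest class has %d samples; choose n_folds <= %d.",
      min(counts), min(counts)))
  }
  withr::with_seed(rng_seed, {
    fold <- integer(nrow(labels))
    names(fold) <- labels$sample_id
    for (lv in names(counts)) {
      idx <- sample(which(labels$label == lv))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
}

# orient e1071 decision values so larger score favours CASE
case_scores <- function(fit, x) {
  dv <- attr(stats::predict(fit, x, decision.values = TRUE), "decision.values")
  s <- dv[, 1]
  if (startsWith(colnames(dv)[1], "NORMAL/")) s <- -s
  s
}

#' Cross-validated classification with a module's genes as features
#'
#' Stratified k-fold cross-validation of a linear-kernel support vector
#' machine (fixed regularization constant `cost`) trained on the feature
#' genes' expression. Per-fold accuracy is measured on the held-out
#' samples; AUC is computed from the pooled held-out decision scores.
#' Optionally a fraction of *training* labels is flipped per fold (label
#' noise is never injected into test samples).
#'
#' @param expr Numeric matrix, genes x samples (typically z-scored).
#' @param labels Phenotype tibble.
#' @param feature_genes Character vector of feature gene IDs.
#' @param n_folds Number of folds (default 10); each class must have at
#'   least `n_folds` samples.
#' @param rng_seed Seed for the fold partition (and, when `noise_seed` is
#'   `NULL`, for the noise flips).
#' @param cost SVM regularization constant (default 1).
#' @param noise_fraction Fraction of training labels flipped per fold
#'   (default 0).
#' @param noise_seed Separate seed for the noise flips, so the same fold
#'   partition can be reused across noise repetitions.
#' @return Object of class `cv_report`: `fold_accuracies`, `mean_accuracy`,
#'   `auc`, `feature_genes`, `n_folds`, `cost`, `noise_fraction`, and a
#'   `scores` tibble (`sample_id`, `truth`, `score`, `fold`).
#' @export
crossvalidate <- function(expr, labels, feature_genes, n_folds = 10,
                          rng_seed = 1, cost = 1, noise_fraction = 0,
                          noise_seed = NULL) {
  validate_expression(expr)
  validate_phenotypes(labels, expr)
  feature_genes <- as.character(feature_genes)
  missing <- setdiff(feature_genes, rownames(expr))
  if (length(missing)) {
    abort(paste0("Feature gene(s) absent from expression matrix: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  fold <- make_folds(labels, n_folds, rng_seed)
  x <- t(expr[feature_genes, labels$sample_id, drop = FALSE])
  y <- factor(labels$label, levels = c("NORMAL", "CASE"))
  names(y) <- labels$sample_id

  flips <- withr::with_seed(noise_seed %||% rng_seed, {
    lapply(seq_len(n_folds), function(k) {
      train_ids <- names(fold)[fold != k]
      n_flip <- ceiling(noise_fraction * length(train_ids))
      if (n_flip > 0) sample(train_ids, n_flip) else character(0)
    })
  })

  acc <- numeric(n_folds)
  scores <- vector("list", n_folds)
  for (k in seq_len(n_folds)) {
    train <- names(fold)[fold != k]
    test <- names(fold)[fold == k]
    y_train <- y[train]
    fl <- flips[[k]]
    if (length(fl)) {
      y_train[fl] <- factor(ifelse(y_train[fl] == "CASE", "NORMAL", "CASE"),
                            levels = levels(y))
    }
    fit <- e1071::svm(x[train, , drop = FALSE], y_train, kernel = "linear",
                      cost = cost, scale = FALSE)
    pred <- stats::predict(fit, x[test, , drop = FALSE])
    acc[k] <- mean(pred == y[test])
    scores[[k]] <- tibble(sample_id = test, truth = as.character(y[test]),
                          score = unname(case_scores(fit, x[test, , drop = FALSE])),
                          fold = k)
  }
  scores <- dplyr::bind_rows(scores)
  structure(
    list(fold_accuracies = acc, mean_accuracy = mean(acc),
         auc = roc_auc(scores$score, scores$truth),
         feature_genes = feature_genes, n_folds = n_folds, cost = cost,
         noise_fraction = noise_fraction, scores = scores),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "%d-fold CV on %d feature gene(s): mean accuracy %.4f, AUC %.4f\n",
    x$n_folds, length(x$feature_genes), x$mean_accuracy, x$auc))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank-sum (Mann-Whitney) formulation with midrank tie handling: the
#' probability that a random CASE score exceeds a random NORMAL score,
#' counting ties as one half.
#'
#' @param scores Numeric classifier scores (larger favours CASE).
#' @param truth Character/factor vector of `"NORMAL"`/`"CASE"`, or logical
#'   (`TRUE` = CASE), aligned with `scores`.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, truth) {
  pos <- if (is.logical(truth)) truth else as.character(truth) == "CASE"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) abort("Both classes must be present to compute AUC.")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Label-noise robustness of cross-validated accuracy
#'
#' Repeats cross-validation while flipping a random fraction of training
#' labels in every fold, `n_reps` times per fraction, keeping the fold
#' partition fixed. Reports mean, SD, a normal-approximation 95% interval
#' for the mean, and empirical 2.5/97.5 percentiles per fraction.
#'
#' @param expr,labels,feature_genes,n_folds,cost As in [crossvalidate()].
#' @param fractions Noise fractions in `[0, 0.5)`.
#' @param n_reps Repetitions per fraction (default 100).
#' @param rng_seed Seed: fixes the fold partition and the per-repetition
#'   noise streams.
#' @return Object of class `noise_report`: `summary` tibble (`fraction`,
#'   `mean_accuracy`, `sd_accuracy`, `ci_lower`, `ci_upper`, `q025`,
#'   `q975`), `reps` tibble (`fraction`, `rep`, `accuracy`), and
#'   `n_repetitions`.
#' @export
noise_robustness <- function(expr, labels, feature_genes,
                             fractions = seq(0.01, 0.10, by = 0.01),
                             n_reps = 100, n_folds = 10, rng_seed = 1,
                             cost = 1) {
  stopifnot(all(fractions >= 0), all(fractions < 0.5), n_reps >= 1)
  noise_seeds <- withr::with_seed(rng_seed, {
    matrix(sample.int(.Machine$integer.max, length(fractions) * n_reps),
           nrow = length(fractions))
  })
  reps <- purrr::map(seq_along(fractions), function(i) {
    acc <- vapply(seq_len(n_reps), function(r) {
      crossvalidate(expr, labels, feature_genes, n_folds = n_folds,
                    rng_seed = rng_seed, cost = cost,
                    noise_fraction = fractions[i],
                    noise_seed = noise_seeds[i, r])$mean_accuracy
    }, numeric(1))
    tibble(fraction = fractions[i], rep = seq_len(n_reps), accuracy = acc)
  })
  reps <- dplyr::bind_rows(reps)
  summary <- dplyr::summarise(
    dplyr::group_by(reps, .data$fraction),
    mean_accuracy = mean(.data$accuracy),
    sd_accuracy = sd(.data$accuracy),
    ci_lower = mean(.data$accuracy) - 1.96 * sd(.data$accuracy) / sqrt(dplyr::n()),
    ci_upper = mean(.data$accuracy) + 1.96 * sd(.data$accuracy) / sqrt(dplyr::n()),
    q025 = unname(stats::quantile(.data$accuracy, 0.025)),
    q975 = unname(stats::quantile(.data$accuracy, 0.975)),
    .groups = "drop")
  structure(list(summary = summary, reps = reps, n_repetitions = n_reps,
                 n_folds = n_folds, rng_seed = rng_seed),
            class = "noise_report")
}

#' @export
print.noise_report <- function(x, ...) {
  cat(sprintf("Label-noise robustness (%d reps, %d-fold CV):\n",
              x$n_repetitions, x$n_folds))
  print(as.data.frame(x$summary), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Compare feature sets by cross-validated accuracy
#'
#' Cross-validates each candidate biomarker gene set with a shared fold
#' partition and reports mean accuracy and across-fold variance per set.
#'
#' @param expr,labels,n_folds,rng_seed,cost As in [crossvalidate()].
#' @param feature_sets Named list of character vectors of feature genes.
#' @return Tibble with one row per set: `name`, `mean_accuracy`,
#'   `var_accuracy`, `auc`.
#' @export
compare_biomarkers <- function(expr, labels, feature_sets, n_folds = 10,
                               rng_seed = 1, cost = 1) {
  if (!length(feature_sets)) abort("Need at least one feature set.")
  if (is.null(names(feature_sets))) abort("`feature_sets` must be named.")
  rows <- purrr::imap(feature_sets, function(genes, nm) {
    cv <- crossvalidate(expr, labels, genes, n_folds = n_folds,
                        rng_seed = rng_seed, cost = cost)
    tibble(name = nm, mean_accuracy = cv$mean_accuracy,
           var_accuracy = var(cv$fold_accuracies), auc = cv$auc)
  })
  dplyr::bind_rows(rows)
}
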