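test_that("ROC AUC handles perfect, inverted, and tied rankings", {
  truth <- c("CASE", "CASE", "NORMAL", "NORMAL")
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), truth), 1)
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), rev(truth)), 0)
  expect_equal(roc_auc(rep(0.5, 4), truth), 0.5)
  expect_error(roc_auc(1:3, rep("CASE", 3)), "Both classes")
})

test_that("AUC equals an independent ROC implementation on random inputs", {
  skip_if_not_installed("pROC")
  withr::with_seed(14, {
    for (i in 1:100) {
      n <- sample(10:60, 1)
      truth <- sample(c("NORMAL", "CASE"), n, replace = TRUE)
      if (length(unique(truth)) < 2) next
      scores <- round(rnorm(n), sample(0:2, 1)) # induce ties sometimes
      ref <- as.numeric(pROC::auc(pROC::roc(
        response = truth, predictor = scores, levels = c("NORMAL", "CASE"),
        direction = "<", quiet = TRUE)))
      expect_equal(roc_auc(scores, truth), ref, tolerance = 1e-12)
    }
  })
})

test_that("stratified folds partition samples with balanced class proportions", {
  toy <- toy_dataset(n_genes = 4, n_per_group = 23, seed = 6)
  cv <- crossvalidate(toy$expr, toy$labels, c("g1", "g2"), n_folds = 5,
                      rng_seed = 3)
  # every sample appears in exactly one test fold
  expect_setequal(cv$scores$sample_id, toy$labels$sample_id)
  expect_equal(nrow(cv$scores), nrow(toy$labels))
  per_fold <- table(cv$scores$fold, cv$scores$truth)
  expect_true(all(abs(per_fold[, "CASE"] - 23 / 5) < 1.5))
  expect_equal(cv$mean_accuracy, mean(cv$fold_accuracies))
  expect_error(crossvalidate(toy$expr, toy$labels, "g1", n_folds = 30),
               "n_folds")
})

test_that("well-separated classes classify nearly perfectly; permuted labels do not", {
  sep <- toy_dataset(n_genes = 6, n_per_group = 50,
                     shift_genes = c("g1", "g2"), shift = 6, seed = 7)
  cv <- crossvalidate(sep$expr, sep$labels, c("g1", "g2"), rng_seed = 1)
  expect_gte(cv$mean_accuracy, 0.95)
  expect_gte(cv$auc, 0.95)

  perm <- toy_dataset(n_genes = 6, n_per_group = 100, seed = 8)
  cvp <- crossvalidate(perm$expr, perm$labels, c("g1", "g2"), rng_seed = 2)
  expect_lt(abs(cvp$mean_accuracy - 0.5), 0.15)

  # determinism
  cv2 <- crossvalidate(sep$expr, sep$labels, c("g1", "g2"), rng_seed = 1)
  expect_identical(cv$fold_accuracies, cv2$fold_accuracies)
  expect_identical(cv$scores, cv2$scores)
})

test_that("zero label noise reproduces the baseline and reports are reproducible", {
  sep <- toy_dataset(n_genes = 5, n_per_group = 30,
                     shift_genes = c("g1", "g2"), shift = 4, seed = 9)
  base <- crossvalidate(sep$expr, sep$labels, c("g1", "g2"), rng_seed = 5)
  nr <- noise_robustness(sep$expr, sep$labels, c("g1", "g2"),
                         fractions = 0, n_reps = 3, rng_seed = 5)
  expect_equal(unique(nr$reps$accuracy), base$mean_accuracy)
  expect_true(all(nr$summary$ci_lower <= nr$summary$mean_accuracy &
                    nr$summary$mean_accuracy <= nr$summary$ci_upper))
  nr2 <- noise_robustness(sep$expr, sep$labels, c("g1", "g2"),
                          fractions = 0, n_reps = 3, rng_seed = 5)
  expect_identical(nr$reps, nr2$reps)
})

test_that("planted features beat random features of the same size", {
  inst <- generate_instance(synthetic_spec(n_genes = 150, n_per_group = 30,
                                           planted_size = 8, rng_seed = 41))
  expr <- zscore_rows(inst$expr)
  random_genes <- setdiff(rownames(expr), inst$truth$planted_genes)[1:8]
  cmp <- compare_biomarkers(
    expr, inst$labels,
    list(planted = inst$truth$planted_genes, random = random_genes),
    rng_seed = 4)
  expect_equal(cmp$name, c("planted", "random"))
  expect_gt(cmp$mean_accuracy[1], cmp$mean_accuracy[2])
  # duplicated set under two names gives identical rows
  cmp2 <- compare_biomarkers(
    expr, inst$labels,
    list(a = inst$truth$planted_genes, b = inst$truth$planted_genes),
    rng_seed = 4)
  expect_equal(cmp2$mean_accuracy[1], cmp2$mean_accuracy[2])
  expect_equal(cmp2$auc[1], cmp2$auc[2])
})

test_that("tidiers and autoplot methods return well-formed objects", {
  sep <- toy_dataset(n_genes = 5, n_per_group = 20,
                     shift_genes = "g1", shift = 4, seed = 10)
  cv <- crossvalidate(sep$expr, sep$labels, "g1", n_folds = 5, rng_seed = 1)
  td <- tidy(cv)
  expect_equal(nrow(td), 5)
  gl <- glance(cv)
  expect_equal(gl$mean_accuracy, cv$mean_accuracy)
  expect_s3_class(autoplot(cv), "ggplot")

  nr <- noise_robustness(sep$expr, sep$labels, "g1", fractions = c(0, 0.1),
                         n_reps = 2, n_folds = 5, rng_seed = 1)
  expect_equal(nrow(tidy(nr)), 2)
  expect_named(glance(nr), c("n_fractions", "n_repetitions",
                             "accuracy_low_noise", "accuracy_high_noise",
                             "accuracy_drop"))
  expect_s3_class(autoplot(nr), "ggplot")
})
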