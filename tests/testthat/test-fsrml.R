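test_that("binarization follows the sigmoid rule with arg-max repair", {
  expect_identical(binarize_position(rep(10, 6)), rep(1L, 6))
  r <- binarize_position(rep(-10, 6))
  expect_equal(sum(r), 1L)  # repair forces exactly one bit on
  expect_identical(binarize_position(c(0.3, -0.2, 1.5)), c(1L, 0L, 1L))
  expect_error(binarize_position(c(1, NaN)), "finite")
})

test_that("mask objective reflects feature information content", {
  # constant feature, balanced labels: accuracy collapses to the majority rate
  n <- 200
  cohort <- data.frame(flat = rep(1, n), nodule = rep(0:1, each = n / 2))
  obj <- mask_objective(1L, cohort, "LR", folds = 5, seed = 1)
  expect_lt(abs(obj - 0.5), 0.05)
  # a feature equal to the label separates perfectly under a tree
  sep <- separable_cohort(100)
  expect_equal(mask_objective(c(1L, 0L), sep, "DT", folds = 5, seed = 1), 0)
  # informative mask beats the noise mask on a synthetic cohort
  cohort <- generate_logistic_cohort(cohort_spec(n = 1000, seed = 3))
  feats <- setdiff(names(cohort), "nodule")
  informative <- as.integer(feats %in% names(cohort_spec()$effects))
  expect_lt(mask_objective(informative, cohort, "LR", seed = 1),
            mask_objective(1L - informative, cohort, "LR", seed = 1))
})

test_that("mask objective validates its inputs", {
  toy <- toy_cohort(50)
  expect_error(mask_objective(c(0L, 0L), toy, "LR"), "empty")
  expect_error(mask_objective(1L, toy, "LR"), "mask length")
  expect_error(mask_objective(c(1L, 1L), toy, "nope"), "LR.*XGBoost")
  tiny <- toy_cohort(8)
  expect_error(mask_objective(c(1L, 1L), tiny, "LR", folds = 5), "degenerate")
})

test_that("split arithmetic matches the published cohort partition", {
  expect_identical(train_test_split_counts(4861, 0.8),
                   c(train = 3889L, test = 972L))
  expect_identical(train_test_split_counts(10, 0.5),
                   c(train = 5L, test = 5L))
  expect_identical(train_test_split_counts(4861, 0.2),
                   c(train = 972L, test = 3889L))
  expect_error(train_test_split_counts(1, 0.8), "at least 2")
  expect_error(train_test_split_counts(100, 1.2), "train_fraction")
})

test_that("stratified split preserves class balance and partitions the data", {
  y <- rep(c(0, 1), c(400, 100))
  sp <- stratified_split(y, 0.8, seed = 9)
  expect_setequal(c(sp$train, sp$test), seq_along(y))
  expect_equal(sum(y[sp$train]), 80)  # 80% of each class
  expect_equal(length(sp$train), 400)
  expect_identical(sp, stratified_split(y, 0.8, seed = 9))
})

test_that("the wrapper is deterministic and reproducible at the reported accuracy", {
  toy <- toy_cohort(150)
  ctl <- tiny_control(seed = 5, pop = 6, iters = 4)
  f1 <- fsrml(toy, base_model = "LR", control = ctl)
  f2 <- fsrml(toy, base_model = "LR", control = ctl)
  expect_identical(f1$mask, f2$mask)
  expect_identical(f1$cv_accuracy, f2$cv_accuracy)
  # reported CV accuracy re-scores exactly with the stored folds/seed
  rescore <- 1 - mask_objective(f1$mask, toy, "LR", folds = f1$folds,
                                seed = f1$seed)
  expect_equal(f1$cv_accuracy, rescore, tolerance = 1e-12)
})

test_that("a single-predictor cohort forces the full mask", {
  one <- data.frame(only = rnorm(80), nodule = rep(0:1, 40))
  fit <- fsrml(one, base_model = "LR", control = tiny_control(pop = 4,
                                                              iters = 2))
  expect_identical(unname(fit$mask), 1L)
  expect_identical(fit$selected, "only")
})

test_that("wrapper methods print, coef, predict and plot coherently", {
  toy <- toy_cohort(150)
  fit <- fsrml(toy, base_model = "LR", control = tiny_control())
  expect_output(print(fit), "CV accuracy")
  expect_output(print(summary(fit)), "selected features")
  expect_identical(coef(fit), fit$mask)
  p <- predict(fit, toy)
  expect_true(all(p >= 0 & p <= 1))
  cls <- predict(fit, toy, type = "class")
  expect_true(all(cls %in% 0:1))
  # the signal feature must have been kept on this easy cohort
  expect_true("f1" %in% fit$selected)
  expect_error(predict(fit, data.frame(nodule = 1)), "missing required")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("informative features are selected more often than noise on average", {
  spec <- cohort_spec(n = 1000)
  feats <- spec$schema$name
  informative <- names(spec$effects)
  sel <- matrix(0L, 3, 33)
  for (s in 1:3) {
    cohort <- generate_logistic_cohort(spec, seed = 300 + s)
    fit <- fsrml(cohort, base_model = "LR", binarize_rule = "threshold",
                 sparsity_weight = 5e-4,
                 control = stoa_control(population_size = 16,
                                        max_iterations = 100, seed = s))
    sel[s, ] <- unname(fit$mask)
  }
  freq <- setNames(colMeans(sel), feats)
  expect_gt(mean(freq[informative]),
            mean(freq[setdiff(feats, informative)]))
  # the strongest effects should be recovered in every run
  expect_equal(unname(freq["age"]), 1)
  expect_equal(unname(freq["smoking"]), 1)
})

test_that("every base model can fit and score the toy cohort", {
  toy <- toy_cohort(120)
  for (m in base_models()) {
    obj <- mask_objective(c(1L, 1L), toy, m, folds = 3, seed = 2)
    expect_true(is.finite(obj) && obj >= 0 && obj <= 1, label = m)
    # strong single signal: every learner should beat chance comfortably
    expect_lt(obj, 0.35, label = m)
  }
})
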