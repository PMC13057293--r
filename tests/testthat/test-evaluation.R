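test_that("stratified folds balance classes to within one sample", {
  withr::with_seed(2, {
    labels <- rep(c(0L, 1L), times = c(850, 884))[sample(1734)]
  })
  folds <- stratified_folds(labels, 10L, seed = 3L)
  expect_identical(sort(unique(folds)), 1:10)
  tab <- table(folds, labels)
  expect_lte(diff(range(tab[, "1"])), 1)
  expect_lte(diff(range(tab[, "0"])), 1)
  expect_lte(diff(range(rowSums(tab))), 2)
  # every sample tested exactly once
  expect_identical(length(folds), 1734L)
  expect_error(stratified_folds(rep(0:1, c(5, 100)), 10L), "at least n_folds")
})

test_that("metrics reproduce the published confusion-matrix worked example", {
  m <- compute_metrics(list(TP = 83, TN = 89, FP = 0, FN = 2))
  expect_equal(m$accuracy, 172 / 174)             # ~98.9%
  expect_equal(m$sensitivity, 83 / 85)            # ~97.6%
  expect_equal(m$specificity, 1)                  # 100%
})

test_that("metric edge cases: perfection, constant scores, empty classes", {
  y <- rep(c(1L, 0L), each = 10)
  perfect <- compute_metrics(list(TP = 10, TN = 10, FP = 0, FN = 0),
                             scores = y, labels = y)
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1",
                                "sensitivity", "specificity")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1,
                 sensitivity = 1, specificity = 1))
  expect_equal(perfect$auc, 1)

  const <- compute_metrics(list(TP = 5, TN = 0, FP = 5, FN = 5),
                           scores = rep(0.4, 15),
                           labels = c(rep(1L, 10), rep(0L, 5)))
  expect_equal(const$auc, 0.5)                    # tied ranks

  undef <- compute_metrics(list(TP = 0, TN = 10, FP = 5, FN = 0))
  expect_true(is.na(undef$sensitivity))           # no positives: NA, not 0
  expect_false(is.na(undef$specificity))
})

test_that("weighted recall equals accuracy on random confusions", {
  withr::with_seed(11, {
    for (i in 1:25) {
      cm <- as.list(stats::setNames(rpois(4, 20) + 1L, c("TP", "TN", "FP", "FN")))
      m <- compute_metrics(cm)
      expect_equal(m$recall, m$accuracy, tolerance = 1e-12)
    }
  })
})

test_that("model specs enforce the block-count architecture contract", {
  expect_length(model_spec("dnn")$hidden_sizes, 4L)
  expect_length(model_spec("snn")$hidden_sizes, 3L)
  expect_error(model_spec("dnn", hidden_sizes = c(8, 8)), "4 hidden")
  expect_error(model_spec("snn", hidden_sizes = c(8, 8, 8, 8)), "3 hidden")
  expect_error(model_spec("made_up"), "unknown model kind")
  expect_identical(model_spec("dnn")$batch_size, 16L)
  expect_identical(model_spec("dnn")$optimizer, "nadam")
  expect_equal(model_spec("dnn")$learning_rate, 0.001)
  expect_identical(model_spec("dnn")$max_epochs, 30L)
})

test_that("neural models accept Top-k input sizes and are seed-deterministic", {
  withr::with_seed(31, {
    n <- 160
    y <- rep(c(0L, 1L), each = n / 2)
    X <- cbind(matrix(rnorm(n * 18), n, 18), 2 * y + rnorm(n, sd = 0.4),
               2 * y + rnorm(n, sd = 0.4))
  })
  spec <- model_spec("snn", max_epochs = 15L, seed = 5L)
  m1 <- fit_model(build_model(spec, 20L), X, y)
  m2 <- fit_model(build_model(spec, 20L), X, y)
  expect_identical(predict_model(m1, X), predict_model(m2, X))
  # a separable direction should be learned well on the training data
  expect_gt(mean((predict_model(m1, X) > 0.5) == y), 0.9)
  expect_error(fit_model(build_model(spec, 10L), X, y), "input_dim")
})

test_that("run_cv tests every sample exactly once and is deterministic", {
  fm <- tiny_feature_matrix(band_effect_d = c(theta = 3, delta = 2,
                                              alpha = 0, beta = 0, gamma = 0))
  spec <- model_spec("lda")
  rep1 <- run_cv(fm, spec, n_folds = 4L, seed = 2L)
  rep2 <- run_cv(fm, spec, n_folds = 4L, seed = 2L)
  expect_identical(rep1$per_fold, rep2$per_fold)
  total <- sum(vapply(rep1$confusion, function(cm) sum(unlist(cm)), 0))
  expect_equal(total, length(fm$labels))
  expect_identical(rownames(rep1$aggregate), c("average", "maximum"))
  expect_gte(rep1$aggregate["maximum", "accuracy"],
             rep1$aggregate["average", "accuracy"])
  # strong injected theta/delta effect separates the tiny cohort well
  expect_gt(rep1$aggregate["average", "accuracy"], 0.9)
})

test_that("subject-wise grouping keeps each subject's epochs in one fold", {
  fm <- tiny_feature_matrix()
  rep <- run_cv(fm, model_spec("gaussian_nb"), n_folds = 3L, seed = 1L,
                grouping = "subject")
  expect_identical(rep$config$grouping, "subject")
  total <- sum(vapply(rep$confusion, function(cm) sum(unlist(cm)), 0))
  expect_equal(total, length(fm$labels))
})

test_that("classical baselines produce valid probabilities", {
  fm <- tiny_feature_matrix(band_effect_d = c(theta = 3, delta = 0, alpha = 0,
                                              beta = 0, gamma = 0))
  sub <- subset_features(fm, grep("^theta", fm$feature_names, value = TRUE))
  for (kind in c("lda", "logistic", "gaussian_nb", "knn")) {
    spec <- model_spec(kind, params = list(k = 5L))
    mdl <- fit_model(build_model(spec, ncol(sub$values)), sub$values, sub$labels)
    p <- predict_model(mdl, sub$values)
    expect_true(all(p >= 0 & p <= 1))
    expect_gt(mean((p > 0.5) == sub$labels), 0.8)
  }
})

test_that("benchmark_suite sweeps settings and mirrors the table layout", {
  fm <- tiny_feature_matrix(band_effect_d = c(theta = 3, delta = 2, alpha = 0,
                                              beta = 0, gamma = 0))
  configs <- list(
    list(name = "theta", features = "theta", spec = model_spec("lda")),
    list(name = "combined", features = "combined", spec = model_spec("lda")),
    list(name = "relieff_top10", features = list(method = "relieff", k = 10L),
         spec = model_spec("gaussian_nb")))
  out <- benchmark_suite(fm, configs, n_folds = 3L, seed = 5L)
  expect_named(out$reports, c("theta", "combined", "relieff_top10"))
  expect_identical(nrow(out$summary), 6L)         # Average + Maximum per config
  expect_identical(out$reports$relieff_top10$config$n_features, 10L)
  out2 <- benchmark_suite(fm, configs, n_folds = 3L, seed = 5L)
  expect_identical(out$summary, out2$summary)
  expect_error(benchmark_suite(fm, list(list(name = "bad", features = "nope",
                                             spec = model_spec("lda")))),
               "unknown feature setting")
})
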