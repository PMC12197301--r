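ns <- asNamespace("salivaflow")

test_that("Method 1 has exactly four conv, four pool, three FC layers", {
  m <- build_method1(seed = 1)
  counts <- layer_counts(m)
  expect_equal(unname(counts[c("conv", "pool", "dense")]), c(4L, 4L, 3L))
  expect_error(build_method1(input_shape = c(50, 50, 1)),
               class = "salivaflow_bad_input_shape")
})

test_that("same build seed gives identical initial parameters", {
  a <- build_method1(seed = 9)
  b <- build_method1(seed = 9)
  expect_identical(a$nn$layers[[1]]$W, b$nn$layers[[1]]$W)
  expect_identical(a$nn$layers[[9]]$W, b$nn$layers[[9]]$W)
  c_ <- build_method1(seed = 10)
  expect_false(identical(a$nn$layers[[1]]$W, c_$nn$layers[[1]]$W))
})

test_that("untrained networks output probabilities strictly inside (0,1)", {
  m1 <- build_method1(seed = 2)
  set.seed(3)
  p <- ns$nn_forward(m1$nn, array(runif(48 * 48), c(48, 48, 1)))$prob
  expect_gt(p, 0)
  expect_lt(p, 1)
  m2 <- build_method2(seed = 2)
  p2 <- ns$nn_forward(m2$nn, array(runif(32 * 32), c(32, 32, 1)))$prob
  expect_gt(p2, 0)
  expect_lt(p2, 1)
})

test_that("the fallback backbone builds offline and freezing isolates the head", {
  frozen <- build_method2(freeze = TRUE, seed = 1)
  full <- build_method2(freeze = FALSE, seed = 1)
  head_params <- sum(vapply(frozen$nn$layers, function(l) {
    if (l$type == "dense") length(l$W) + length(l$b) else 0
  }, 0))
  expect_equal(n_parameters(frozen, trainable_only = TRUE), head_params)
  expect_equal(n_parameters(full, trainable_only = TRUE),
               n_parameters(full))
  expect_error(build_method2("densenet121"),
               class = "salivaflow_backbone_unavailable")
  expect_error(build_method2("resnet50"),
               class = "salivaflow_unknown_backbone")
})

test_that("training requires both classes and memorizes a small corpus", {
  ds <- tiny_corpus(n_each = 4, seed = 8)
  single <- ds[ds$binary_label, ]
  m <- build_method2(seed = 1)
  expect_error(train_classifier(m, single, train_config(epochs = 1)),
               class = "salivaflow_single_class")
  fit <- train_classifier(m, ds, train_config(epochs = 15, batch_size = 4,
                                              seed = 2))
  expect_true(fit$trained)
  expect_equal(nrow(fit$history), 15)
  preds <- predict(fit, ds)
  expect_true(all(preds$prob > 0 & preds$prob < 1))
  expect_gte(mean(preds$is_swallow == ds$binary_label), 0.9)
})

test_that("batch predictions equal per-item predictions", {
  ds <- tiny_corpus(n_each = 3, seed = 12)
  fit <- train_classifier(build_method1(seed = 1), ds,
                          train_config(epochs = 3, batch_size = 3, seed = 4))
  batch <- predict(fit, ds)
  single <- vapply(ds$clip, function(cl) predict(fit, cl)$prob, 0)
  expect_equal(batch$prob, unname(single))
  expect_error(predict(build_method1(), ds), class = "salivaflow_untrained")
})

test_that("stratified folds reproduce the study's per-fold class counts", {
  labels <- rep(c(TRUE, FALSE), c(990, 1310))
  fold <- make_stratified_folds(labels, k = 5, seed = 1)
  for (f in 1:5) {
    expect_equal(sum(labels[fold == f]), 198)        # test swallows
    expect_equal(sum(!labels[fold == f]), 262)       # test non-swallows
    expect_equal(sum(labels[fold != f]), 792)        # train swallows
    expect_equal(sum(!labels[fold != f]), 1048)      # train non-swallows
  }
})

test_that("fold sizes per class never differ by more than one", {
  set.seed(13)
  for (i in 1:10) {
    n1 <- sample(20:200, 1)
    n0 <- sample(20:200, 1)
    labels <- rep(c(TRUE, FALSE), c(n1, n0))
    fold <- make_stratified_folds(labels, k = 5, seed = i)
    for (cl in c(TRUE, FALSE)) {
      sizes <- table(fold[labels == cl])
      expect_lte(diff(range(sizes)), 1)
    }
    expect_equal(sort(unique(fold)), 1:5)
  }
})

test_that("subject-grouped folds keep each subject in one fold", {
  labels <- rep(c(TRUE, FALSE), 30)
  groups <- rep(sprintf("S%d", 1:10), each = 6)
  fold <- make_stratified_folds(labels, k = 5, seed = 2, groups = groups)
  per_subject <- tapply(fold, groups, function(f) length(unique(f)))
  expect_true(all(per_subject == 1))
})

test_that("holdout evaluation conserves counts and matches brute force", {
  ds <- tiny_corpus(n_each = 4, seed = 21)
  fit <- train_classifier(build_method2(seed = 3), ds,
                          train_config(epochs = 10, batch_size = 4, seed = 5))
  res <- holdout_evaluate(fit, ds)
  expect_equal(sum(res$confusion$n), nrow(ds))
  preds <- predict(fit, ds)
  expect_equal(res$accuracy, 1 - mean(preds$is_swallow != ds$binary_label))
  expect_gte(res$accuracy, 0)
  expect_lte(res$accuracy, 1)
})

test_that("a perfect oracle classifier scores 1.0 in every fold", {
  # checks the fold bookkeeping, not the learner: accuracy of ground truth
  labels <- rep(c(TRUE, FALSE), c(12, 18))
  fold <- make_stratified_folds(labels, k = 5, seed = 3)
  accs <- vapply(1:5, function(f) mean(labels[fold == f] == labels[fold == f]), 0)
  expect_true(all(accs == 1))
  tested <- integer(0)
  for (f in 1:5) tested <- c(tested, which(fold == f))
  expect_equal(sort(tested), seq_along(labels))   # each item tested once
})
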