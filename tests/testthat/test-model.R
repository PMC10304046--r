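test_that("a linearly separable fixture is fit to training accuracy 1", {
  obs <- separable_obs(40)
  fit <- snippet_svm(obs)
  expect_s3_class(fit, "snippet_svm")
  expect_identical(unname(predict(fit, obs)), obs$label)
})

test_that("fitting is deterministic for identical data", {
  obs <- small_labeled_obs(seed = 3)
  f1 <- snippet_svm(obs)
  f2 <- snippet_svm(obs)
  expect_identical(f1$w, f2$w)
  expect_identical(f1$b, f2$b)
})

test_that("single-class training data is rejected", {
  obs <- separable_obs(20)
  obs$label <- "yes"
  expect_error(snippet_svm(obs), "degenerate training set")
  expect_error(cross_validate(transform(obs, label = "no"), k = 2),
               "degenerate training set")
})

test_that("the stored (w, b) reproduces the solver's decision function", {
  obs <- small_labeled_obs(seed = 8)
  fit <- snippet_svm(obs)
  x <- vectorize_observations(obs, fit$space)
  y <- factor(tolower(obs$label), levels = c("no", "yes"))
  ref <- e1071::svm(x, y, type = "C-classification", kernel = "linear",
                    cost = 1, scale = FALSE)
  expect_identical(unname(predict(fit, obs)),
                   as.character(predict(ref, x)))
  dv <- attr(predict(ref, x, decision.values = TRUE), "decision.values")
  orient <- if (startsWith(colnames(dv), "yes")) 1 else -1
  expect_equal(predict(fit, obs, type = "decision"),
               orient * as.numeric(dv), tolerance = 1e-10)
})

test_that("model serialization round-trips the decision function bit-exactly", {
  obs <- small_labeled_obs(seed = 5)
  fit <- snippet_svm(obs)
  path <- withr::local_tempfile(fileext = ".json")
  write_snippet_svm(fit, path)
  back <- read_snippet_svm(path)
  expect_identical(back$w, fit$w)
  expect_identical(back$b, fit$b)
  expect_identical(back$space$bigrams, fit$space$bigrams)
  expect_identical(predict(back, obs, type = "decision"),
                   predict(fit, obs, type = "decision"))
})

test_that("precision/recall/F1 follow the confusion-count definitions", {
  m <- precision_recall_f1(tp = 3, fp = 1, fn = 1)
  expect_equal(unname(m), c(0.75, 0.75, 0.75))
  # undefined ratios surface as NA, never as silent zeros
  expect_true(is.na(precision_recall_f1(0, 0, 5)[["precision"]]))
  expect_true(is.na(precision_recall_f1(0, 3, 0)[["recall"]]))
  expect_equal(harmonic_f1(0.5, 1), 2 / 3)
})

test_that("stratified folds partition near-evenly within each class", {
  lab <- rep(c("yes", "no"), c(70, 30))
  fold <- stratified_folds(lab, k = 10, seed = 2)
  expect_identical(sort(unique(fold)), 1:10)
  per_yes <- table(fold[lab == "yes"])
  per_no <- table(fold[lab == "no"])
  expect_lte(diff(range(per_yes)), 1)
  expect_lte(diff(range(per_no)), 1)
  # same seed, same assignment
  expect_identical(fold, stratified_folds(lab, k = 10, seed = 2))
})

test_that("cross-validation is reproducible and reports coherent averages", {
  obs <- small_labeled_obs(seed = 13)
  cv1 <- cross_validate(obs, k = 5, seed = 4)
  cv2 <- cross_validate(obs, k = 5, seed = 4)
  expect_identical(cv1[setdiff(names(cv1), "fold_weights")],
                   cv2[setdiff(names(cv2), "fold_weights")])
  expect_identical(cv1$fold_weights, cv2$fold_weights)
  # weighted F1 lies between the class F1 values
  expect_gte(cv1$weighted$f1, min(cv1$per_class$f1))
  expect_lte(cv1$weighted$f1, max(cv1$per_class$f1))
  # per-class metrics agree with a brute-force confusion counter
  pr <- cv1$predictions
  for (cls in c("yes", "no")) {
    tp <- sum(pr$pred == cls & pr$label == cls)
    fp <- sum(pr$pred == cls & pr$label != cls)
    fn <- sum(pr$pred != cls & pr$label == cls)
    row <- cv1$per_class[cv1$per_class$class == cls, ]
    expect_equal(row$precision, tp / (tp + fp))
    expect_equal(row$recall, tp / (tp + fn))
  }
  expect_error(cross_validate(obs[1:5, ], k = 10), "exceeds")
})

test_that("no test-fold information leaks into training-fold weights", {
  obs <- small_labeled_obs(seed = 21)
  cv <- cross_validate(obs, k = 5, seed = 9)
  f <- 3L
  # refit on the training folds only, with the held-out fold's labels
  # scrambled: the stored fold weights must be unchanged
  scrambled <- obs
  te <- which(cv$fold == f)
  scrambled$label[te] <- sample(scrambled$label[te])
  refit <- snippet_svm(scrambled[cv$fold != f, , drop = FALSE])
  expect_identical(refit$w, cv$fold_weights[[f]])
  # and the held-out fold's tokens contribute no feature columns
  sp_tr <- build_feature_space(obs[cv$fold != f, , drop = FALSE])
  expect_identical(names(cv$fold_weights[[f]]),
                   c(sp_tr$bigrams, paste0("kw:", sp_tr$keywords),
                     "kw:(unknown)"))
})
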