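test_that("Monte-Carlo splits are class-proportional, disjoint and seeded", {
  y <- factor(rep(c("baseline", "post"), each = 90))
  spl <- mc_splits(y, runs = 20, seed = 3)
  expect_length(spl, 20)
  for (s in spl) {
    expect_equal(length(s$train), 120)
    expect_equal(sum(y[s$train] == "baseline"), 60)
    expect_equal(sum(y[s$test] == "post"), 30)
    expect_length(intersect(s$train, s$test), 0)
    expect_setequal(c(s$train, s$test), seq_along(y))
  }
  expect_identical(spl, mc_splits(y, runs = 20, seed = 3))
  expect_length(mc_splits(y, runs = 1, seed = 1), 1)
  expect_error(mc_splits(factor(c("a", "a", "b"))), "3")
})

test_that("all eight classifier kinds fit and predict a separable toy problem", {
  set.seed(60)
  n <- 60
  X <- cbind(sig = c(rnorm(n, 0), rnorm(n, 4)), noise = rnorm(2 * n))
  y <- factor(rep(c("baseline", "post"), each = n))
  for (sp in classifier_specs(forest_trees = 100)) {
    fit <- fit_classifier(sp, X, y)
    pr <- predict_classifier(fit, X)
    expect_gt(mean(pr$pred == y), 0.95)
    expect_length(pr$score, 2 * n)
  }
})

test_that("performance metrics match hand-computed confusion matrices", {
  lev <- c("baseline", "post")
  truth <- factor(rep(lev, each = 15), levels = lev)

  perfect <- performance_summary(list(truth), list(truth),
                                 list(c(rep(1, 15), rep(0, 15))),
                                 positive = "baseline")
  expect_true(all(perfect$metrics$median == 100))

  inverted <- factor(rev(truth), levels = lev)
  inv <- performance_summary(list(inverted), list(truth), positive = "baseline")
  expect_equal(perf_stat(inv, "accuracy"), 0)

  # 30 test cases, 26 correct: 13/15 sensitivity and specificity
  pred <- truth
  pred[c(1, 2)] <- "post"; pred[c(16, 17)] <- "baseline"
  one <- performance_summary(list(pred), list(truth), positive = "baseline")
  m <- one$metrics
  expect_equal(m$median[m$metric == "accuracy"], 26 / 30 * 100, tolerance = 1e-9)
  expect_equal(m$median[m$metric == "sensitivity"], 13 / 15 * 100, tolerance = 1e-9)
  expect_equal(m$median[m$metric == "balanced_accuracy"], 26 / 30 * 100,
               tolerance = 1e-9)
  expect_equal(m$median[m$metric == "ppv"], 13 / 15 * 100, tolerance = 1e-9)
  expect_equal(m$median[m$metric == "f1"],
               2 * (13 / 15) * (13 / 15) / (13 / 15 + 13 / 15) * 100,
               tolerance = 1e-9)

  # single-class truth is excluded with a count
  ex <- performance_summary(list(pred, truth[1:5]), list(truth, truth[1:5]),
                            positive = "baseline")
  expect_equal(ex$excluded_runs, 1)
})

test_that("rank-based AUC agrees with pROC", {
  set.seed(61)
  truth <- factor(rep(c("baseline", "post"), each = 40))
  score <- rnorm(80) + (truth == "baseline")
  ours <- performance_summary(list(truth), list(truth), list(score),
                              positive = "baseline")
  ref <- as.numeric(pROC::auc(pROC::roc(truth, score, levels = c("post", "baseline"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(perf_stat(ours, "roc_auc"), ref * 100, tolerance = 1e-9)
})

test_that("dropping a variable the tree ignores leaves accuracy unchanged", {
  set.seed(62)
  n <- 60
  X <- cbind(sig = c(rnorm(n), rnorm(n, 5)), dead = rnorm(2 * n))
  y <- factor(rep(c("baseline", "post"), each = n))
  spl <- mc_splits(y, runs = 1, seed = 4)
  h <- run_harness(X, y, classifier_specs("cart"), spl, drop_one = TRUE)
  expect_equal(unname(h$classifiers$cart$profile$dacc[1, "dead"]), 0)
  expect_gt(unname(h$classifiers$cart$profile$dacc[1, "sig"]), 0.3)
})

test_that("a single-variable design skips the drop-one stage", {
  set.seed(63)
  X <- matrix(c(rnorm(40), rnorm(40, 3)), ncol = 1,
              dimnames = list(NULL, "only"))
  y <- factor(rep(c("baseline", "post"), each = 40))
  h <- run_harness(X, y, classifier_specs("logistic_a"),
                   mc_splits(y, runs = 5, seed = 1))
  expect_equal(h$classifiers$logistic_a$profile$selected, "only")
  expect_null(h$classifiers$logistic_a$profile$dacc)
})

test_that("labels independent of the design give chance-level accuracy", {
  set.seed(64)
  X <- matrix(rnorm(180 * 5), 180, 5,
              dimnames = list(NULL, paste0("v", 1:5)))
  y <- factor(rep(c("baseline", "post"), each = 90))
  spl <- mc_splits(y, runs = 200, seed = 9)
  h <- run_harness(X, y, classifier_specs("cart"), spl, drop_one = FALSE)
  acc <- perf_stat(h$classifiers$cart$summary, "accuracy")
  expect_gte(acc, 45); expect_lte(acc, 55)
})

test_that("permuted training features reduce every classifier to guessing", {
  d <- default_test_design(seed = 10)
  specs <- classifier_specs(c("logistic_a", "naive_bayes", "knn"),
                            forest_trees = 50)
  spl <- mc_splits(d$y, runs = 60, seed = 11)
  ctl <- permutation_control(d$X, d$y, specs, spl, seed = 11)
  for (k in names(ctl)) {
    acc <- perf_stat(ctl[[k]], "accuracy")
    expect_gte(acc, 42); expect_lte(acc, 58)
  }
})

test_that("a constant single feature yields exact guessing for logistic", {
  X <- matrix(1, 60, 1, dimnames = list(NULL, "flat"))
  y <- factor(rep(c("baseline", "post"), each = 30))
  spl <- mc_splits(y, runs = 10, seed = 2)
  h <- run_harness(X, y, classifier_specs("logistic_a"), spl, drop_one = FALSE)
  expect_equal(perf_stat(h$classifiers$logistic_a$summary, "accuracy"), 50)
  ctl <- permutation_control(X, y, classifier_specs("logistic_a"), spl, seed = 2)
  expect_equal(perf_stat(ctl$logistic_a, "accuracy"), 50)
})

test_that("harness selections and summaries are reproducible under a seed", {
  set.seed(65)
  X <- matrix(rnorm(120 * 4), 120, 4, dimnames = list(NULL, paste0("v", 1:4)))
  X[, 1] <- X[, 1] + rep(c(0, 2), each = 60)
  y <- factor(rep(c("baseline", "post"), each = 60))
  specs <- classifier_specs(c("random_forest", "cart"), forest_trees = 50)
  h1 <- run_harness(X, y, specs, mc_splits(y, runs = 10, seed = 5), seed = 5)
  h2 <- run_harness(X, y, specs, mc_splits(y, runs = 10, seed = 5), seed = 5)
  expect_identical(h1$classifiers$random_forest$profile$dacc,
                   h2$classifiers$random_forest$profile$dacc)
  expect_identical(h1$classifiers$cart$summary$metrics,
                   h2$classifiers$cart$summary$metrics)
})
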