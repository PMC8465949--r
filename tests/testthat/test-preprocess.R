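test_that("Tukey ladder selection matches a direct KS comparison", {
  set.seed(10)
  x_log <- exp(rnorm(500))
  expect_equal(tukey_select(x_log)$lambda, 0)
  x_norm <- rnorm(500)
  expect_equal(tukey_select(x_norm)$lambda, 1)

  expect_warning(out <- tukey_select(rep(3, 10)), "constant")
  expect_equal(out$lambda, 1)

  # oracle: recompute every candidate's KS statistic with stats::ks.test
  lambdas <- c(-1, -0.5, 0, 0.5, 1, 2)
  for (i in 1:5) {
    x <- exp(rnorm(200, sd = runif(1, 0.2, 1.2))) + runif(1, -2, 2)
    shift <- if (min(x) <= 0) 1 - min(x) else 0
    ks <- sapply(lambdas, function(l) {
      z <- if (l == 1) x else if (l == 0) log(x + shift)
           else if (l < 0) -(x + shift)^l else (x + shift)^l
      suppressWarnings(ks.test(z, "pnorm", mean(z), sd(z))$statistic)
    })
    expect_equal(tukey_select(x)$lambda, lambdas[which.min(ks)])
  }
})

test_that("Tukey selection is invariant to positive rescaling", {
  set.seed(11)
  for (x in list(exp(rnorm(300)), exp(rnorm(300, sd = 0.3)) + 2,
                 rnorm(300)^2 + 1)) {
    l1 <- tukey_select(x)$lambda
    l2 <- tukey_select(2.5 * x)$lambda
    expect_equal(l1, l2)
  }
})

test_that("iterative Grubbs masking matches hand-computed critical values", {
  x <- c(8, 9, 10, 10, 11, 50)
  # by hand: G = |50 - mean| / sd must exceed the N = 6 critical value
  expect_gt(max(abs(x - mean(x)) / sd(x)), oracle_grubbs_crit(6))
  mask <- grubbs_iterative(x)
  expect_equal(which(mask), 6L)

  expect_equal(sum(grubbs_iterative(1:20)), 0)     # uniform grid: none
  expect_equal(sum(grubbs_iterative(c(5, 5, 5))), 0)  # zero variance

  # brute-force equivalence on all subsets of size <= 8 of a fixture pool
  pool <- c(1, 2, 2, 3, 4, 5, 30, 100)
  for (k in 3:8) {
    combos <- combn(length(pool), k)
    for (j in seq_len(ncol(combos))) {
      v <- pool[combos[, j]]
      expect_identical(grubbs_iterative(v), oracle_grubbs_mask(v))
    }
  }
})

test_that("median imputation fills with per-variable per-occasion medians", {
  sch <- toy_schema()
  tab <- toy_cohort()
  out <- impute_block(tab, sch, "anatomy", method = "median")
  # scoreA missing at p2/post; only other post value is 20
  expect_equal(out$scoreA[4], 20)
  full <- out
  expect_identical(impute_block(full, sch, "anatomy", method = "median"), full)
})

test_that("forest imputation recovers a deterministic linear dependence", {
  set.seed(21)
  n <- 120
  A <- runif(n * 2, 1, 50)
  tab <- data.frame(patient_id = rep(sprintf("q%03d", 1:n), 2),
                    occasion = rep(c("baseline", "post"), each = n),
                    varA = A, varB = 2 * A, stringsAsFactors = FALSE)
  sch <- crs_schema(c("varA", "varB"), c("qol", "qol"),
                    c("interval", "interval"), c(0, 0), c(60, 120),
                    c("decreases", "decreases"))
  miss <- sample(n * 2, 20)
  truth <- tab$varB[miss]
  tab$varB[miss] <- NA
  out <- impute_block(tab, sch, "qol", method = "forest", seed = 2)
  rmse <- sqrt(mean((out$varB[miss] - truth)^2))
  expect_lt(rmse, 0.2 * sd(2 * A))
})

test_that("a fully missing variable is reported by name", {
  sch <- toy_schema()
  tab <- toy_cohort()
  tab$scoreB <- NA_real_
  expect_error(impute_block(tab, sch, "qol", method = "median"), "scoreB")
})

test_that("one-hot recoding maps missing categoricals to the zero condition", {
  sch <- toy_schema()
  tab <- toy_cohort()
  tab$scoreA[4] <- 5  # complete the interval columns first
  enc <- encode_onehot(tab, sch)

  expect_equal(enc$flagD, c(1, 1, 0, 0))        # binary passes as one column
  tab2 <- tab; tab2$flagD[2] <- NA
  expect_equal(encode_onehot(tab2, sch)$flagD[2], 0)

  cols <- paste0("colorE_", 1:3)
  expect_true(all(cols %in% names(enc)))
  m <- as.matrix(enc[cols])
  expect_equal(rowSums(m), c(1, 1, 1, 0))        # missing row sums to 0

  tab3 <- tab; tab3$colorE[1] <- 5
  expect_error(encode_onehot(tab3, sch), "unseen")

  sch_nonom <- sch[sch$scale != "nominal", ]
  class(sch_nonom) <- class(sch)
  enc2 <- encode_onehot(tab[setdiff(names(tab), "colorE")], sch_nonom)
  expect_equal(ncol(enc2), 2 + 4)               # width unchanged
})

test_that("the full preprocessing pipeline leaves no missing cells", {
  co <- default_test_cohort(seed = 6)
  dirty <- inject_artifacts(co, missing_rate = 0.03, outlier_rate = 0.005,
                            seed = 6)
  for (method in c("median", "forest")) {
    pp <- preprocess_cohort(dirty, default_schema(), impute = method, seed = 1)
    expect_false(anyNA(pp$design))
    expect_true(is.numeric(as.matrix(pp$design[setdiff(names(pp$design),
                                                       c("patient_id", "occasion"))])))
  }
  # outlier report names real injected cells
  pp <- preprocess_cohort(dirty, default_schema(), impute = "median")
  expect_gt(nrow(pp$report$outliers), 0)
})
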