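#' Class-proportional Monte-Carlo cross-validation splits
#'
#' Each run draws, independently and class-proportionally, 2/3 of the
#' cases (by default) into a training subset; the remaining 1/3 forms the
#' disjoint test subset.
#'
#' @param labels 2-level factor (or coercible) of class labels.
#' @param train_fraction fraction of each class assigned to training.
#' @param runs number of Monte-Carlo splits.
#' @param seed integer seed; equal seeds give identical split lists.
#' @return list of `runs` elements, each `list(train = idx, test = idx)`.
#' @export
mc_splits <- function(labels, train_fraction = 2 / 3, runs = 1000, seed = 1) {
  y <- factor(labels)
  if (nlevels(y) != 2) stop("exactly two classes are required")
  if (any(table(y) < 3)) stop("each class needs at least 3 members")
  set.seed(seed)
  lapply(seq_len(runs), function(r) {
    train <- unlist(lapply(levels(y), function(l) {
      idx <- which(y == l)
      sample(idx, round(length(idx) * train_fraction))
    }), use.names = FALSE)
    list(train = sort(train), test = sort(setdiff(seq_along(y), train)))
  })
}

# rank-based (Mann-Whitney) area under the ROC curve, in [0, 1]
auc_rank <- function(score, truth, positive) {
  pos <- truth == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Summarize classification performance over Monte-Carlo runs
#'
#' Computes, per run, sensitivity, specificity, positive and negative
#' predictive value, F1, accuracy, balanced accuracy and the rank-based
#' ROC-AUC, all on the percent scale, and aggregates them as the median
#' with a 2.5th/97.5th percentile interval across runs. Runs whose test
#' truth contains a single class are excluded and counted.
#'
#' @param predictions list of per-run predicted factors.
#' @param truths list of per-run true factors.
#' @param scores list of per-run numeric scores for the positive class
#'   (may be NULL; AUC is then NA).
#' @param positive the positive class label (default: first factor level).
#' @return object of class `crs_performance`: data frame `metrics` with
#'   median/ci_low/ci_high per metric (percent), `per_run` matrix,
#'   `excluded_runs` count.
#' @export
performance_summary <- function(predictions, truths, scores = NULL,
                                positive = NULL) {
  stopifnot(length(predictions) == length(truths))
  if (is.null(positive)) positive <- levels(factor(truths[[1]]))[1]
  metric_names <- c("sensitivity", "specificity", "ppv", "npv", "f1",
                    "accuracy", "balanced_accuracy", "roc_auc")
  rows <- list(); excluded <- 0
  for (r in seq_along(predictions)) {
    truth <- truths[[r]]; pred <- predictions[[r]]
    if (length(unique(truth)) < 2) { excluded <- excluded + 1; next }
    is_pos <- truth == positive
    tp <- sum(pred == positive & is_pos); fn <- sum(pred != positive & is_pos)
    fp <- sum(pred == positive & !is_pos); tn <- sum(pred != positive & !is_pos)
    sens <- tp / (tp + fn); spec <- tn / (tn + fp)
    ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
    f1 <- if (!is.na(ppv) && (ppv + sens) > 0) 2 * ppv * sens / (ppv + sens) else NA_real_
    acc <- (tp + tn) / (tp + tn + fp + fn)
    bacc <- (sens + spec) / 2
    auc <- if (!is.null(scores) && !is.null(scores[[r]]))
      auc_rank(scores[[r]], truth, positive) else NA_real_
    rows[[length(rows) + 1]] <-
      c(sens, spec, ppv, npv, f1, acc, bacc, auc) * 100
  }
  per_run <- do.call(rbind, rows)
  colnames(per_run) <- metric_names
  met <- t(apply(per_run, 2, function(v)
    stats::quantile(v, c(0.5, 0.025, 0.975), names = FALSE, na.rm = TRUE)))
  metrics <- data.frame(metric = metric_names, median = met[, 1],
                        ci_low = met[, 2], ci_high = met[, 3],
                        stringsAsFactors = FALSE)
  out <- list(metrics = metrics, per_run = per_run, excluded_runs = excluded,
              positive = positive)
  class(out) <- "crs_performance"
  out
}

#' @export
print.crs_performance <- function(x, ...) {
  cat("Classification performance over", nrow(x$per_run), "runs",
      if (x$excluded_runs) paste0("(", x$excluded_runs, " excluded)") else "",
      "\n")
  m <- x$metrics
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-18s %5.1f (%5.1f-%5.1f)\n", m$metric[i], m$median[i],
                m$ci_low[i], m$ci_high[i]))
  invisible(x)
}

#' Extract one aggregated metric from a performance summary
#'
#' @param summary a `crs_performance`.
#' @param metric one of the metric names (e.g. `"accuracy"`,
#'   `"balanced_accuracy"`, `"roc_auc"`).
#' @param what `"median"`, `"ci_low"` or `"ci_high"`.
#' @return scalar on the percent scale.
#' @export
perf_stat <- function(summary, metric, what = "median") {
  m <- summary$metrics
  m[[what]][m$metric == metric]
}

#' Monte-Carlo drop-one-variable importance harness
#'
#' For every split and classifier: fit on the training subset with all d
#' variables and record the test accuracy (`Acc_complete`); then leave
#' each variable out of training one at a time and record the reduced test
#' accuracy. The importance of a variable in that run is
#' `dAcc = Acc_complete - Acc_reduced`. Per run, the positive part of the
#' dAcc vector is categorized by computed ABC analysis and the subset-A
#' members are tallied. Per classifier, the selected set has the modal
#' size of subset A over the runs and contains the variables most often
#' placed in A (ties broken by mean dAcc, then by name).
#'
#' @param design numeric design matrix or data frame (columns = variables).
#' @param labels 2-level factor along the rows.
#' @param specs classifier specs from [classifier_specs()].
#' @param splits split list from [mc_splits()].
#' @param drop_one compute drop-one importances (set `FALSE` for
#'   performance-only evaluation).
#' @param seed base seed passed to stochastic classifiers.
#' @return object of class `crs_harness`: per classifier a list with
#'   `profile` (`dacc` runs x d matrix, `a_counts`, `modal_a_size`,
#'   `selected`) and `summary` (a `crs_performance`), plus `failures`
#'   (count of skipped runs).
#' @export
run_harness <- function(design, labels, specs, splits, drop_one = TRUE,
                        seed = 1) {
  X <- as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- paste0("v", seq_len(ncol(X)))
  y <- factor(labels)
  stopifnot(nlevels(y) == 2, length(splits) >= 1)
  d <- ncol(X); vars <- colnames(X)

  res <- list()
  for (sp in names(specs)) {
    spec <- specs[[sp]]
    dacc <- matrix(NA_real_, length(splits), d, dimnames = list(NULL, vars))
    a_member <- matrix(0, length(splits), d, dimnames = list(NULL, vars))
    a_size <- rep(NA_integer_, length(splits))
    preds <- vector("list", length(splits))
    truths <- vector("list", length(splits))
    scores <- vector("list", length(splits))
    failures <- 0

    for (r in seq_along(splits)) {
      tr <- splits[[r]]$train; te <- splits[[r]]$test
      run <- tryCatch({
        fit <- fit_classifier(spec, X[tr, , drop = FALSE], y[tr],
                              seed = seed + r)
        pr <- predict_classifier(fit, X[te, , drop = FALSE])
        acc_complete <- mean(pr$pred == y[te])
        da <- rep(NA_real_, d)
        if (drop_one && d > 1) {
          for (j in seq_len(d)) {
            fit_j <- fit_classifier(spec, X[tr, -j, drop = FALSE], y[tr],
                                    seed = seed + r, need_scores = FALSE)
            pr_j <- predict_classifier(fit_j, X[te, -j, drop = FALSE])
            da[j] <- acc_complete - mean(pr_j$pred == y[te])
          }
        }
        list(pred = pr$pred, score = pr$score, acc = acc_complete, dacc = da)
      }, error = function(e) NULL)
      if (is.null(run)) { failures <- failures + 1; next }
      preds[[r]] <- run$pred; truths[[r]] <- y[te]; scores[[r]] <- run$score
      if (drop_one && d > 1) {
        dacc[r, ] <- run$dacc
        pos <- pmax(run$dacc, 0)
        if (any(pos > 0)) {
          if (d >= 3) {
            part <- abc_partition(pos, names = vars)
            A <- part$A
          } else {
            # too few items for a curve: the strictly dominant one(s)
            A <- vars[pos == max(pos)]
          }
          a_member[r, A] <- 1
          a_size[r] <- length(A)
        } else a_size[r] <- 0L
      }
    }

    ok <- !vapply(preds, is.null, TRUE)
    summary <- performance_summary(preds[ok], truths[ok], scores[ok],
                                   positive = levels(y)[1])
    if (drop_one && d > 1) {
      a_counts <- colSums(a_member, na.rm = TRUE)
      sizes <- a_size[!is.na(a_size) & a_size > 0]
      k_star <- if (length(sizes)) {
        tb <- table(sizes)
        as.integer(names(tb)[which.max(tb)])  # first mode on ties
      } else 0L
      mean_dacc <- colMeans(dacc, na.rm = TRUE)
      ord <- order(-a_counts, -mean_dacc, vars)
      selected <- vars[ord][seq_len(k_star)]
      profile <- list(dacc = dacc, a_counts = a_counts,
                      modal_a_size = k_star, selected = selected,
                      mean_dacc = mean_dacc)
    } else {
      profile <- list(dacc = NULL, a_counts = stats::setNames(rep(0, d), vars),
                      modal_a_size = if (d == 1) 1L else 0L,
                      selected = if (d == 1) vars else character(),
                      mean_dacc = stats::setNames(rep(NA_real_, d), vars))
    }
    res[[sp]] <- list(profile = profile, summary = summary,
                      failures = failures)
  }
  out <- list(classifiers = res, n_runs = length(splits), variables = vars)
  class(out) <- "crs_harness"
  out
}

#' Permutation negative control
#'
#' Re-runs the performance part of the harness with every training column
#' independently permuted across the training rows before fitting (test
#' data untouched). This destroys all feature-label association while
#' preserving the marginal distribution of each feature, so any
#' above-chance accuracy indicates overfitting of the evaluation scheme
#' itself.
#'
#' @inheritParams run_harness
#' @param seed seed controlling the permutations.
#' @return named list of `crs_performance` objects, one per classifier.
#' @export
permutation_control <- function(design, labels, specs, splits, seed = 1) {
  X <- as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- paste0("v", seq_len(ncol(X)))
  y <- factor(labels)
  set.seed(seed)
  perms <- lapply(seq_along(splits), function(r) {
    ntr <- length(splits[[r]]$train)
    lapply(seq_len(ncol(X)), function(j) sample.int(ntr))
  })
  out <- list()
  for (sp in names(specs)) {
    spec <- specs[[sp]]
    preds <- list(); truths <- list(); scores <- list()
    for (r in seq_along(splits)) {
      tr <- splits[[r]]$train; te <- splits[[r]]$test
      Xtr <- X[tr, , drop = FALSE]
      for (j in seq_len(ncol(X))) Xtr[, j] <- Xtr[perms[[r]][[j]], j]
      run <- tryCatch({
        fit <- fit_classifier(spec, Xtr, y[tr], seed = seed + r)
        predict_classifier(fit, X[te, , drop = FALSE])
      }, error = function(e) NULL)
      if (is.null(run)) next
      k <- length(preds) + 1
      preds[[k]] <- run$pred; truths[[k]] <- y[te]; scores[[k]] <- run$score
    }
    out[[sp]] <- performance_summary(preds, truths, scores,
                                     positive = levels(y)[1])
  }
  out
}
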