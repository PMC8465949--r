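#' Classifier specifications for the feature-selection harness
#'
#' Builds the heterogeneous set of eight classifiers used by the harness:
#' a random forest (default 1500 trees), two logistic-regression variants
#' (one unpenalized maximum-likelihood fit, one weakly ridge-penalized via
#' weight decay), a linear-kernel support vector machine, k-nearest
#' neighbors (Euclidean distance, k = 7, tunable 3..9), a Gaussian naive
#' Bayes classifier, a CART tree and a rule-generating tree with entropy
#' splits (a transparent stand-in for hierarchical rule-based C5.0-style
#' classifiers).
#'
#' @param kinds subset of the eight kinds to instantiate.
#' @param forest_trees trees in the random forest (the full-fidelity
#'   setting is 1500; smaller forests are appropriate for scaled-down
#'   runs).
#' @param knn_k neighbors for kNN (3..9).
#' @param ridge_decay weight decay of the penalized logistic variant.
#' @return named list of classifier specs (class `crs_classifier_spec`).
#' @export
classifier_specs <- function(kinds = c("random_forest", "logistic_a",
                                       "logistic_b", "svm_linear", "knn",
                                       "naive_bayes", "cart", "rule_tree"),
                             forest_trees = 1500, knn_k = 7,
                             ridge_decay = 0.01) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  stopifnot(knn_k >= 3, knn_k <= 9, forest_trees >= 1)
  specs <- lapply(kinds, function(k) {
    s <- list(kind = k, forest_trees = forest_trees, knn_k = knn_k,
              ridge_decay = ridge_decay)
    class(s) <- "crs_classifier_spec"
    s
  })
  names(specs) <- kinds
  specs
}

# standardize columns by training statistics (constant columns pass through)
std_train <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  s[s == 0 | is.na(s)] <- 1
  list(mu = mu, s = s, X = sweep(sweep(X, 2, mu), 2, s, "/"))
}
std_apply <- function(st, X) sweep(sweep(X, 2, st$mu), 2, st$s, "/")

#' Fit and apply one harness classifier
#'
#' The uniform fit/predict contract behind the harness: binary labels in,
#' label predictions and positive-class scores out, for any of the eight
#' classifier kinds.
#'
#' @param spec one element of [classifier_specs()].
#' @param X numeric matrix or data frame of features (rows = cases).
#' @param y 2-level factor of class labels.
#' @param seed seed forwarded to stochastic learners (the forest).
#' @param need_scores set `FALSE` to allow cheaper fits when only label
#'   predictions will be evaluated (e.g. drop-one refits); scores are then
#'   0/1 votes for the forest.
#' @return `fit_classifier` returns a fitted-classifier object;
#'   `predict_classifier` returns `list(pred = factor, score = numeric)`
#'   where `score` is monotone in the probability of the second factor
#'   level (a decision value for the SVM).
#' @export
fit_classifier <- function(spec, X, y, seed = 1, need_scores = TRUE) {
  X <- as.matrix(X)
  lev <- levels(y)
  out <- list(kind = spec$kind, levels = lev, need_scores = need_scores)
  if (spec$kind == "random_forest") {
    out$fit <- ranger::ranger(x = X, y = y, num.trees = spec$forest_trees,
                              probability = need_scores, num.threads = 1,
                              seed = seed)
  } else if (spec$kind == "logistic_a") {
    out$fit <- suppressWarnings(
      stats::glm.fit(cbind(1, X), as.numeric(y == lev[2]),
                     family = stats::binomial()))
  } else if (spec$kind == "logistic_b") {
    df <- data.frame(X); df$.y <- y
    out$fit <- nnet::multinom(.y ~ ., data = df, decay = spec$ridge_decay,
                              trace = FALSE)
    out$cols <- colnames(df)[-ncol(df)]
  } else if (spec$kind == "svm_linear") {
    st <- std_train(X)
    out$std <- st
    out$fit <- e1071::svm(st$X, y, kernel = "linear", scale = FALSE)
  } else if (spec$kind == "knn") {
    st <- std_train(X)
    out$std <- st; out$y <- y; out$k <- spec$knn_k
  } else if (spec$kind == "naive_bayes") {
    out$fit <- e1071::naiveBayes(X, y)
    # cache the Gaussian parameters for vectorized prediction
    out$mu <- sapply(out$fit$tables, function(t) t[, 1])
    out$sd <- sapply(out$fit$tables, function(t) t[, 2])
    if (is.null(dim(out$mu))) {
      out$mu <- matrix(out$mu, nrow = 2, dimnames = list(lev, colnames(X)))
      out$sd <- matrix(out$sd, nrow = 2, dimnames = list(lev, colnames(X)))
    }
    out$sd[out$sd < 1e-3] <- 1e-3
    out$prior <- out$fit$apriori / sum(out$fit$apriori)
  } else if (spec$kind %in% c("cart", "rule_tree")) {
    df <- data.frame(X); df$.y <- y
    ctrl <- rpart::rpart.control(xval = 0, cp = 0.01)
    parms <- if (spec$kind == "rule_tree") list(split = "information")
             else list(split = "gini")
    out$fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                            control = ctrl, parms = parms)
    out$cols <- colnames(df)[-ncol(df)]
  } else stop("unknown classifier kind: ", spec$kind)
  out
}

#' @rdname fit_classifier
#' @param fit object from `fit_classifier`.
#' @export
predict_classifier <- function(fit, X) {
  X <- as.matrix(X)
  lev <- fit$levels
  score <- switch(fit$kind,
    random_forest = {
      p <- stats::predict(fit$fit, data = X, num.threads = 1)$predictions
      if (fit$need_scores) p[, lev[2]]
      else as.numeric(p == lev[2])  # classification forest: labels only
    },
    logistic_a = {
      b <- fit$fit$coefficients
      b[is.na(b)] <- 0
      stats::plogis(as.vector(cbind(1, X) %*% b))
    },
    logistic_b = {
      df <- data.frame(X); colnames(df) <- fit$cols
      as.vector(stats::predict(fit$fit, newdata = df, type = "probs"))
    },
    svm_linear = {
      pr <- stats::predict(fit$fit, std_apply(fit$std, X), decision.values = TRUE)
      dv <- as.vector(attr(pr, "decision.values"))
      # decision values are oriented toward the first training label
      if (colnames(attr(pr, "decision.values"))[1] ==
          paste(lev[2], lev[1], sep = "/")) dv else -dv
    },
    knn = {
      pr <- class::knn(fit$std$X, std_apply(fit$std, X), fit$y, k = fit$k,
                       prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == lev[2], p, 1 - p)
    },
    naive_bayes = {
      # vectorized Gaussian class-conditional log-likelihoods
      ll <- sapply(lev, function(l) {
        rowSums(stats::dnorm(X, rep(fit$mu[l, ], each = nrow(X)),
                             rep(fit$sd[l, ], each = nrow(X)), log = TRUE)) +
          log(fit$prior[l])
      })
      1 / (1 + exp(ll[, 1] - ll[, 2]))
    },
    {
      df <- data.frame(X); colnames(df) <- fit$cols
      p <- stats::predict(fit$fit, newdata = df, type = "prob")
      p[, lev[2]]
    })
  pred <- factor(ifelse(score > 0.5 |
                          (fit$kind == "svm_linear" & score > 0),
                        lev[2], lev[1]), levels = lev)
  list(pred = pred, score = as.numeric(score))
}
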