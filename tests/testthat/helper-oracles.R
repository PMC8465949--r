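# Independent oracle implementations used across the test files. These
# deliberately avoid the package's own code paths.

# Exhaustive-search ABC boundary oracle: the A|B boundary is the curve
# point closest to (0, 1), found by scanning every candidate index.
oracle_ab_index <- function(values) {
  v <- sort(values, decreasing = TRUE)
  n <- length(v)
  x <- seq_len(n) / n
  y <- cumsum(v) / sum(v)
  d <- sqrt(x^2 + (1 - y)^2)
  which(d == min(d))[1]
}

# Two-sided Grubbs critical value computed directly from its definition.
oracle_grubbs_crit <- function(N, alpha = 0.05) {
  t <- qt(1 - alpha / (2 * N), N - 2)
  ((N - 1) / sqrt(N)) * sqrt(t^2 / (N - 2 + t^2))
}

# Brute-force iterative Grubbs masking using the oracle critical value.
oracle_grubbs_mask <- function(x, alpha = 0.05) {
  mask <- rep(FALSE, length(x))
  repeat {
    keep <- which(!mask)
    if (length(keep) < 3) break
    v <- x[keep]
    if (sd(v) == 0) break
    dev <- abs(v - mean(v)) / sd(v)
    if (max(dev) <= oracle_grubbs_crit(length(v), alpha)) break
    mask[keep[which.max(dev)]] <- TRUE
  }
  mask
}

# Plain multiple correspondence analysis of an all-categorical data frame,
# via correspondence analysis of the indicator matrix.
oracle_mca_scores <- function(df) {
  Z <- do.call(cbind, lapply(df, function(col) {
    f <- factor(col)
    stats::model.matrix(~ f - 1)
  }))
  P <- Z / sum(Z)
  r <- rowSums(P); c <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - r %*% t(c)) %*% diag(1 / sqrt(c))
  sv <- svd(S)
  # standard row coordinates
  sweep(diag(1 / sqrt(r)) %*% sv$u, 2, sv$d, "*")
}

# Tiny paired toy cohort covering every scale type, built in code.
toy_schema <- function() {
  crs_schema(
    name = c("scoreA", "scoreB", "gradeC", "flagD", "colorE"),
    category = c("anatomy", "qol", "olfactory", "demographic", "demographic"),
    scale = c("interval", "interval", "ordinal", "binary", "nominal"),
    lo = c(0, 0, 0, 0, 1), hi = c(100, 50, 5, 1, 3),
    improves_when = c("decreases", "decreases", "increases", "none", "none")
  )
}

toy_cohort <- function() {
  data.frame(
    patient_id = rep(c("p1", "p2"), each = 2),
    occasion = rep(c("baseline", "post"), 2),
    scoreA = c(40, 20, 60, NA),
    scoreB = c(10, 5, 12, 6),
    gradeC = c(1, 3, 2, 2),
    flagD = c(1, 1, 0, 0),
    colorE = c(1, 1, 3, NA),
    stringsAsFactors = FALSE
  )
}

# Default synthetic cohort shared by several test files (seeded).
default_test_cohort <- function(seed = 1) {
  generate_cohort(default_config(), seed = seed)
}

# Design matrix + labels of the default cohort after median preprocessing.
default_test_design <- function(seed = 1) {
  co <- default_test_cohort(seed)
  pp <- preprocess_cohort(co, default_schema(), impute = "median")
  list(X = pp$design[setdiff(names(pp$design), c("patient_id", "occasion"))],
       y = factor(pp$design$occasion, levels = c("baseline", "post")),
       table = pp$table)
}
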