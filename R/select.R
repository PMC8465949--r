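# map design-matrix column names back to schema variables (one-hot columns
# are named <variable>_<level>)
design_to_schema <- function(cols, schema) {
  out <- stats::setNames(rep(NA_character_, length(cols)), cols)
  for (i in seq_along(cols)) {
    if (cols[i] %in% schema$name) { out[i] <- cols[i]; next }
    hit <- schema$name[vapply(schema$name,
                              function(v) startsWith(cols[i], paste0(v, "_")), TRUE)]
    if (length(hit) == 1) out[i] <- hit
  }
  out
}

#' Weighted cross-classifier consensus vote
#'
#' Combines the per-classifier subset-A membership counts into one final
#' variable set. Each classifier's vote is weighted by
#' `w = median balanced accuracy * max(0, ci_low(accuracy) - 50) / 50`,
#' i.e. by its performance and by the distance of the lower 95% CI limit of
#' its accuracy from the 50% guessing level; chance-level classifiers get
#' weight zero. The weighted membership sums are themselves categorized by
#' computed ABC analysis and subset A is returned.
#'
#' @param harness a `crs_harness` from [run_harness()].
#' @return list with `selected` (character vector, possibly empty),
#'   `scores` (weighted sums per variable), `weights` (per classifier) and
#'   `chance_level` (TRUE when every classifier weight is zero).
#' @export
consensus_vote <- function(harness) {
  stopifnot(inherits(harness, "crs_harness"))
  cls <- harness$classifiers
  w <- vapply(cls, function(cl) {
    bacc <- perf_stat(cl$summary, "balanced_accuracy")
    lo <- perf_stat(cl$summary, "accuracy", "ci_low")
    bacc * max(0, lo - 50) / 50
  }, 0)
  scores <- Reduce(`+`, Map(function(cl, wc) cl$profile$a_counts * wc, cls, w))
  if (all(w == 0) || all(scores == 0))
    return(list(selected = character(), scores = scores, weights = w,
                chance_level = TRUE))
  part <- abc_partition(scores, names = names(scores))
  list(selected = part$A, scores = scores, weights = w, chance_level = FALSE)
}

#' Feature selection with iterative category knockout
#'
#' The main fitting function of the package. Runs the Monte-Carlo drop-one
#' importance harness with all classifiers on the full design, combines
#' the per-classifier selections by the weighted consensus vote, then
#' repeats the whole procedure after removing the entire variable category
#' of the most relevant (top-ranked) consensus variable, until
#' classification accuracy
#' with the newly selected variables no longer exceeds the 50% guessing
#' level (lower 95% CI limit of the best classifier's accuracy at or below
#' 50%) or no categories remain.
#'
#' @param design numeric design data frame/matrix (e.g. the `design`
#'   element of [preprocess_cohort()], identifier columns allowed and
#'   ignored).
#' @param labels 2-level factor along the rows (the test occasion).
#' @param schema a [crs_schema]; assigns every design column to a
#'   category.
#' @param specs classifier specs (default: all eight with scaled-down
#'   forest size 300).
#' @param runs Monte-Carlo splits per iteration.
#' @param train_fraction training fraction per split.
#' @param seed integer seed.
#' @param max_iterations safety cap on knockout iterations.
#' @return object of class `crs_select`: list of `iterations`, each with
#'   `variables` (design columns in play), `harness`, `consensus`,
#'   `selected`, `category` (knocked out next), `performance`
#'   (per-classifier summaries with only the selected variables) and
#'   `chance_level`; plus `selected` (the ranked criteria list: the most
#'   relevant variable of each above-chance iteration) and the call.
#' @export
crs_select <- function(design, labels, schema, specs = NULL, runs = 200,
                       train_fraction = 2 / 3, seed = 1,
                       max_iterations = 10) {
  if (is.null(specs)) specs <- classifier_specs(forest_trees = 300)
  df <- as.data.frame(design)
  df <- df[setdiff(names(df), c("patient_id", "occasion"))]
  y <- factor(labels)
  cat_of <- design_to_schema(names(df), schema)
  if (anyNA(cat_of)) stop("design column(s) not mapped to schema: ",
                          paste(names(df)[is.na(cat_of)], collapse = ", "))
  cat_of <- stats::setNames(schema$category[match(cat_of, schema$name)], names(df))

  iterations <- list()
  remaining <- names(df)
  final_selected <- character()
  it <- 0
  while (length(remaining) && it < max_iterations) {
    it <- it + 1
    splits <- mc_splits(y, train_fraction, runs, seed = seed + 1000 * it)
    h <- run_harness(df[remaining], y, specs, splits, drop_one = TRUE,
                     seed = seed + 1000 * it)
    cons <- consensus_vote(h)
    sel <- cons$selected
    perf <- NULL; chance <- cons$chance_level
    if (length(sel)) {
      perf_h <- run_harness(df[sel], y, specs, splits, drop_one = FALSE,
                            seed = seed + 1000 * it)
      perf <- lapply(perf_h$classifiers, `[[`, "summary")
      best_lo <- max(vapply(perf, perf_stat, 0, "accuracy", "ci_low"))
      chance <- best_lo <= 50
    }
    # the category knocked out next is that of the most relevant (top-
    # ranked) consensus variable; sel is ordered by decreasing consensus
    # score
    categories <- unname(cat_of[sel[1]])
    iterations[[it]] <- list(variables = remaining, harness = h,
                             consensus = cons, selected = sel,
                             category = categories, performance = perf,
                             chance_level = chance)
    if (chance || !length(sel)) break
    final_selected <- c(final_selected, sel[1])
    remaining <- remaining[!cat_of[remaining] %in% categories]
  }
  out <- list(iterations = iterations, selected = final_selected,
              labels = levels(y), runs = runs, seed = seed,
              call = match.call())
  class(out) <- "crs_select"
  out
}

#' @export
print.crs_select <- function(x, ...) {
  cat("Monte-Carlo feature selection with category knockout\n")
  cat("  iterations:", length(x$iterations), " runs per iteration:", x$runs, "\n")
  for (i in seq_along(x$iterations)) {
    itr <- x$iterations[[i]]
    sel <- itr$selected
    cat(sprintf("  [%d] d = %2d -> %s%s%s\n", i, length(itr$variables),
                if (length(sel)) paste(utils::head(sel, 4), collapse = ", ")
                else "(none)",
                if (length(sel) > 4) sprintf(", ... (%d in subset A)",
                                             length(sel)) else "",
                if (itr$chance_level) "  [chance level - stopped]" else ""))
  }
  cat("  ranked criteria:",
      if (length(x$selected)) paste(x$selected, collapse = " > ")
      else "(none)", "\n")
  invisible(x)
}

#' @export
summary.crs_select <- function(object, ...) {
  for (i in seq_along(object$iterations)) {
    itr <- object$iterations[[i]]
    cat("Iteration", i, "(d =", length(itr$variables), "variables)\n")
    w <- itr$consensus$weights
    cat("  classifier weights:",
        paste(sprintf("%s=%.1f", names(w), w), collapse = ", "), "\n")
    cat("  consensus:", paste(itr$selected, collapse = ", "), "\n")
    if (!is.null(itr$performance)) {
      acc <- vapply(itr$performance, perf_stat, 0, "accuracy")
      lo <- vapply(itr$performance, perf_stat, 0, "accuracy", "ci_low")
      hi <- vapply(itr$performance, perf_stat, 0, "accuracy", "ci_high")
      for (k in names(acc))
        cat(sprintf("    %-14s accuracy %5.1f (%5.1f-%5.1f)\n", k, acc[k],
                    lo[k], hi[k]))
    }
  }
  invisible(object)
}

#' @export
plot.crs_select <- function(x, iteration = 1, ...) {
  itr <- x$iterations[[iteration]]
  counts <- sapply(itr$harness$classifiers, function(cl) cl$profile$a_counts)
  tot <- rowSums(counts)
  ord <- order(tot, decreasing = TRUE)
  graphics::barplot(t(counts[ord, , drop = FALSE]), las = 2,
                    cex.names = 0.6, col = grDevices::hcl.colors(ncol(counts), "Blues"),
                    main = paste("Subset-A membership counts, iteration", iteration),
                    ylab = "runs placed in ABC subset A")
  invisible(x)
}

#' Depth-1 threshold rule for a single feature
#'
#' Learns, once, on a class-proportional random `train_fraction` share of
#' the records, the single-split threshold rule that minimizes training
#' misclassification (ties resolved toward the smallest threshold), then
#' evaluates the fixed rule on bootstrap resamples of the held-out
#' records.
#'
#' @param x numeric feature vector.
#' @param y 2-level factor of labels.
#' @param train_fraction fraction used to learn the rule (default 0.8).
#' @param boots bootstrap resamples of the held-out share (default 1000).
#' @param seed integer seed.
#' @return list with `threshold`, `direction` (`">="` means: predict
#'   `positive` when `x >= threshold`), `positive` (label predicted on the
#'   high side), `train_accuracy`, and bootstrap `accuracy_median`,
#'   `ci_low`, `ci_high`.
#' @export
extract_simple_rule <- function(x, y, train_fraction = 0.8, boots = 1000,
                                seed = 1) {
  y <- factor(y)
  stopifnot(nlevels(y) == 2, length(x) == length(y))
  if (stats::sd(x, na.rm = TRUE) == 0) stop("constant feature; no rule")
  set.seed(seed)
  tr <- unlist(lapply(levels(y), function(l) {
    idx <- which(y == l)
    sample(idx, round(length(idx) * train_fraction))
  }), use.names = FALSE)
  te <- setdiff(seq_along(x), tr)

  u <- sort(unique(x[tr]))
  cand <- (u[-1] + u[-length(u)]) / 2
  best <- NULL
  for (t in cand) for (hi_lab in levels(y)) {
    pred <- ifelse(x[tr] >= t, hi_lab, setdiff(levels(y), hi_lab))
    err <- mean(pred != y[tr])
    if (is.null(best) || err < best$err - 1e-12) best <- list(t = t, hi = hi_lab, err = err)
  }
  apply_rule <- function(v) ifelse(v >= best$t, best$hi, setdiff(levels(y), best$hi))
  accs <- vapply(seq_len(boots), function(b) {
    idx <- sample(te, length(te), replace = TRUE)
    mean(apply_rule(x[idx]) == y[idx])
  }, 0) * 100
  q <- stats::quantile(accs, c(0.5, 0.025, 0.975), names = FALSE)
  list(threshold = best$t, cut_value = min(u[u > best$t]),
       direction = ">=", positive = best$hi,
       train_accuracy = (1 - best$err) * 100,
       accuracy_median = q[1], ci_low = q[2], ci_high = q[3], boot = accs)
}
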