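#' Factor analysis of mixed data
#'
#' Joint low-dimensional projection of continuous and categorical
#' variables: continuous columns are centered and scaled to unit variance
#' (population SD, i.e. denominator n); each categorical level indicator is
#' divided by the square root of its level proportion and centered, as in
#' multiple correspondence analysis. The combined matrix is decomposed by
#' SVD with row weight 1/n, so each eigenvalue is the squared singular
#' value divided by the number of rows and the total inertia equals
#' (number of continuous variables) + (total levels - number of
#' categorical variables). Dimensions with eigenvalue > 1 are retained.
#' The sign of each dimension is fixed by making its first nonzero loading
#' positive.
#'
#' @param design data frame; `factor`/`character` columns are treated as
#'   categorical, numeric columns as continuous (ordinal scales included).
#'   Identifier columns named `patient_id`/`occasion` are ignored.
#' @param min_eigen retention threshold (default 1).
#' @return object of class `crs_famd`: `eigenvalues`, `explained`
#'   (percent of total inertia per dimension), `scores`
#'   (rows x retained dims), `contrib` (per-variable percent contribution
#'   per retained dim, columns sum to 100), `n_dims`, `dropped`
#'   (constant columns removed with a warning).
#' @export
famd_fit <- function(design, min_eigen = 1) {
  df <- design[setdiff(names(design), c("patient_id", "occasion"))]
  if (!ncol(df)) stop("empty design table")
  n <- nrow(df)
  if (n < 3) stop("need at least 3 rows")

  is_cat <- vapply(df, function(c) is.factor(c) || is.character(c), TRUE)
  dropped <- character()
  for (v in names(df)) {
    vals <- df[[v]]
    if (length(unique(vals)) < 2) { dropped <- c(dropped, v) }
  }
  if (length(dropped)) {
    warning("dropping constant column(s): ", paste(dropped, collapse = ", "))
    df <- df[setdiff(names(df), dropped)]
    is_cat <- is_cat[setdiff(names(is_cat), dropped)]
  }
  if (!ncol(df)) stop("no informative columns left")

  blocks <- list(); owner <- character()
  for (v in names(df)) {
    if (!is_cat[[v]]) {
      x <- as.numeric(df[[v]])
      s <- stats::sd(x) * sqrt((n - 1) / n)
      blocks[[v]] <- matrix((x - mean(x)) / s, ncol = 1,
                            dimnames = list(NULL, v))
      owner <- c(owner, v)
    } else {
      fx <- factor(df[[v]])
      Z <- stats::model.matrix(~ fx - 1)
      colnames(Z) <- paste0(v, "_", levels(fx))
      p <- colMeans(Z)
      Zw <- sweep(Z, 2, sqrt(p), "/")
      Zw <- sweep(Zw, 2, colMeans(Zw), "-")
      blocks[[v]] <- Zw
      owner <- c(owner, rep(v, ncol(Z)))
    }
  }
  M <- do.call(cbind, blocks)
  sv <- svd(M / sqrt(n))
  eig <- sv$d^2
  pos <- eig > 1e-10
  eig <- eig[pos]
  U <- sv$u[, pos, drop = FALSE]
  V <- sv$v[, pos, drop = FALSE]
  # deterministic sign: first nonzero loading positive
  for (j in seq_len(ncol(V))) {
    nz <- which(abs(V[, j]) > 1e-10)[1]
    if (length(nz) && V[nz, j] < 0) { V[, j] <- -V[, j]; U[, j] <- -U[, j] }
  }
  keep <- which(eig > min_eigen)
  if (!length(keep)) keep <- 1L
  scores <- sweep(U[, keep, drop = FALSE], 2, sv$d[pos][keep] * sqrt(n), "*")
  colnames(scores) <- paste0("dim", keep)

  contrib <- matrix(0, length(unique(owner)), length(keep),
                    dimnames = list(unique(owner), colnames(scores)))
  for (j in seq_along(keep)) {
    cc <- V[, keep[j]]^2 * 100
    contrib[, j] <- tapply(cc, factor(owner, levels = unique(owner)), sum)
  }

  out <- list(eigenvalues = eig, explained = 100 * eig / sum(eig),
              scores = scores, contrib = contrib, n_dims = length(keep),
              retained = keep, total_inertia = sum(eig), dropped = dropped,
              n = n)
  class(out) <- "crs_famd"
  out
}

#' @export
print.crs_famd <- function(x, ...) {
  cat("Factor analysis of mixed data:", x$n, "rows,",
      length(x$eigenvalues), "dimensions,", x$n_dims, "retained (eigenvalue > 1)\n")
  k <- min(5, x$n_dims)
  cat("  eigenvalues:", paste(signif(x$eigenvalues[seq_len(k)], 3), collapse = ", "),
      if (x$n_dims > k) "..." else "", "\n")
  cat("  explained %:", paste(signif(x$explained[seq_len(k)], 3), collapse = ", "),
      "\n")
  invisible(x)
}

#' Occasion separation per retained FAMD dimension
#'
#' Tests, per retained dimension, whether the projection scores separate
#' the two label groups with a Wilcoxon-Mann-Whitney U test.
#'
#' @param model a `crs_famd` fit.
#' @param labels a two-level grouping vector along the design rows.
#' @param alpha significance level for the `significant` flag.
#' @return data frame with `dim`, `p_value`, `significant`.
#' @export
dimension_separation <- function(model, labels, alpha = 0.05) {
  stopifnot(inherits(model, "crs_famd"))
  g <- factor(labels)
  if (nlevels(g) != 2 || any(table(g) == 0))
    stop("labels must contain exactly two non-empty groups")
  p <- vapply(seq_len(ncol(model$scores)), function(j) {
    s <- model$scores[, j]
    stats::wilcox.test(s[g == levels(g)[1]], s[g == levels(g)[2]],
                       exact = FALSE)$p.value
  }, 0)
  data.frame(dim = colnames(model$scores), p_value = p,
             significant = p < alpha, stringsAsFactors = FALSE)
}

#' Variables contributing above the uniform expectation
#'
#' Returns the variables whose contribution to the given dimension exceeds
#' the value expected if all d variables contributed uniformly, i.e.
#' 100/d percent (strict inequality).
#'
#' @param model a `crs_famd` fit.
#' @param dim retained dimension index (1 = first retained).
#' @return character vector of variable names, sorted by decreasing
#'   contribution.
#' @export
top_contributors <- function(model, dim = 1) {
  stopifnot(inherits(model, "crs_famd"))
  if (dim < 1 || dim > model$n_dims) stop("dimension ", dim, " is not retained")
  co <- model$contrib[, dim]
  thr <- 100 / length(co)
  sel <- co[co > thr]
  names(sel)[order(-sel)]
}
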