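#' Sign-coded change matrix for selected variables
#'
#' Codes each patient's change from baseline to post-surgery in each
#' selected variable as +1 (improved), 0 (unchanged) or -1 (worsened),
#' after standardizing the direction of improvement via the schema's
#' `improves_when` field (e.g. a Lildholdt decrease and an olfactory
#' self-rating increase both code as +1). Variables with
#' `improves_when = "none"` are excluded with a warning.
#'
#' @param table paired cohort data frame.
#' @param selected character vector of schema variable names.
#' @param schema a [crs_schema].
#' @return object of class `crs_signmat`: integer matrix patients x
#'   variables with `row_sums` and `col_sums` attributes.
#' @export
sign_matrix <- function(table, selected, schema) {
  tab <- paired_cohort(table)
  base <- tab[tab$occasion == "baseline", , drop = FALSE]
  post <- tab[tab$occasion == "post", , drop = FALSE]
  post <- post[match(base$patient_id, post$patient_id), , drop = FALSE]

  keep <- character()
  for (v in selected) {
    i <- match(v, schema$name)
    if (is.na(i)) stop("variable '", v, "' not in schema")
    if (schema$improves_when[i] == "none") {
      warning("variable '", v, "' has no improvement direction; excluded")
    } else keep <- c(keep, v)
  }
  if (!length(keep)) stop("no variables with an improvement direction")
  m <- sapply(keep, function(v) {
    i <- match(v, schema$name)
    s <- sign(post[[v]] - base[[v]])
    if (schema$improves_when[i] == "decreases") -s else s
  })
  m <- matrix(as.integer(m), nrow(base), length(keep),
              dimnames = list(base$patient_id, keep))
  structure(m, row_sums = rowSums(m), col_sums = colSums(m),
            class = c("crs_signmat", class(m)))
}

#' Pairwise agreement of change directions
#'
#' Chi-square tests on the cross-tables of sign codes for every pair of
#' selected variables; p-values are unadjusted. Pairs involving a column
#' with a single observed sign are flagged untestable.
#'
#' @param matrix a `crs_signmat`.
#' @return data frame with `var1`, `var2`, `chi_square`, `p_value`,
#'   `untestable`.
#' @export
agreement_chi2 <- function(matrix) {
  v <- colnames(matrix)
  if (length(v) < 2) stop("at least 2 columns are required")
  rows <- list()
  for (i in seq_len(length(v) - 1)) for (j in (i + 1):length(v)) {
    a <- matrix[, i]; b <- matrix[, j]
    untestable <- length(unique(a)) < 2 || length(unique(b)) < 2 ||
      nrow(matrix) < 3
    stat <- NA_real_; p <- NA_real_
    if (!untestable) {
      tst <- suppressWarnings(stats::chisq.test(table(a, b)))
      stat <- unname(tst$statistic); p <- tst$p.value
    }
    rows[[length(rows) + 1]] <- data.frame(var1 = v[i], var2 = v[j],
                                           chi_square = stat, p_value = p,
                                           untestable = untestable,
                                           stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Patient-level overall outcome counts
#'
#' Classifies each patient by the row sum of the sign matrix: positive =
#' overall improved, zero = no consistent effect, negative = predominantly
#' worsened.
#'
#' @param matrix a `crs_signmat`.
#' @return named integer vector with counts `improved`,
#'   `no_consistent_effect`, `worsened`.
#' @export
patient_outcomes <- function(matrix) {
  rs <- attr(matrix, "row_sums")
  c(improved = sum(rs > 0), no_consistent_effect = sum(rs == 0),
    worsened = sum(rs < 0))
}

#' Symptom-freedom counts at each occasion
#'
#' Counts patients meeting each symptom-freedom criterion before and after
#' surgery: normal Lildholdt score (= 0), no significant endoscopic
#' findings (Lund-Kennedy < 2), the four SNOT-20 cutoffs (< 12 total,
#' < 12 primary, < 10.5 secondary, < 14 general), the three TDI diagnosis
#' categories, and a perceptible TDI improvement (>= 5.5 points).
#' Occasions are compared by Pearson chi-square on the occasion-by-status
#' counts (without continuity correction).
#'
#' @param table paired cohort data frame.
#' @param schema a [crs_schema].
#' @return list with `criteria` (data frame: criterion, baseline count,
#'   post count, chi_square, p_value), `tdi_diagnosis` (2 x 3 occasion x
#'   category table with chi-square test), `tdi_improved_count` (patients
#'   with a TDI gain >= 5.5) and `n` (paired patients).
#' @export
symptom_free_counts <- function(table, schema) {
  tab <- paired_cohort(table)
  base <- tab[tab$occasion == "baseline", , drop = FALSE]
  post <- tab[tab$occasion == "post", , drop = FALSE]
  post <- post[match(base$patient_id, post$patient_id), , drop = FALSE]
  n <- nrow(base)

  crits <- list(
    lildholdt_normal = function(d) d$lildholdt == 0,
    lk_no_findings   = function(d) d$lund_kennedy < 2,
    snot_total_free  = function(d) d$snot_total < 12,
    snot_primary_free = function(d) d$snot_primary < 12,
    snot_secondary_free = function(d) d$snot_secondary < 10.5,
    snot_general_free = function(d) d$snot_general < 14
  )
  rows <- lapply(names(crits), function(cn) {
    b <- sum(crits[[cn]](base), na.rm = TRUE)
    p <- sum(crits[[cn]](post), na.rm = TRUE)
    m <- rbind(c(b, n - b), c(p, n - p))
    tst <- if (all(m > 0) || (b != p))
      suppressWarnings(stats::chisq.test(m, correct = FALSE)) else NULL
    data.frame(criterion = cn, baseline = b, post = p,
               chi_square = if (is.null(tst)) NA_real_ else unname(tst$statistic),
               p_value = if (is.null(tst)) NA_real_ else tst$p.value,
               stringsAsFactors = FALSE)
  })
  criteria <- do.call(rbind, rows)

  diag_tab <- rbind(baseline = table(olfactory_diagnosis(base$tdi)),
                    post = table(olfactory_diagnosis(post$tdi)))
  diag_test <- suppressWarnings(stats::chisq.test(diag_tab, correct = FALSE))

  list(criteria = criteria, tdi_diagnosis = diag_tab,
       tdi_diagnosis_chi2 = unname(diag_test$statistic),
       tdi_diagnosis_p = diag_test$p.value,
       tdi_improved_count = sum(perceptible_improvement(base$tdi, post$tdi),
                                na.rm = TRUE),
       n = n)
}

#' Spearman correlations of changes and of post-surgery raw values
#'
#' For the selected variables, the lower triangle of the returned `rho`
#' matrix holds Spearman correlations of the per-patient baseline-to-post
#' differences; the upper triangle holds Spearman correlations of the raw
#' post-surgery values. The diagonal is 1.
#'
#' @param table paired cohort data frame.
#' @param selected schema variable names.
#' @return list with matrices `rho` and `p_value` (same layout) and
#'   logical matrix `undefined` flagging constant-input pairs.
#' @export
delta_correlations <- function(table, selected) {
  tab <- paired_cohort(table)
  base <- tab[tab$occasion == "baseline", , drop = FALSE]
  post <- tab[tab$occasion == "post", , drop = FALSE]
  post <- post[match(base$patient_id, post$patient_id), , drop = FALSE]
  k <- length(selected)
  if (k < 2) stop("at least 2 variables are required")
  deltas <- sapply(selected, function(v) post[[v]] - base[[v]])
  raws <- sapply(selected, function(v) post[[v]])

  rho <- diag(1, k); pm <- matrix(NA_real_, k, k); und <- matrix(FALSE, k, k)
  dimnames(rho) <- dimnames(pm) <- dimnames(und) <- list(selected, selected)
  fill <- function(x, y) {
    if (stats::sd(x, na.rm = TRUE) == 0 || stats::sd(y, na.rm = TRUE) == 0)
      return(NULL)
    suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  }
  for (i in 2:k) for (j in 1:(i - 1)) {
    tst <- fill(deltas[, i], deltas[, j])          # lower triangle: deltas
    if (is.null(tst)) und[i, j] <- TRUE
    else { rho[i, j] <- unname(tst$estimate); pm[i, j] <- tst$p.value }
    tst <- fill(raws[, j], raws[, i])              # upper triangle: post raw
    if (is.null(tst)) und[j, i] <- TRUE
    else { rho[j, i] <- unname(tst$estimate); pm[j, i] <- tst$p.value }
  }
  list(rho = rho, p_value = pm, undefined = und)
}
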