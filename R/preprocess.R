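#' Select a Tukey ladder-of-powers transform toward normality
#'
#' Evaluates the candidate exponents lambda in \{-1, -0.5, 0 (log), 0.5, 1,
#' 2\} as order-preserving power transforms and returns the one whose
#' transformed sample is closest to a normal distribution by the
#' Kolmogorov-Smirnov statistic (against a normal with the transformed
#' sample's own mean and SD). Log and non-identity powers operate on a
#' shifted copy `x + shift` with `shift = 1 - min(x)` whenever
#' `min(x) <= 0`, so all candidates are defined. The identity wins ties.
#'
#' @param values numeric vector with at least 8 non-missing values.
#' @param lambdas candidate exponents.
#' @return list with `lambda`, `shift`, `ks` (the winning KS statistic),
#'   `constant` (TRUE for degenerate input, where the identity is returned
#'   with a warning) and `transform`, a function applying the selection.
#' @export
tukey_select <- function(values, lambdas = c(-1, -0.5, 0, 0.5, 1, 2)) {
  x <- values[!is.na(values)]
  if (length(x) < 8) stop("at least 8 non-missing values are required")
  if (stats::sd(x) == 0) {
    warning("constant input; identity transform returned")
    return(list(lambda = 1, shift = 0, ks = NA_real_, constant = TRUE,
                transform = identity))
  }
  shift <- if (min(x) <= 0) 1 - min(x) else 0
  apply_lambda <- function(x, lam) {
    if (lam == 1) return(x)
    xs <- x + shift
    if (lam == 0) return(log(xs))
    if (lam < 0) return(-xs^lam)  # negated so the transform stays increasing
    xs^lam
  }
  ks_stat <- function(z) {
    z <- sort(z)
    p <- stats::pnorm(z, mean(z), stats::sd(z))
    n <- length(z)
    max(pmax(abs(seq_len(n) / n - p), abs(p - (seq_len(n) - 1) / n)))
  }
  ks <- vapply(lambdas, function(l) ks_stat(apply_lambda(x, l)), 0)
  best <- min(ks)
  id <- which(lambdas == 1)
  pick <- if (length(id) && ks[id] <= best + 1e-12) id else which.min(ks)
  lam <- lambdas[pick]
  list(lambda = lam, shift = shift, ks = ks[pick], constant = FALSE,
       transform = function(v) apply_lambda(v, lam))
}

#' Iterative two-sided Grubbs outlier masking
#'
#' At each iteration the statistic `G = max |x_i - mean| / sd` is compared
#' with the two-sided critical value
#' `((N-1)/sqrt(N)) * sqrt(t^2 / (N-2+t^2))` where `t` is the upper
#' `alpha/(2N)` quantile of Student's t with `N-2` degrees of freedom. If
#' significant, the most extreme point is masked and the test is repeated
#' on the remainder.
#'
#' @param values numeric vector (NAs are ignored and never masked).
#' @param alpha significance level per iteration.
#' @return logical vector along `values`; `TRUE` marks masked outliers.
#' @export
grubbs_iterative <- function(values, alpha = 0.05) {
  mask <- rep(FALSE, length(values))
  repeat {
    keep <- which(!mask & !is.na(values))
    N <- length(keep)
    if (N < 3) break
    x <- values[keep]
    s <- stats::sd(x)
    if (s == 0) break
    dev <- abs(x - mean(x)) / s
    G <- max(dev)
    tq <- stats::qt(1 - alpha / (2 * N), N - 2)
    crit <- ((N - 1) / sqrt(N)) * sqrt(tq^2 / (N - 2 + tq^2))
    if (G <= crit) break
    mask[keep[which.max(dev)]] <- TRUE
  }
  mask
}

#' Impute missing values within one variable category block
#'
#' Missing interval/ordinal cells of the block are filled either with the
#' per-variable, per-occasion median or by an iterated ensemble-of-trees
#' regression (each incomplete variable predicted from the other variables
#' of the same block, sweeps repeated until the imputed values change by
#' less than 0.1% or 10 sweeps).
#'
#' @param table cohort data frame.
#' @param schema a [crs_schema].
#' @param category block to impute: `"anatomy"`, `"olfactory"`, `"qol"` or
#'   `"demographic"`.
#' @param method `"median"` or `"forest"`.
#' @param seed seed for the forest method.
#' @param num_trees trees per forest (default 100).
#' @return `table` with the block's interval/ordinal missing cells filled.
#' @export
impute_block <- function(table, schema, category,
                         method = c("forest", "median"), seed = 1,
                         num_trees = 100) {
  method <- match.arg(method)
  vars <- schema$name[schema$category == category &
                        schema$scale %in% c("interval", "ordinal")]
  vars <- intersect(vars, names(table))
  if (!length(vars)) return(table)
  for (v in vars) if (all(is.na(table[[v]])))
    stop("variable '", v, "' is entirely missing; cannot impute")
  na_map <- lapply(table[vars], is.na)
  if (!any(unlist(na_map))) return(table)

  med_fill <- function(tab) {
    for (v in vars) {
      for (occ in unique(tab$occasion)) {
        idx <- tab$occasion == occ
        miss <- idx & is.na(tab[[v]])
        if (any(miss)) tab[[v]][miss] <- stats::median(tab[[v]][idx], na.rm = TRUE)
      }
    }
    tab
  }
  if (method == "median") return(med_fill(table))

  set.seed(seed)
  tab <- med_fill(table)  # initialization
  ord_vars <- schema$name[schema$scale == "ordinal"]
  for (sweep in seq_len(10)) {
    delta <- 0; scale_tot <- 0
    for (v in vars) {
      miss <- na_map[[v]]
      if (!any(miss)) next
      others <- setdiff(vars, v)
      if (!length(others)) next
      df <- data.frame(y = tab[[v]], tab[others], occ = as.numeric(tab$occasion == "post"))
      fit <- ranger::ranger(y ~ ., data = df[!miss, , drop = FALSE],
                            num.trees = num_trees, num.threads = 1,
                            mtry = max(1, ceiling((ncol(df) - 1) * 2 / 3)),
                            seed = seed + sweep)
      new <- stats::predict(fit, df[miss, , drop = FALSE])$predictions
      if (v %in% ord_vars) {
        i <- match(v, schema$name)
        new <- pmin(pmax(round(new), schema$lo[i]), schema$hi[i])
      }
      delta <- delta + sum((new - tab[[v]][miss])^2)
      scale_tot <- scale_tot + sum(tab[[v]][miss]^2) + 1e-12
      tab[[v]][miss] <- new
    }
    if (sqrt(delta / scale_tot) < 1e-3) break
  }
  tab
}

#' One-hot recode binary/nominal variables into a numeric design table
#'
#' Binary variables become a single 0/1 column; nominal variables become one
#' 0/1 indicator column per schema level. Missing binary/nominal values are
#' assigned to the zero condition in all derived columns. Interval and
#' ordinal columns pass through unchanged.
#'
#' @param table cohort data frame (interval/ordinal columns imputed).
#' @param schema a [crs_schema].
#' @return data frame with `patient_id`, `occasion` and numeric columns.
#' @export
encode_onehot <- function(table, schema) {
  out <- table[c("patient_id", "occasion")[c("patient_id", "occasion") %in% names(table)]]
  for (i in seq_len(nrow(schema))) {
    v <- schema$name[i]
    if (!v %in% names(table)) next
    x <- table[[v]]
    if (schema$scale[i] %in% c("interval", "ordinal")) {
      out[[v]] <- x
    } else if (schema$scale[i] == "binary") {
      bad <- !is.na(x) & !x %in% c(0, 1)
      if (any(bad)) stop("binary variable '", v, "' has level(s) outside {0, 1}")
      out[[v]] <- ifelse(is.na(x), 0, x)
    } else {  # nominal
      lv <- seq(schema$lo[i], schema$hi[i])
      bad <- !is.na(x) & !x %in% lv
      if (any(bad)) stop("nominal variable '", v, "' has unseen level(s): ",
                         paste(unique(x[bad]), collapse = ", "))
      for (l in lv) out[[paste0(v, "_", l)]] <- as.numeric(!is.na(x) & x == l)
    }
  }
  out
}

#' Full preprocessing pipeline
#'
#' Runs, in order: per-variable transform selection along Tukey's ladder of
#' powers (interval variables only), iterative Grubbs outlier removal
#' pooled over both occasions (interval variables only; masked values become
#' missing), block-wise imputation for each of the four variable
#' categories, and one-hot recoding. The result is a complete numeric
#' design table.
#'
#' @param table cohort data frame.
#' @param schema a [crs_schema].
#' @param impute `"forest"` or `"median"`.
#' @param alpha Grubbs significance level.
#' @param transform apply the selected Tukey transforms to the interval
#'   columns of the design (default FALSE: selection is reported but values
#'   are left on their clinical scales).
#' @param seed seed for the forest imputer.
#' @return list with `design` (complete numeric table), `table` (the
#'   cohort after outlier removal and imputation, original scales) and
#'   `report` (chosen transforms, removed outliers, missing counts).
#' @export
preprocess_cohort <- function(table, schema, impute = c("forest", "median"),
                              alpha = 0.05, transform = FALSE, seed = 1) {
  impute <- match.arg(impute)
  interval_vars <- intersect(schema$name[schema$scale == "interval"], names(table))
  transforms <- list()
  outliers <- list()
  miss_before <- colSums(is.na(table[intersect(schema$name, names(table))]))

  for (v in interval_vars) {
    x <- table[[v]]
    if (sum(!is.na(x)) >= 8)
      transforms[[v]] <- tukey_select(x)[c("lambda", "shift", "ks")]
    mask <- grubbs_iterative(x, alpha = alpha)
    if (any(mask)) {
      outliers[[v]] <- data.frame(patient_id = table$patient_id[mask],
                                  occasion = table$occasion[mask],
                                  variable = v, value = x[mask],
                                  stringsAsFactors = FALSE)
      table[[v]][mask] <- NA_real_
    }
  }
  for (cat in c("anatomy", "olfactory", "qol", "demographic"))
    table <- impute_block(table, schema, cat, method = impute, seed = seed)

  if (transform) {
    for (v in names(transforms)) {
      tr <- tukey_select(table[[v]])
      table[[v]] <- tr$transform(table[[v]])
    }
  }
  design <- encode_onehot(table, schema)
  report <- list(
    transforms = transforms,
    outliers = if (length(outliers)) do.call(rbind, outliers) else NULL,
    imputation = impute,
    missing_before = miss_before,
    missing_after = colSums(is.na(design[setdiff(names(design),
                                                 c("patient_id", "occasion"))]))
  )
  list(design = design, table = table, report = report)
}
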