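#' Generate a synthetic paired pre/post cohort
#'
#' Draws `config$n_patients` patients observed at both occasions from the
#' study conditions encoded in the configuration (see [default_config()]).
#' Within-patient dependence uses a Gaussian copula on latent normals;
#' baseline latents are drawn as a permuted stratified normal sample so that
#' the configured marginals are recovered tightly even at moderate n. The
#' Lildholdt score and olfactory self-rating #2 are drawn from joint
#' pre/post tables (fitted by iterative proportional fitting) via quota
#' sampling, which reproduces both their marginals and their paired
#' change-direction fractions almost exactly; binary prevalences are drawn
#' as fixed counts. A shared latent improvement factor couples the change in
#' self-rated olfaction to the change in primary nasal symptoms.
#'
#' Demographic and concomitant-disease variables are identical across the
#' two occasions, except age, which advances by 1/3 year (the four-month
#' follow-up interval).
#'
#' @param config a `crs_config` from [default_config()].
#' @param seed integer seed; equal seeds give identical cohorts.
#' @return A paired cohort data frame (2 rows per patient, no missing
#'   values) that passes [validate_cohort()] against [default_schema()].
#' @export
generate_cohort <- function(config = default_config(), seed = 1) {
  stopifnot(inherits(config, "crs_config"))
  set.seed(seed)
  n <- config$n_patients

  strat_norm <- function() sample(stats::qnorm((seq_len(n) - stats::runif(n)) / n))
  cut_points <- function(p) stats::qnorm(pmin(pmax(cumsum(p)[-length(p)], 1e-12), 1 - 1e-12))
  to_cat <- function(z, sup, p) sup[findInterval(z, cut_points(p)) + 1]

  f <- stats::rnorm(n)  # shared improvement factor: higher = more improvement
  # within-instrument block factors (severity at baseline / at follow-up)
  block_names <- unique(stats::na.omit(vapply(config$variables, function(v)
    if (is.null(v$block)) NA_character_ else v$block, "")))
  u_pre <- lapply(block_names, function(b) stats::rnorm(n))
  u_post <- lapply(block_names, function(b) stats::rnorm(n))
  names(u_pre) <- names(u_post) <- block_names
  pre <- list(); post <- list()

  zrank <- function(x) stats::qnorm((rank(x, ties.method = "average") - 0.375) /
                                      (n + 0.25))
  # process joint-table variables first so later variables can couple to
  # their realized values (e.g. the two olfactory self-rating scales)
  ord <- order(!vapply(config$variables, function(v)
    identical(v$coupling, "joint"), TRUE))
  for (v in config$variables[ord]) {
    if (v$type == "binary") {
      x <- quota_binary(n, v$prob)
      y <- x
      if (v$coupling == "remit" && sum(x) > 0) {
        keep <- round(n * v$prob_post)
        ones <- which(x == 1)
        y <- numeric(n)
        if (keep > 0) y[sample(ones, min(keep, length(ones)))] <- 1
      }
      pre[[v$name]] <- x; post[[v$name]] <- y
      next
    }
    if (identical(v$coupling, "joint")) {
      cells <- quota_cells(v$joint, n)
      xp <- v$sup_pre[cells[, 1]]; yp <- v$sup_post[cells[, 2]]
      if (v$assign_loading > 0) {
        a <- v$assign_loading
        g <- a * f + sqrt(1 - a^2) * stats::rnorm(n)
        ord_pairs <- order(yp - xp, stats::runif(n))
        ord_pat <- order(g)
        xo <- numeric(n); yo <- numeric(n)
        xo[ord_pat] <- xp[ord_pairs]; yo[ord_pat] <- yp[ord_pairs]
        xp <- xo; yp <- yo
      } else {
        perm <- sample.int(n)
        xp <- xp[perm]; yp <- yp[perm]
      }
      pre[[v$name]] <- xp; post[[v$name]] <- yp
      next
    }
    z1 <- strat_norm()
    if (identical(v$coupling, "copy")) {
      x <- if (v$type == "categorical") to_cat(z1, v$sup_pre, v$p_pre)
           else v$margin_pre$qfun(stats::pnorm(z1))
      y <- if (is.null(v$post_offset)) x else x + v$post_offset
      pre[[v$name]] <- x; post[[v$name]] <- y
      next
    }
    # Gaussian-copula coupling, optionally loaded on the shared improvement
    # factor and/or an instrument block factor; margins are applied through
    # stratified uniforms in the rank order of the latents, so the copula
    # (dependence) and the marginal law are controlled separately
    w <- if (is.null(v$f_loading)) 0 else v$f_loading
    lp <- if (is.null(v$bl_pre)) 0 else v$bl_pre
    lq <- if (is.null(v$bl_post)) 0 else v$bl_post
    if (w^2 + lq^2 > 1) stop("loadings of '", v$name, "' exceed unit variance")
    if (identical(v$block, "self_rating")) {
      u_pre[["self_rating"]] <- zrank(pre[["olf_rating_2"]])
      u_post[["self_rating"]] <- zrank(post[["olf_rating_2"]])
    }
    z1l <- if (lp > 0) lp * u_pre[[v$block]] + sqrt(1 - lp^2) * z1 else z1
    resid <- -w * f + lq * (if (lq > 0) u_post[[v$block]] else 0) +
      sqrt(1 - w^2 - lq^2) * stats::rnorm(n)
    z2l <- v$rho * z1l + sqrt(1 - v$rho^2) * resid
    u1 <- (rank(z1l, ties.method = "first") - stats::runif(n)) / n
    u2 <- (rank(z2l, ties.method = "first") - stats::runif(n)) / n
    if (v$type == "categorical") {
      pre[[v$name]] <- to_cat(stats::qnorm(u1), v$sup_pre, v$p_pre)
      post[[v$name]] <- to_cat(stats::qnorm(u2), v$sup_post, v$p_post)
    } else {
      pre[[v$name]] <- v$margin_pre$qfun(u1)
      post[[v$name]] <- v$margin_post$qfun(u2)
    }
  }

  pre <- pre[names(config$variables)]
  post <- post[names(config$variables)]
  ids <- sprintf("P%03d", seq_len(n))
  out <- rbind(
    data.frame(patient_id = ids, occasion = "baseline", as.data.frame(pre),
               stringsAsFactors = FALSE),
    data.frame(patient_id = ids, occasion = "post", as.data.frame(post),
               stringsAsFactors = FALSE)
  )
  rownames(out) <- NULL
  out
}

#' Inject missingness and outliers into a cohort table
#'
#' Missingness is applied completely at random to the non-demographic cells
#' (anatomy, olfactory and quality-of-life variables at both occasions).
#' Outliers replace values of interval-scaled variables by the column mean
#' plus or minus six column SDs. The number of altered cells equals
#' `round(rate * eligible cells)` for each mechanism.
#'
#' @param table a cohort data frame.
#' @param missing_rate,outlier_rate rates in \[0, 1\].
#' @param seed integer seed.
#' @param schema the variable schema (default [default_schema()]).
#' @return The modified cohort table. Injected outliers may exceed the
#'   schema support on purpose; they are meant to be caught by outlier
#'   removal during preprocessing.
#' @export
inject_artifacts <- function(table, missing_rate = 0, outlier_rate = 0,
                             seed = 1, schema = default_schema()) {
  stopifnot(missing_rate >= 0, missing_rate <= 1,
            outlier_rate >= 0, outlier_rate <= 1)
  set.seed(seed)
  out <- table

  if (outlier_rate > 0) {
    vars <- schema$name[schema$scale == "interval"]
    cells <- expand.grid(row = seq_len(nrow(out)), var = vars,
                         stringsAsFactors = FALSE)
    k <- round(outlier_rate * nrow(cells))
    if (k > 0) {
      pick <- cells[sample.int(nrow(cells), k), , drop = FALSE]
      for (i in seq_len(nrow(pick))) {
        v <- pick$var[i]
        mu <- mean(out[[v]], na.rm = TRUE); s <- stats::sd(out[[v]], na.rm = TRUE)
        out[pick$row[i], v] <- mu + sample(c(-6, 6), 1) * s
      }
    }
  }

  if (missing_rate > 0) {
    vars <- schema$name[schema$category != "demographic"]
    cells <- expand.grid(row = seq_len(nrow(out)), var = vars,
                         stringsAsFactors = FALSE)
    k <- round(missing_rate * nrow(cells))
    if (k > 0) {
      pick <- cells[sample.int(nrow(cells), k), , drop = FALSE]
      for (i in seq_len(nrow(pick))) out[pick$row[i], pick$var[i]] <- NA_real_
    }
  }
  out
}
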