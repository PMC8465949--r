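# Internal calibration machinery for the synthetic cohort generator.
# All of these are deterministic given their inputs; randomness enters only
# in generate_cohort().

#' Moment-matched probability vector on a discrete support
#'
#' Finds the minimum-norm probability vector on `support` with the requested
#' mean and standard deviation (constrained least squares: minimize
#' `sum(p^2)` subject to the two moment constraints, the simplex constraint
#' and non-negativity, the latter enforced by active-set clipping).
#'
#' @param support numeric vector of support points.
#' @param mean,sd target moments.
#' @return probability vector of `length(support)`.
#' @export
match_probs <- function(support, mean, sd) {
  k <- as.numeric(support)
  m2 <- sd^2 + mean^2
  act <- rep(TRUE, length(k))
  for (it in seq_len(length(k))) {
    A <- rbind(1, k[act], k[act]^2)
    b <- c(1, mean, m2)
    lam <- tryCatch(solve(A %*% t(A), b), error = function(e) NULL)
    if (is.null(lam)) break
    p_act <- as.vector(t(A) %*% lam)
    if (all(p_act >= -1e-10)) {
      p <- numeric(length(k))
      p[act] <- pmax(p_act, 0)
      p <- p / sum(p)
      return(p)
    }
    act[act][which.min(p_act)] <- FALSE
    if (sum(act) < 3) break
  }
  stop("no probability vector on the given support attains mean ", mean,
       " and sd ", sd)
}

# Truncated-normal moments for underlying N(mu, sig) on [a, b]
tnorm_moments <- function(mu, sig, a, b) {
  al <- (a - mu) / sig; be <- (b - mu) / sig
  Z <- stats::pnorm(be) - stats::pnorm(al)
  if (Z < 1e-12) return(c(NA_real_, NA_real_))
  da <- stats::dnorm(al); db <- stats::dnorm(be)
  m <- mu + sig * (da - db) / Z
  v <- sig^2 * (1 + (al * da - be * db) / Z - ((da - db) / Z)^2)
  c(m, sqrt(max(v, 0)))
}

#' Continuous marginal matched to printed mean/SD on a bounded range
#'
#' Solves for a truncated-normal marginal on `[lo, hi]` whose truncated mean
#' and SD equal the targets. Where the target pair lies outside the
#' truncated-normal family (strongly skewed or near-bimodal scales), a
#' moment-matched scaled Beta distribution is used instead.
#'
#' @param mean,sd target moments; `lo`, `hi` the support bounds.
#' @return list with `dist` ("tnorm" or "beta"), parameters, and `qfun`,
#'   a quantile function mapping (0,1) to the support.
#' @export
continuous_margin <- function(mean, sd, lo, hi) {
  stopifnot(lo < hi, mean > lo, mean < hi, sd > 0)
  obj <- function(par) {
    ms <- tnorm_moments(par[1], exp(par[2]), lo, hi)
    if (anyNA(ms)) return(1e6)
    ((ms[1] - mean) / sd)^2 + ((ms[2] - sd) / sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(maxit = 3000, reltol = 1e-14))
  if (fit$value < 1e-8) {
    mu <- fit$par[1]; sig <- exp(fit$par[2])
    al <- (lo - mu) / sig; be <- (hi - mu) / sig
    pa <- stats::pnorm(al); pb <- stats::pnorm(be)
    return(list(dist = "tnorm", mu = mu, sig = sig, lo = lo, hi = hi,
                qfun = function(u) stats::qnorm(pa + u * (pb - pa)) * sig + mu))
  }
  # scaled Beta fallback
  m <- (mean - lo) / (hi - lo)
  v <- (sd / (hi - lo))^2
  if (v >= m * (1 - m)) stop("mean/sd pair infeasible on [", lo, ", ", hi, "]")
  al <- m * (m * (1 - m) / v - 1)
  be <- (1 - m) * (m * (1 - m) / v - 1)
  list(dist = "beta", shape1 = al, shape2 = be, lo = lo, hi = hi,
       qfun = function(u) stats::qbeta(u, al, be) * (hi - lo) + lo)
}

# Discretized Gaussian-copula base joint for two categorical margins
copula_joint <- function(p, q, rho, grid = 400) {
  # numerical integration over the latent bivariate normal
  z <- stats::qnorm((seq_len(grid) - 0.5) / grid)
  cp <- c(0, cumsum(p)); cq <- c(0, cumsum(q))
  M <- matrix(0, length(p), length(q))
  for (g in seq_len(grid)) {
    # conditional law of z2 | z1 = z[g]
    cond <- stats::pnorm((stats::qnorm(pmin(pmax(cq, 1e-12), 1 - 1e-12)) -
                            rho * z[g]) / sqrt(1 - rho^2))
    cond[1] <- 0; cond[length(cond)] <- 1
    pr2 <- diff(cond)
    i <- findInterval(stats::pnorm(z[g]), cp, rightmost.closed = TRUE,
                      all.inside = TRUE)
    M[i, ] <- M[i, ] + pr2 / grid
  }
  # repair row margins distorted by binning
  M <- M * (p / pmax(rowSums(M), 1e-12))
  M
}

#' Joint pre/post law with fixed margins and change-direction masses
#'
#' Builds a joint probability table over (baseline value, post value) whose
#' row margin is `p` (baseline), column margin is `q` (post) and whose mass
#' below/on/above the diagonal (post < pre, post == pre, post > pre,
#' compared on the value scales) equals `frac_down`, `frac_eq`, `frac_up`.
#' Fitted by iterative proportional fitting started from a Gaussian-copula
#' base with correlation `base_rho`; regions with target mass 0 are zeroed.
#'
#' @param sup_pre,sup_post numeric supports of the two margins.
#' @param p,q margin probability vectors.
#' @param frac_down,frac_eq,frac_up target region masses (sum to 1).
#' @param base_rho copula correlation of the starting table.
#' @param iters IPF sweeps.
#' @return matrix `length(p) x length(q)` summing to 1.
#' @export
couple_margins <- function(sup_pre, sup_post, p, q, frac_down, frac_eq, frac_up,
                           base_rho = 0.5, iters = 400) {
  stopifnot(abs(frac_down + frac_eq + frac_up - 1) < 1e-8)
  M <- copula_joint(p, q, base_rho)
  D <- outer(sup_post, sup_pre, function(post, pre) sign(post - pre))
  D <- t(D)  # rows = pre, cols = post
  reg <- list(down = D < 0, eq = D == 0, up = D > 0)
  tgt <- c(down = frac_down, eq = frac_eq, up = frac_up)
  for (r in names(reg)) if (tgt[[r]] == 0) M[reg[[r]]] <- 0
  for (it in seq_len(iters)) {
    for (r in names(reg)) {
      s <- sum(M[reg[[r]]])
      if (s > 0 && tgt[[r]] > 0) M[reg[[r]]] <- M[reg[[r]]] * tgt[[r]] / s
    }
    M <- M * (p / pmax(rowSums(M), 1e-15))
    M <- t(t(M) * (q / pmax(colSums(M), 1e-15)))
  }
  err <- max(abs(rowSums(M) - p), abs(colSums(M) - q),
             abs(vapply(names(reg), function(r) sum(M[reg[[r]]]), 0) - tgt))
  if (err > 0.02)
    stop("change fractions are inconsistent with the requested margins (IPF residual ",
         signif(err, 3), ")")
  M / sum(M)
}

# Quota draw of n cells from a joint table: floor(n * M) plus a randomized
# largest-remainder top-up, so realized cell counts differ from n * M by < 1.
quota_cells <- function(M, n) {
  ex <- as.vector(M) * n
  base <- floor(ex)
  rem <- ex - base
  k <- n - sum(base)
  if (k > 0) {
    extra <- sample(seq_along(ex), k, prob = pmax(rem, 1e-12))
    base[extra] <- base[extra] + 1
  }
  idx <- rep(seq_along(ex), base)
  cbind(row = (idx - 1) %% nrow(M) + 1, col = (idx - 1) %/% nrow(M) + 1)
}

# Quota draw of a binary vector with exactly round(n * prob) ones
quota_binary <- function(n, prob) {
  x <- numeric(n)
  k <- round(n * prob)
  if (k > 0) x[sample.int(n, k)] <- 1
  x
}
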