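# Maximum-likelihood white-noise (WN) and Brownian-motion (BM) model fits for
# family-level values, and the Monte Carlo power / model-comparison analysis.

new_evo_fit <- function(model, mu, sigma2, lnL, n) {
  structure(list(model = model, mu = mu, sigma2 = sigma2, lnL = lnL,
                 n = n, n_params = 2L), class = "evo_fit")
}

#' @export
print.evo_fit <- function(x, ...) {
  cat(sprintf("%s fit: mu = %.4g, sigma2 = %.4g, lnL = %.4f (n = %d)\n",
              x$model, x$mu, x$sigma2, x$lnL, x$n))
  invisible(x)
}

# Gaussian log-likelihood of values under covariance V (already including
# any measurement-error variances) with mean mu*1.
mvn_loglik <- function(values, mu, V) {
  n <- length(values)
  cs <- chol_solver(V)
  r <- values - mu
  -0.5 * (n * log(2 * pi) + cs$logdet + sum(r * cs$solve(r)))
}

# Profile ML over sigma2 for covariance sigma2 * B + diag(se^2), mean
# profiled as the GLS mean. Returns list(mu, sigma2, lnL).
profile_sigma2_ml <- function(values, B, se) {
  D <- diag(se^2, length(values))
  obj <- function(ls2) {
    s2 <- exp(ls2)
    V <- s2 * B + D
    cs <- chol_solver(V)
    one <- rep(1, length(values))
    iV1 <- cs$solve(one)
    mu <- sum(iV1 * values) / sum(iV1 * one)
    r <- values - mu
    -(-0.5 * (length(values) * log(2 * pi) + cs$logdet + sum(r * cs$solve(r))))
  }
  v0 <- stats::var(values)
  opt <- stats::optimize(obj, interval = log(c(v0 * 1e-6 + 1e-12, v0 * 1e3 + 1e-6)))
  s2 <- exp(opt$minimum)
  V <- s2 * B + D
  cs <- chol_solver(V)
  one <- rep(1, length(values))
  iV1 <- cs$solve(one)
  mu <- sum(iV1 * values) / sum(iV1 * one)
  list(mu = mu, sigma2 = s2, lnL = -opt$objective)
}

#' Maximum-likelihood white-noise fit
#'
#' The null model: values are independent draws from Normal(mu, sigma2),
#' unrelated to the phylogeny. With per-tip standard errors supplied, the
#' known error variances add to sigma2 and the fit is by 1-D profile ML.
#'
#' @param values named numeric vector of family-level values.
#' @param se optional per-family standard errors (measurement error).
#' @return an `evo_fit` with `model = "WN"`, `mu`, `sigma2`, `lnL`.
#' @export
fit_wn <- function(values, se = NULL) {
  n <- length(values)
  if (n < 3) stop("need >= 3 values")
  if (stats::var(values) == 0) stop("zero-variance data: WN fit degenerate")
  if (is.null(se)) {
    mu <- mean(values)
    s2 <- sum((values - mu)^2) / n
    lnL <- -0.5 * n * (log(2 * pi * s2) + 1)
    return(new_evo_fit("WN", mu, s2, lnL, n))
  }
  stopifnot(length(se) == n, all(se >= 0))
  pf <- profile_sigma2_ml(values, diag(n), se)
  new_evo_fit("WN", pf$mu, pf$sigma2, pf$lnL, n)
}

#' Maximum-likelihood Brownian-motion fit
#'
#' Values are multivariate normal with mean mu (the root state) and
#' covariance sigma2 * C, where C is the shared branch-length matrix of the
#' tree. Without measurement error the estimates are closed-form GLS; with
#' per-tip SEs the covariance becomes sigma2 * C + diag(se^2) and sigma2 is
#' profiled numerically.
#'
#' @param values named numeric vector; names must match tree tips.
#' @param tree a `phylo` object.
#' @param se optional per-family standard errors, named like `values`.
#' @return an `evo_fit` with `model = "BM"`.
#' @export
fit_bm <- function(values, tree, se = NULL) {
  values <- align_to_tips(values, tree)
  n <- length(values)
  if (n < 3) stop("need >= 3 tips")
  C <- bm_covariance(tree)[names(values), names(values)]
  if (any(diag(C) <= 0) || det(C) <= 0)
    stop("singular BM covariance (duplicate zero-length tips?)")
  if (is.null(se)) {
    cs <- chol_solver(C)
    one <- rep(1, n)
    iC1 <- cs$solve(one)
    mu <- sum(iC1 * values) / sum(iC1 * one)
    r <- values - mu
    s2 <- sum(r * cs$solve(r)) / n
    if (s2 <= 0) stop("zero-variance data: BM fit degenerate")
    lnL <- -0.5 * (n * log(2 * pi * s2) + cs$logdet + n)
    return(new_evo_fit("BM", mu, s2, lnL, n))
  }
  se <- align_to_tips(se, tree, "se")
  pf <- profile_sigma2_ml(values, C, se)
  new_evo_fit("BM", pf$mu, pf$sigma2, pf$lnL, n)
}

# Simulate n_sim datasets (columns) from a fitted WN or BM model, adding
# measurement error when SEs are carried.
simulate_from_fit <- function(fit, tree, se, n_sim) {
  n <- fit$n
  if (fit$model == "WN") {
    sd_tot <- sqrt(fit$sigma2 + if (is.null(se)) 0 else se^2)
    y <- matrix(stats::rnorm(n * n_sim, fit$mu, sd_tot), n, n_sim)
  } else {
    C <- bm_covariance(tree)[tree$tip.label, tree$tip.label]
    V <- fit$sigma2 * C
    if (!is.null(se)) V <- V + diag(se^2, n)
    L <- t(chol(V))
    y <- fit$mu + L %*% matrix(stats::rnorm(n * n_sim), n, n_sim)
  }
  rownames(y) <- tree$tip.label
  y
}

#' Monte Carlo power analysis of the WN vs BM model comparison
#'
#' Fits both models to the data, simulates `n_sim` datasets from each fitted
#' model, refits BOTH models to every simulated dataset, and collects the
#' likelihood-ratio statistic delta = 2 (lnL_BM - lnL_WN) under each
#' generating model. The overlap of the two delta distributions shows how
#' much power the tip sample gives; the observed delta is compared against
#' the (1 - alpha) quantile of the WN-generated null.
#'
#' @param values named numeric vector of family-level values.
#' @param tree a `phylo` object.
#' @param se optional per-family SEs; simulated datasets reuse them.
#' @param n_sim simulated datasets per model (default 1000).
#' @param seed RNG seed.
#' @param alpha quantile level for the model call (default 0.05).
#' @return object of class `pmc_result`: `delta_obs`, `delta_null`,
#'   `delta_alt`, `power`, `preferred_model`, `n_failed`, the two fits.
#' @export
pmc_power <- function(values, tree, se = NULL, n_sim = 1000, seed = NULL,
                      alpha = 0.05) {
  if (!is.null(se)) se <- align_to_tips(se, tree, "se")
  wn <- fit_wn(align_to_tips(values, tree), se = se)
  bm <- fit_bm(values, tree, se = se)
  delta_obs <- 2 * (bm$lnL - wn$lnL)
  refit_delta <- function(y) {
    tryCatch({
      names(y) <- tree$tip.label
      2 * (fit_bm(y, tree, se = se)$lnL - fit_wn(y, se = se)$lnL)
    }, error = function(e) NA_real_)
  }
  sims <- with_seed(seed, list(
    null = simulate_from_fit(wn, tree, se, n_sim),
    alt = simulate_from_fit(bm, tree, se, n_sim)
  ))
  delta_null <- apply(sims$null, 2, refit_delta)
  delta_alt <- apply(sims$alt, 2, refit_delta)
  n_failed <- sum(is.na(delta_null)) + sum(is.na(delta_alt))
  delta_null <- delta_null[!is.na(delta_null)]
  delta_alt <- delta_alt[!is.na(delta_alt)]
  crit <- stats::quantile(delta_null, 1 - alpha, names = FALSE)
  structure(list(
    delta_obs = delta_obs, delta_null = delta_null, delta_alt = delta_alt,
    n_sim = n_sim, n_failed = n_failed,
    power = mean(delta_alt > crit),
    preferred_model = if (delta_obs > crit) "BM" else "WN",
    fits = list(WN = wn, BM = bm), alpha = alpha
  ), class = "pmc_result")
}

#' @export
print.pmc_result <- function(x, ...) {
  cat(sprintf(paste0("pmc: delta_obs = %.3f, power = %.3f ",
                     "(n_sim = %d, failed = %d), preferred model: %s\n"),
              x$delta_obs, x$power, x$n_sim, x$n_failed, x$preferred_model))
  invisible(x)
}
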