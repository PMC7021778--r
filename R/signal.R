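# Phylogenetic-signal statistics on family-level variables: Blomberg's K
# (with measurement error), Fritz-Purvis D for binary traits, effect-size
# matrices and regressions of dissimilarity on patristic distance.

# K variance ratio for one or more trait columns under covariance V.
# Y: n x m matrix of tip values (rows ordered like V). Returns K per column.
k_statistic_core <- function(Y, V) {
  n <- nrow(Y)
  cs <- chol_solver(V)
  one <- rep(1, n)
  iV1 <- cs$solve(one)
  denom <- sum(iV1 * one)
  expected <- (sum(diag(V)) - n / denom) / (n - 1)
  mu <- as.numeric(crossprod(iV1, Y)) / denom
  Dv <- Y - tcrossprod(one, mu)  # n x m centered at phylogenetic mean
  mse0 <- colSums(Dv^2) / (n - 1)
  mse <- colSums(Dv * cs$solve(Dv)) / (n - 1)
  (mse0 / mse) / expected
}

#' Blomberg's K phylogenetic signal statistic
#'
#' Variance-ratio statistic comparing tip dispersion around the phylogenetic
#' (GLS) mean with the contrast-based dispersion expected under the tree's
#' Brownian covariance; K = 1 matches Brownian motion, K = 0 phylogenetic
#' independence. When standard errors are supplied, the Brownian rate sigma2
#' is first estimated by ML under BM plus known error variances and K is
#' computed on the error-adjusted covariance C + diag(se^2) / sigma2, so
#' weakly estimated responses are down-weighted. The permutation test
#' shuffles values (and SEs, jointly) across tips and counts variance ratios
#' at least as large as observed.
#'
#' @param values named numeric vector of family-level values.
#' @param tree a `phylo` object; tip labels must match `values` names.
#' @param se optional per-family standard errors.
#' @param n_perm permutations for the signal test (default 1000); 0 skips the
#'   test.
#' @param seed RNG seed.
#' @return object of class `k_result`: `K`, `p`, `n_perm`, `used_se`,
#'   `sigma2` (error model rate, when SEs used).
#' @export
blomberg_k <- function(values, tree, se = NULL, n_perm = 1000, seed = NULL) {
  values <- align_to_tips(values, tree)
  n <- length(values)
  if (n < 4) stop("need >= 4 tips")
  if (stats::var(values) == 0) stop("constant values: K undefined")
  if (n_perm > 0 && n_perm < 99) warning("n_perm < 99: permutation p crude")
  C <- bm_covariance(tree)[names(values), names(values)]
  if (!is.null(se)) {
    se <- align_to_tips(se, tree, "se")
    k_of <- function(y, s) {
      s2 <- profile_sigma2_ml(y, C, s)$sigma2
      k_statistic_core(cbind(y), C + diag(s^2 / s2, n))
    }
    K <- k_of(values, se)
    p <- NA_real_
    if (n_perm > 0) {
      perms <- with_seed(seed, replicate(n_perm, sample.int(n),
                                         simplify = FALSE))
      kp <- vapply(perms, function(i) k_of(values[i], se[i]), numeric(1))
      p <- (1 + sum(kp >= K - 1e-12)) / (n_perm + 1)
    }
    return(structure(list(K = unname(K), p = p, n_perm = n_perm,
                          used_se = TRUE,
                          sigma2 = profile_sigma2_ml(values, C, se)$sigma2),
                     class = "k_result"))
  }
  K <- k_statistic_core(cbind(values), C)
  p <- NA_real_
  if (n_perm > 0) {
    Yp <- with_seed(seed, replicate(n_perm, values[sample.int(n)]))
    kp <- k_statistic_core(Yp, C)
    p <- (1 + sum(kp >= K - 1e-12)) / (n_perm + 1)
  }
  structure(list(K = unname(K), p = p, n_perm = n_perm, used_se = FALSE,
                 sigma2 = NA_real_), class = "k_result")
}

#' @export
print.k_result <- function(x, ...) {
  cat(sprintf("Blomberg K = %.4f, p = %s (%d permutations%s)\n",
              x$K, format(x$p, digits = 3), x$n_perm,
              if (x$used_se) ", SE-weighted" else ""))
  invisible(x)
}

# Sum over internal nodes of |differences between child-clade averages|,
# with nodal values obtained by downpass averaging of the children. For
# multifurcations the sum runs over all unordered child pairs.
sister_difference_sum <- function(tree, x) {
  n <- length(tree$tip.label)
  nn <- max(tree$edge)
  val <- c(as.numeric(x), rep(NA_real_, nn - n))
  tr <- stats::reorder(tree, "postorder")
  d <- 0
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  for (node in unique(tr$edge[, 1])) {  # postorder: children before parents
    ch <- kids[[as.character(node)]]
    v <- val[ch]
    val[node] <- mean(v)
    if (length(v) > 1) {
      pr <- utils::combn(v, 2)
      d <- d + sum(abs(pr[1, ] - pr[2, ]))
    }
  }
  d
}

#' Fritz-Purvis D statistic for a binary trait
#'
#' Measures phylogenetic signal in a binary trait by the sum of sister-clade
#' differences of nodal averages, rescaled between the expectation under a
#' random tip shuffle (D = 1) and the expectation under a thresholded
#' Brownian process at the observed prevalence (D = 0). D < 0 indicates
#' stronger clumping than Brownian motion; D > 1 overdispersion.
#'
#' @param values named 0/1 vector over tree tips (e.g. widespread vs rare
#'   families).
#' @param tree a `phylo` object.
#' @param n_perm shuffles and BM simulations for the two reference
#'   distributions (default 1000).
#' @param seed RNG seed.
#' @return object of class `d_result`: `D`, `p_random` (fraction of shuffles
#'   with d <= observed), `p_brownian` (fraction of BM simulations with
#'   d >= observed), `d_obs`, `n_perm`.
#' @export
d_statistic <- function(values, tree, n_perm = 1000, seed = NULL) {
  values <- align_to_tips(values, tree)
  if (!all(values %in% c(0, 1))) stop("values must be binary 0/1")
  m <- sum(values)
  n <- length(values)
  if (m == 0 || m == n) stop("D undefined: trait prevalence is 0 or 1")
  d_obs <- sister_difference_sum(tree, values)
  C <- bm_covariance(tree)[tree$tip.label, tree$tip.label]
  L <- t(chol(C))
  res <- with_seed(seed, {
    d_r <- vapply(seq_len(n_perm), function(i)
      sister_difference_sum(tree, values[sample.int(n)]), numeric(1))
    Z <- L %*% matrix(stats::rnorm(n * n_perm), n, n_perm)
    d_b <- vapply(seq_len(n_perm), function(j) {
      y <- Z[, j]
      b <- as.numeric(rank(y, ties.method = "first") > n - m)  # top-m = 1
      sister_difference_sum(tree, b)
    }, numeric(1))
    list(d_r = d_r, d_b = d_b)
  })
  D <- (d_obs - mean(res$d_b)) / (mean(res$d_r) - mean(res$d_b))
  structure(list(D = D, d_obs = d_obs,
                 p_random = mean(res$d_r <= d_obs),
                 p_brownian = mean(res$d_b >= d_obs),
                 n_perm = n_perm), class = "d_result")
}

#' @export
print.d_result <- function(x, ...) {
  cat(sprintf("Fritz-Purvis D = %.3f (p_random = %.3f, p_brownian = %.3f)\n",
              x$D, x$p_random, x$p_brownian))
  invisible(x)
}

#' Pairwise effect-size matrix between families
#'
#' Cohen's d — |x_i - x_j| / sqrt((se_i^2 + se_j^2) / 2) — for variables that
#' carry a standard error, or plain absolute raw differences for those that
#' do not (edf, R²).
#'
#' @param values named numeric vector of family-level values.
#' @param se per-family standard errors (required for `"cohens_d"`).
#' @param kind `"cohens_d"` or `"raw_difference"`.
#' @return symmetric zero-diagonal dissimilarity matrix over families.
#' @export
effect_size_matrix <- function(values, se = NULL,
                               kind = c("cohens_d", "raw_difference")) {
  kind <- match.arg(kind)
  n <- length(values)
  nm <- names(values)
  diffs <- abs(outer(values, values, "-"))
  if (kind == "raw_difference") {
    dimnames(diffs) <- list(nm, nm)
    return(diffs)
  }
  if (is.null(se)) stop("cohens_d requires standard errors")
  stopifnot(length(se) == n, all(se >= 0))
  pooled <- sqrt((outer(se^2, se^2, "+")) / 2)
  if (any(pooled[upper.tri(pooled)] == 0))
    stop("cohens_d undefined: a pair has both SEs zero")
  out <- diffs / pooled
  diag(out) <- 0
  dimnames(out) <- list(nm, nm)
  out
}

#' Regression of pairwise dissimilarities on patristic distance
#'
#' OLS of the lower-triangle dissimilarities (effect sizes or raw
#' differences between families) on patristic divergence times, with a
#' permutation null built by jointly permuting the family labels of the
#' dissimilarity matrix. Increasing dissimilarity with divergence time is
#' the distance-based face of phylogenetic signal.
#'
#' @param dissimilarity symmetric family dissimilarity matrix.
#' @param patristic symmetric patristic distance matrix (same families).
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @param exact enumerate all family permutations (families <= ~7).
#' @return object of class `distreg_result`: `slope`, `intercept`, `se`,
#'   `r2`, `p` (permutation, on |t| of the slope), `n_perm`.
#' @export
signal_distance_regression <- function(dissimilarity, patristic,
                                       n_perm = 999, seed = NULL,
                                       exact = FALSE) {
  dissimilarity <- as.matrix(dissimilarity)
  patristic <- as.matrix(patristic)
  if (!is.null(rownames(dissimilarity)) && !is.null(rownames(patristic)))
    patristic <- patristic[rownames(dissimilarity), rownames(dissimilarity)]
  if (stats::sd(lower_vec(patristic)) == 0)
    stop("constant patristic distances")
  fit <- mrm(dissimilarity, list(patristic = patristic), n_perm = n_perm,
             seed = seed, exact = exact)
  co <- fit$coefficients
  structure(list(slope = co$slope[1], intercept = fit$intercept,
                 se = co$se[1], r2 = fit$r2, p = co$p[1],
                 p_r2 = fit$p_r2, n_perm = fit$n_perm),
            class = "distreg_result")
}

#' @export
print.distreg_result <- function(x, ...) {
  cat(sprintf("distance regression: slope = %.4g, R2 = %.3f, p = %.4g\n",
              x$slope, x$r2, x$p))
  invisible(x)
}
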