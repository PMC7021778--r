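# Beta-diversity distance matrices and multiple regression on distance
# matrices (MRM) with permutation inference.

#' Sørensen dissimilarity matrix for one family
#'
#' Pairwise Sørensen index (b + c) / (2a + b + c) between sites, computed on
#' the family's member species at its presence-only sites.
#'
#' @param occ an `occurrence_matrix`.
#' @param family family name; when NULL `occ$incidence` is used whole.
#' @return symmetric site x site matrix with entries in \[0, 1\].
#' @export
sorensen_matrix <- function(occ, family = NULL) {
  m <- if (is.null(family)) occ$incidence
       else occ$incidence[, occ$taxonomy == family, drop = FALSE]
  m <- m[rowSums(m) > 0, , drop = FALSE]
  if (nrow(m) < 2) stop("need >= 2 presence sites")
  # binary Bray-Curtis is the Sørensen index
  as.matrix(vegan::vegdist(m, method = "bray", binary = TRUE))
}

#' Geographic, elevational and habitat distance matrices among sites
#'
#' Geographic distance is Euclidean on (x, y); elevational distance is
#' |delta elevation|; habitat dissimilarity is Euclidean distance on
#' arcsine-square-root transformed habitat cover proportions.
#'
#' @param meta a `site_metadata` table.
#' @param sites optional site subset (character ids), in the desired order.
#' @return named list of symmetric matrices: `geographic`, `elevational`,
#'   `habitat` (NULL when no habitat columns exist).
#' @export
site_distance_matrices <- function(meta, sites = NULL) {
  if (!is.null(sites)) {
    idx <- match(sites, meta$site)
    if (anyNA(idx)) stop("missing site metadata for: ",
                         paste(sites[is.na(idx)], collapse = ", "))
    meta <- meta[idx, , drop = FALSE]
  }
  lab <- meta$site
  geo <- as.matrix(stats::dist(cbind(meta$x, meta$y)))
  elev <- as.matrix(stats::dist(meta$elevation))
  dimnames(geo) <- dimnames(elev) <- list(lab, lab)
  hab_cols <- grep("^habitat_", names(meta), value = TRUE)
  hab <- NULL
  if (length(hab_cols)) {
    p <- as.matrix(meta[, hab_cols, drop = FALSE])
    if (any(p < 0 | p > 1)) stop("habitat proportions must lie in [0,1]")
    hab <- as.matrix(stats::dist(asin(sqrt(p))))
    dimnames(hab) <- list(lab, lab)
  }
  list(geographic = geo, elevational = elev, habitat = hab)
}

# Core OLS on vectorized lower triangles; returns coefficients, SEs, t, R2.
mrm_ols <- function(yv, X) {
  fit <- stats::lm.fit(X, yv)
  if (fit$rank < ncol(X))
    stop("collinear predictor distance matrices: ",
         paste(colnames(X)[is.na(fit$coefficients)], collapse = ", "))
  r <- fit$residuals
  n <- length(yv)
  p <- fit$rank
  rss <- sum(r^2)
  tss <- sum((yv - mean(yv))^2)
  sigma2 <- rss / (n - p)
  XtXi <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  se <- sqrt(diag(XtXi) * sigma2)
  b <- fit$coefficients[seq_len(p)]
  tt <- ifelse(se > 0, b / se, ifelse(abs(b) < 1e-12, 0, sign(b) * Inf))
  list(coef = b, se = se, t = tt, r2 = if (tss > 0) 1 - rss / tss else 0)
}

#' Multiple regression on distance matrices
#'
#' OLS of the vectorized lower triangle of a response distance matrix on one
#' or more predictor distance matrices. Significance comes from a permutation
#' null: rows and columns of the RESPONSE matrix are permuted jointly, the
#' model refitted, and observed |t| (per slope) and R² (overall) compared
#' against the permuted values; p = (1 + #{perm >= obs}) / (n_perm + 1).
#' With `exact = TRUE` all n! site permutations are enumerated instead
#' (feasible for <= ~7 sites) and p is the exact fraction, identity included.
#'
#' @param response symmetric response distance matrix.
#' @param predictors named list of symmetric predictor matrices.
#' @param n_perm number of random permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @param exact enumerate all permutations instead of sampling.
#' @return object of class `mrm_result`: data.frame `coefficients` (term,
#'   slope, se, t, p), plus `r2`, `p_r2`, `n_perm`, `n_sites`, `dropped`
#'   (constant predictors flagged and excluded).
#' @export
mrm <- function(response, predictors, n_perm = 999, seed = NULL,
                exact = FALSE) {
  response <- as.matrix(response)
  n <- nrow(response)
  if (n < 4) stop("need >= 4 sites for MRM")
  if (is.null(names(predictors)) || any(!nzchar(names(predictors))))
    names(predictors) <- paste0("X", seq_along(predictors))
  pv <- lapply(predictors, function(m) lower_vec(as.matrix(m)))
  bad <- vapply(pv, function(v) stats::sd(v) == 0, logical(1))
  dropped <- names(pv)[bad]
  if (all(bad)) stop("all predictors constant")
  if (any(bad))
    warning("constant predictor(s) flagged and dropped: ",
            paste(dropped, collapse = ", "))
  pv <- pv[!bad]
  yv <- lower_vec(response)
  X <- cbind(`(Intercept)` = 1, do.call(cbind, pv))
  obs <- mrm_ols(yv, X)
  k <- length(pv)
  slope_idx <- 1 + seq_len(k)

  perms <- if (exact) all_permutations(n)
           else with_seed(seed, replicate(n_perm, sample.int(n),
                                          simplify = FALSE))
  ge_t <- numeric(k)
  ge_r2 <- 0
  for (pm in perms) {
    yp <- lower_vec(response[pm, pm])
    st <- mrm_ols(yp, X)
    ge_t <- ge_t + (abs(st$t[slope_idx]) >= abs(obs$t[slope_idx]) - 1e-12)
    ge_r2 <- ge_r2 + (st$r2 >= obs$r2 - 1e-12)
  }
  if (exact) {
    m <- length(perms)  # identity included in the enumeration
    p_slope <- ge_t / m
    p_r2 <- ge_r2 / m
  } else {
    p_slope <- (1 + ge_t) / (n_perm + 1)
    p_r2 <- (1 + ge_r2) / (n_perm + 1)
  }
  coef_tab <- data.frame(
    term = names(pv), slope = unname(obs$coef[slope_idx]),
    se = unname(obs$se[slope_idx]), t = unname(obs$t[slope_idx]),
    p = p_slope, stringsAsFactors = FALSE)
  structure(list(coefficients = coef_tab, intercept = unname(obs$coef[1]),
                 r2 = obs$r2, p_r2 = p_r2,
                 n_perm = if (exact) length(perms) else n_perm,
                 n_sites = n, exact = exact, dropped = dropped),
            class = "mrm_result")
}

#' @export
print.mrm_result <- function(x, ...) {
  cat(sprintf("MRM on %d sites (%s permutations): R2 = %.3f, p = %.4g\n",
              x$n_sites, if (x$exact) "exact" else x$n_perm, x$r2, x$p_r2))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Six turnover responses for one family
#'
#' Regresses the family's Sørensen dissimilarities on geographic, elevational
#' and habitat distances. Slopes (with SEs) come from ONE joint MRM with all
#' three predictors; the three R² values come from three SEPARATE
#' single-predictor MRMs, reported as 0 when the single-predictor fit is not
#' significant (permutation p >= `alpha`).
#'
#' @param occ an `occurrence_matrix`.
#' @param meta a `site_metadata` table.
#' @param family family name.
#' @param n_perm permutations per MRM (default 999).
#' @param seed master seed; child seeds are derived per MRM.
#' @param alpha significance threshold for zeroing non-significant R².
#' @return one-row data.frame with slopes, SEs, R²s and p-values for the
#'   three gradients, plus `n_sites`.
#' @export
turnover_responses <- function(occ, meta, family, n_perm = 999, seed = NULL,
                               alpha = 0.05) {
  m <- occ$incidence[, occ$taxonomy == family, drop = FALSE]
  keep <- rowSums(m) > 0
  sites <- occ$sites[keep]
  if (length(sites) < 4) stop("family present at < 4 sites: ", family)
  sor <- sorensen_matrix(occ, family)
  dd <- site_distance_matrices(meta, sites)
  preds <- list(xy = dd$geographic, z = dd$elevational, hab = dd$habitat)
  preds <- preds[!vapply(preds, is.null, logical(1))]
  seeds <- derive_seeds(if (is.null(seed)) 1L else seed, 1 + length(preds))
  joint <- mrm(sor, preds, n_perm = n_perm, seed = seeds[1])
  out <- list(family = family, n_sites = length(sites))
  for (i in seq_along(preds)) {
    nm <- names(preds)[i]
    row <- joint$coefficients[joint$coefficients$term == nm, ]
    out[[paste0("slope_", nm)]] <- if (nrow(row)) row$slope else NA_real_
    out[[paste0("se_", nm)]] <- if (nrow(row)) row$se else NA_real_
    out[[paste0("p_slope_", nm)]] <- if (nrow(row)) row$p else NA_real_
    single <- mrm(sor, preds[i], n_perm = n_perm, seed = seeds[1 + i])
    out[[paste0("r2_", nm)]] <- if (single$p_r2 < alpha) single$r2 else 0
    out[[paste0("p_r2_", nm)]] <- single$p_r2
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}
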