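# Generalized least squares with optional Brownian-motion correlation and
# variance weights; AICc model selection over predictor subsets.

#' Generalized least squares fit with BM correlation and variance weights
#'
#' ML fit of y = X b + e with Var(e) = sigma2 * W^(1/2) V W^(1/2), where V is
#' the Brownian-motion correlation of the tree (its covariance scaled to unit
#' diagonal) or the identity, and W holds relative variance weights
#' (normalized to mean 1, so sigma2 stays interpretable). Coefficient tests
#' are two-sided t tests on n - p degrees of freedom.
#'
#' @param y named response vector over families.
#' @param X design matrix (or data.frame of predictors; an intercept column
#'   is added when absent).
#' @param tree `phylo` object, required when `correlation = "BM"`.
#' @param weights optional relative variances (e.g. squared SEs of the
#'   response); zeros floored at 1e-8 x mean with a warning.
#' @param correlation `"none"` or `"BM"`.
#' @return object of class `gls_fit`: `coefficients` table (estimate, se, t,
#'   p), `sigma2` (ML), `lnL`, `k` (parameter count incl. sigma2), `n`,
#'   `AICc`, `correlation`, `weighted`.
#' @export
gls_fit <- function(y, X = NULL, tree = NULL, weights = NULL,
                    correlation = c("none", "BM")) {
  correlation <- match.arg(correlation)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (!any(apply(X, 2, function(col) all(col == col[1]))))
    X <- cbind(`(Intercept)` = 1, X)
  p <- ncol(X)
  if (qr(X)$rank < p) stop("singular design matrix")
  if (correlation == "BM") {
    if (is.null(tree)) stop("BM correlation requires a tree")
    yn <- align_to_tips(y, tree)
    C <- bm_covariance(tree)[names(yn), names(yn)]
    V <- stats::cov2cor(C)
    ord <- match(names(yn), names(y))
    X <- X[ord, , drop = FALSE]
    if (!is.null(weights)) weights <- weights[ord]
    y <- yn
  } else {
    V <- diag(n)
  }
  if (!is.null(weights)) {
    stopifnot(length(weights) == n, all(weights >= 0))
    if (any(weights == 0)) {
      warning("zero weights floored at 1e-8 x mean")
      weights[weights == 0] <- 1e-8 * mean(weights[weights > 0])
    }
    w <- weights / mean(weights)
    sw <- sqrt(w)
    S0 <- V * tcrossprod(sw)  # W^(1/2) V W^(1/2)
  } else {
    S0 <- V
  }
  cs <- chol_solver(S0)
  Xi <- cs$solve(X)
  XtSX <- crossprod(X, Xi)
  b <- solve(XtSX, crossprod(Xi, y))
  r <- as.numeric(y - X %*% b)
  rss <- sum(r * cs$solve(r))
  sigma2_ml <- rss / n
  lnL <- -0.5 * (n * log(2 * pi * sigma2_ml) + cs$logdet + n)
  vcv_b <- solve(XtSX) * rss / (n - p)  # unbiased sigma2 for tests (as nlme)
  se <- sqrt(diag(vcv_b))
  tval <- as.numeric(b) / se
  pval <- 2 * stats::pt(abs(tval), n - p, lower.tail = FALSE)
  k <- p + 1
  aicc <- if (n > k + 1) -2 * lnL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
          else Inf
  structure(list(
    coefficients = data.frame(term = colnames(X), estimate = as.numeric(b),
                              se = se, t = tval, p = pval,
                              stringsAsFactors = FALSE),
    sigma2 = sigma2_ml, lnL = lnL, k = k, n = n, AICc = aicc,
    correlation = correlation, weighted = !is.null(weights)
  ), class = "gls_fit")
}

#' @export
print.gls_fit <- function(x, ...) {
  cat(sprintf("GLS (%s correlation%s): lnL = %.3f, AICc = %.3f\n",
              x$correlation, if (x$weighted) ", weighted" else "",
              x$lnL, x$AICc))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

# Significance stars at 0.10 / 0.05 / 0.01 / 0.001.
p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
    ifelse(p < 0.05, "*", ifelse(p < 0.10, ".", ""))))
}

#' AICc model selection over predictor subsets x correlation structure
#'
#' Enumerates the intercept-only model and every predictor subset, each with
#' and without the BM correlation structure (exhaustive enumeration makes the
#' forward/backward search deterministic at the few predictors used here).
#' Models are ranked by AICc; Akaike weights and the dAICc < 3 equal-support
#' flag are reported.
#'
#' @param y named response vector over families.
#' @param predictors data.frame of candidate predictors (rows = families,
#'   ordered like `y`).
#' @param tree `phylo` for the BM-correlated candidates.
#' @param weights optional relative response variances.
#' @param max_size largest subset size (default: all predictors).
#' @return object of class `model_table`: data.frame ranked by AICc with
#'   `predictors`, `correlation`, `k`, `lnL`, `AICc`, `dAICc`, `weight`,
#'   `supported` (dAICc < 3), `coef_summary`; plus `fits` (list).
#' @export
model_selection <- function(y, predictors, tree = NULL, weights = NULL,
                            max_size = ncol(predictors)) {
  predictors <- as.data.frame(predictors)
  pn <- names(predictors)
  subsets <- list(character(0))
  for (s in seq_len(min(max_size, length(pn))))
    subsets <- c(subsets, utils::combn(pn, s, simplify = FALSE))
  corrs <- if (is.null(tree)) "none" else c("none", "BM")
  rows <- list()
  fits <- list()
  dropped <- character(0)
  for (ss in subsets) {
    X <- if (length(ss)) as.matrix(predictors[, ss, drop = FALSE]) else NULL
    for (cr in corrs) {
      label <- paste(c(if (length(ss)) ss, if (cr == "BM") "BM"),
                     collapse = " + ")
      if (label == "") label <- "(intercept)"
      fit <- tryCatch(
        gls_fit(y, X, tree = tree, weights = weights, correlation = cr),
        error = function(e) NULL)
      if (is.null(fit) || !is.finite(fit$AICc)) {
        dropped <- c(dropped, label)
        next
      }
      co <- fit$coefficients
      co <- co[co$term != "(Intercept)", , drop = FALSE]
      coef_summary <- if (nrow(co))
        paste(sprintf("%s (%.3g%s)", co$term, co$estimate, p_stars(co$p)),
              collapse = " + ")
      else ""
      rows[[length(rows) + 1]] <- data.frame(
        predictors = label, correlation = cr, k = fit$k, lnL = fit$lnL,
        AICc = fit$AICc, coef_summary = coef_summary,
        stringsAsFactors = FALSE)
      fits[[label]] <- fit
    }
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$AICc), , drop = FALSE]
  tab$dAICc <- tab$AICc - tab$AICc[1]
  rel <- exp(-tab$dAICc / 2)
  tab$weight <- rel / sum(rel)
  tab$supported <- tab$dAICc < 3
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits, dropped = dropped),
            class = "model_table")
}

#' @export
print.model_table <- function(x, ...) {
  print(x$table[, c("predictors", "correlation", "AICc", "dAICc", "weight",
                    "supported")], row.names = FALSE, digits = 4)
  if (length(x$dropped))
    cat("dropped (n <= k + 1 or singular):",
        paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}
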