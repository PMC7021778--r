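# Shared fixtures, built in code at test time.

# Small deterministic occurrence matrix: 6 sites x 7 species, 3 families.
toy_occurrence <- function() {
  inc <- rbind(
    S1 = c(1, 1, 0, 1, 0, 0, 1),
    S2 = c(1, 0, 1, 0, 1, 0, 0),
    S3 = c(0, 1, 1, 0, 0, 1, 0),
    S4 = c(1, 1, 0, 0, 1, 0, 1),
    S5 = c(0, 0, 0, 1, 0, 1, 0),
    S6 = c(1, 0, 1, 1, 0, 0, 0))
  colnames(inc) <- paste0("sp", 1:7)
  tax <- setNames(c("A", "A", "A", "B", "B", "B", "C"), colnames(inc))
  occurrence_matrix(inc, tax)
}

toy_metadata <- function(sites = paste0("S", 1:6)) {
  n <- length(sites)
  # coordinates deliberately irregular so no two distance matrices are
  # collinear
  xs <- c(0, 4, 1, 9, 3, 7)[seq_len(n)]
  ys <- c(2, 8, 5, 0, 7, 3)[seq_len(n)]
  site_metadata(data.frame(
    site = sites,
    x = xs,
    y = ys,
    elevation = c(100, 900, 400, 1600, 700, 1200)[seq_len(n)],
    habitat_1 = c(0.2, 0.5, 0.3, 0.7, 0.4, 0.6)[seq_len(n)],
    habitat_2 = 1 - c(0.2, 0.5, 0.3, 0.7, 0.4, 0.6)[seq_len(n)],
    stringsAsFactors = FALSE))
}

# Balanced 4-tip ultrametric tree: ((a:1,b:1):1,(c:1,d:1):1);
balanced4 <- function() {
  ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
}

# Random symmetric zero-diagonal matrix with labels.
rand_sym <- function(n, labels = NULL, scale = 1) {
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- stats::runif(n * (n - 1) / 2) * scale
  m <- m + t(m)
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  m
}

# Independent OLS on unfolded lower triangles (oracle for mrm).
ols_on_triangles <- function(response, predictors) {
  yv <- response[lower.tri(response)]
  xs <- lapply(predictors, function(m) m[lower.tri(m)])
  stats::lm(yv ~ ., data = as.data.frame(xs))
}

# Independent multivariate-normal log-density (oracle for BM/GLS fits).
dmvnorm_log <- function(y, mean, V) {
  n <- length(y)
  r <- y - mean
  ev <- eigen(V, symmetric = TRUE)
  -0.5 * (n * log(2 * pi) + sum(log(ev$values)) +
            sum((crossprod(ev$vectors, r))^2 / ev$values))
}

# Exhaustive permutation generator (oracle, independent of the package's).
perms_oracle <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perms_oracle(n - 1L)) {
    for (k in 0:(n - 1L)) out[[length(out) + 1L]] <- append(p, n, after = k)
  }
  out
}
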