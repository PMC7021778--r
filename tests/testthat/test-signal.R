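test_that("Blomberg K equals a hand-built linear-algebra oracle on 4 tips", {
  tr <- balanced4()
  x <- c(a = 2.0, b = 1.6, c = -0.5, d = -0.9)
  got <- blomberg_k(x, tr, n_perm = 0)$K
  # oracle: direct evaluation of the variance-ratio formula
  C <- ape::vcv(tr)[names(x), names(x)]
  iC <- solve(C)
  one <- rep(1, 4)
  mu <- sum(iC %*% x) / sum(iC %*% one)
  mse0 <- sum((x - mu)^2) / 3
  mse <- drop(t(x - mu) %*% iC %*% (x - mu)) / 3
  expected <- (sum(diag(C)) - 4 / sum(iC)) / 3
  expect_equal(got, (mse0 / mse) / expected, tolerance = 1e-12)
})

test_that("Blomberg K agrees with the phytools reference implementation", {
  skip_if_not_installed("phytools")
  set.seed(19)
  tr <- simulate_tree(15, depth_ma = 250, seed = 2)
  x <- simulate_bm_traits(tr, sigma2 = 0.5, root_value = 3, seed = 4)[, 1]
  expect_equal(blomberg_k(x, tr, n_perm = 0)$K,
               as.numeric(phytools::phylosig(tr, x, method = "K")),
               tolerance = 1e-8)
  # SE-weighted variant: same error model, nearly identical K
  se <- setNames(runif(15, 0.05, 0.3), names(x))
  expect_equal(blomberg_k(x, tr, se = se, n_perm = 0)$K,
               unname(phytools::phylosig(tr, x, method = "K", se = se)$K),
               tolerance = 0.01)
})

test_that("K averages 1 under BM, is affine-invariant, and SEs nest", {
  tr <- simulate_tree(20, depth_ma = 300, seed = 8)
  Y <- simulate_bm_traits(tr, sigma2 = 1, n_reps = 150, seed = 9)
  ks <- vapply(seq_len(ncol(Y)), function(j)
    blomberg_k(Y[, j], tr, n_perm = 0)$K, numeric(1))
  expect_lt(abs(mean(ks) - 1), 0.15)

  x <- Y[, 1]
  k1 <- blomberg_k(x, tr, n_perm = 0)$K
  k2 <- blomberg_k(5 * x - 3, tr, n_perm = 0)$K
  expect_equal(k1, k2, tolerance = 1e-10)
  # with SEs rescaled alongside the values
  se <- setNames(runif(20, 0.05, 0.2), names(x))
  k3 <- blomberg_k(x, tr, se = se, n_perm = 0)$K
  k4 <- blomberg_k(5 * x - 3, tr, se = 5 * se, n_perm = 0)$K
  expect_equal(k3, k4, tolerance = 1e-6)
  # se -> 0 recovers the unweighted statistic
  k5 <- blomberg_k(x, tr, se = se * 0 + 1e-8, n_perm = 0)$K
  expect_equal(k5, k1, tolerance = 1e-4)

  expect_error(blomberg_k(setNames(rep(1, 20), names(x)), tr), "constant")
})

test_that("K permutation test detects BM signal and stays null-calibrated", {
  tr <- simulate_tree(16, depth_ma = 300, seed = 21)
  x <- simulate_bm_traits(tr, sigma2 = 1, seed = 22)[, 1]
  res <- blomberg_k(x, tr, n_perm = 499, seed = 23)
  expect_lt(res$p, 0.05)
  expect_gte(res$p, 1 / 500)
  # shuffled values: p should be unremarkable most of the time (spot check)
  set.seed(24)
  ps <- replicate(20, {
    xs <- setNames(sample(x), names(x))
    blomberg_k(xs, tr, n_perm = 99, seed = NULL)$p
  })
  expect_gt(mean(ps > 0.05), 0.6)
})

test_that("D statistic hits its construction endpoints and sign behavior", {
  tr <- simulate_tree(24, depth_ma = 200, seed = 31)
  n <- 24

  # thresholded BM traits -> D near 0; random shuffles -> D near 1
  set.seed(32)
  d_bm <- replicate(40, {
    y <- simulate_bm_traits(tr, 1, seed = NULL)[, 1]
    b <- setNames(as.numeric(rank(y, ties.method = "first") > n - 8),
                  names(y))
    d_statistic(b, tr, n_perm = 150, seed = NULL)$D
  })
  expect_lt(abs(mean(d_bm) - 0), 0.15)
  d_rand <- replicate(40, {
    b <- setNames(sample(c(rep(1, 8), rep(0, n - 8))), tr$tip.label)
    d_statistic(b, tr, n_perm = 150, seed = NULL)$D
  })
  expect_lt(abs(mean(d_rand) - 1), 0.15)

  # one clade fixed at 1 on a balanced two-clade tree: D typically < 0
  bal <- ape::read.tree(
    text = "(((a:1,b:1):1,(c:1,d:1):1):2,((e:1,f:1):1,(g:1,h:1):1):2);")
  b <- setNames(c(1, 1, 1, 1, 0, 0, 0, 0), letters[1:8])
  dd <- d_statistic(b, bal, n_perm = 400, seed = 5)
  expect_lt(dd$D, 0.3)
  expect_lt(dd$p_random, 0.2)

  expect_error(d_statistic(setNames(rep(1, 24), tr$tip.label), tr),
               "prevalence")
})

test_that("effect sizes follow the printed formulas and invariances", {
  es <- effect_size_matrix(c(a = 10, b = 20), se = c(a = 2, b = 2))
  expect_equal(es["a", "b"], 5)  # 10 / sqrt((4+4)/2) = 10/2

  raw <- effect_size_matrix(c(a = 1.5, b = 1.5, c = 3),
                            kind = "raw_difference")
  expect_equal(raw["a", "b"], 0)
  expect_equal(raw["a", "c"], 1.5)

  set.seed(41)
  x <- setNames(rnorm(6), letters[1:6])
  se <- setNames(runif(6, .1, 1), letters[1:6])
  m <- effect_size_matrix(x, se)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 6))
  # scale-free under joint rescaling
  expect_equal(effect_size_matrix(10 * x, 10 * se), m, tolerance = 1e-12)

  expect_error(effect_size_matrix(c(a = 1, b = 2), se = c(a = 0, b = 0)),
               "undefined")
  expect_error(effect_size_matrix(c(a = 1, b = 2), kind = "cohens_d"),
               "requires")
})

test_that("distance regression matches OLS and exact enumeration oracles", {
  set.seed(51)
  tr <- simulate_tree(5, depth_ma = 100, seed = 3)
  patr <- patristic_matrix(tr)

  # proportional dissimilarity: slope recovered exactly, R2 = 1
  prop <- signal_distance_regression(0.01 * patr, patr, n_perm = 199,
                                     seed = 6)
  expect_equal(prop$slope, 0.01, tolerance = 1e-12)
  expect_equal(prop$r2, 1, tolerance = 1e-12)
  # p is bounded below by 1/(n_perm+1) and inflated only by exact ties from
  # tree automorphisms (label swaps that reproduce the perfect fit)
  expect_gte(prop$p, 1 / 200)
  expect_lte(prop$p, 0.05)

  # OLS oracle on unfolded triangles
  diss <- rand_sym(5, tr$tip.label)
  got <- signal_distance_regression(diss, patr, n_perm = 99, seed = 7)
  oracle <- ols_on_triangles(diss, list(pa = patr[rownames(diss),
                                                  rownames(diss)]))
  expect_equal(got$slope, unname(coef(oracle))[2], tolerance = 1e-10)
  expect_equal(got$r2, summary(oracle)$r.squared, tolerance = 1e-10)

  # exact 5! enumeration equals an independent oracle
  ex <- signal_distance_regression(diss, patr, exact = TRUE)
  obs_t <- abs(coef(summary(oracle))[2, 3])
  ts <- vapply(perms_oracle(5), function(pm) {
    dp <- diss[pm, pm]
    abs(coef(summary(ols_on_triangles(dp, list(pa = patr[rownames(diss),
                                                         rownames(diss)]))))[2, 3])
  }, numeric(1))
  expect_equal(ex$p, mean(ts >= obs_t - 1e-12))
  expect_equal(ex$n_perm, factorial(5))
})
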