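test_that("Sørensen values follow (b+c)/(2a+b+c) and its endpoints", {
  inc <- rbind(S1 = c(1, 1, 0), S2 = c(0, 1, 1))
  colnames(inc) <- paste0("sp", 1:3)
  occ <- occurrence_matrix(inc, setNames(rep("F", 3), colnames(inc)))
  expect_equal(sorensen_matrix(occ)["S1", "S2"], 0.5)  # (1+1)/(2+1+1)

  inc2 <- rbind(S1 = c(1, 0, 1), S2 = c(1, 0, 1), S3 = c(0, 1, 0))
  colnames(inc2) <- paste0("sp", 1:3)
  occ2 <- occurrence_matrix(inc2, setNames(rep("F", 3), colnames(inc2)))
  sm <- sorensen_matrix(occ2)
  expect_equal(sm["S1", "S2"], 0)  # identical composition
  expect_equal(sm["S1", "S3"], 1)  # disjoint composition
  expect_true(all(sm >= 0 & sm <= 1))

  # invariant under species-column permutation
  set.seed(3)
  inc3 <- matrix(rbinom(8 * 10, 1, .4), 8, 10,
                 dimnames = list(paste0("S", 1:8), paste0("sp", 1:10)))
  inc3[rowSums(inc3) == 0, 1] <- 1
  occ3 <- occurrence_matrix(inc3, setNames(rep("F", 10), colnames(inc3)))
  perm <- sample(10)
  occ3p <- occurrence_matrix(inc3[, perm], setNames(rep("F", 10),
                                                    colnames(inc3)[perm]))
  expect_equal(sorensen_matrix(occ3), sorensen_matrix(occ3p))
})

test_that("site distances: elevation gaps, arcsine habitat, zero identities", {
  meta <- site_metadata(data.frame(
    site = c("S1", "S2"), x = c(0, 3), y = c(0, 4),
    elevation = c(100, 400), habitat_1 = c(0.25, 1.0)))
  dd <- site_distance_matrices(meta)
  expect_equal(dd$elevational["S1", "S2"], 300)
  expect_equal(dd$geographic["S1", "S2"], 5)  # 3-4-5 triangle
  # |arcsin(.5) - arcsin(1)| = pi/6 - pi/2 -> pi/3
  expect_equal(dd$habitat["S1", "S2"], pi / 3)

  meta2 <- site_metadata(data.frame(
    site = c("A", "B"), x = c(1, 1), y = c(2, 2),
    elevation = c(5, 5), habitat_1 = c(.4, .4), habitat_2 = c(.6, .6)))
  dd2 <- site_distance_matrices(meta2)
  expect_equal(dd2$habitat["A", "B"], 0)
  expect_equal(dd2$geographic["A", "B"], 0)
})

test_that("MRM coefficients equal OLS on the unfolded triangles", {
  set.seed(12)
  labs <- paste0("S", 1:9)
  p1 <- rand_sym(9, labs); p2 <- rand_sym(9, labs)
  resp <- 0.3 + 1.5 * p1 - 0.7 * p2 + rand_sym(9, labs, scale = 0.1)
  got <- mrm(resp, list(a = p1, b = p2), n_perm = 99, seed = 4)
  oracle <- ols_on_triangles(resp, list(a = p1, b = p2))
  expect_equal(got$coefficients$slope, unname(coef(oracle))[2:3],
               tolerance = 1e-10)
  expect_equal(got$intercept, unname(coef(oracle))[1], tolerance = 1e-10)
  expect_equal(got$r2, summary(oracle)$r.squared, tolerance = 1e-10)
  expect_equal(got$coefficients$se,
               unname(coef(summary(oracle))[2:3, 2]), tolerance = 1e-10)

  # response = 2 x predictor exactly: slope 2, R2 = 1, minimum attainable p
  got2 <- mrm(2 * p1, list(a = p1), n_perm = 999, seed = 5)
  expect_equal(got2$coefficients$slope, 2, tolerance = 1e-12)
  expect_equal(got2$r2, 1, tolerance = 1e-12)
  expect_equal(got2$p_r2, 1 / 1000)

  # constant predictor is flagged and dropped
  expect_warning(
    got3 <- mrm(resp, list(a = p1, const = matrix(2, 9, 9) - diag(2, 9))),
    "constant predictor")
  expect_identical(got3$dropped, "const")
})

test_that("exact permutation p equals exhaustive enumeration on 4 sites", {
  set.seed(9)
  labs <- paste0("S", 1:4)
  pred <- rand_sym(4, labs)
  resp <- 1.2 * pred + rand_sym(4, labs, scale = 0.5)
  got <- mrm(resp, list(a = pred), exact = TRUE)
  expect_equal(got$n_perm, factorial(4))

  # independent enumeration oracle
  obs <- local({
    f <- ols_on_triangles(resp, list(a = pred))
    abs(coef(summary(f))[2, 3])
  })
  ts <- vapply(perms_oracle(4), function(pm) {
    rp <- resp[pm, pm]
    f <- ols_on_triangles(rp, list(a = pred))
    abs(coef(summary(f))[2, 3])
  }, numeric(1))
  expect_equal(got$coefficients$p, mean(ts >= obs - 1e-12))
})

test_that("turnover responses recover structure and zero out null R²", {
  # elevation-only decay: slope_z positive and significant, r2_xy mostly 0
  set.seed(42)
  st <- simulate_study(n_families = 3, n_sites = 120,
                       species_per_family = 18, seed = 77,
                       width_range = c(500, 500),
                       amplitude_range = c(0.9, 0.9),
                       turnover_xy_range = c(1e-4, 1e-4),
                       turnover_z_range = c(0.003, 0.003),
                       landscape = list(drift = 0))
  tr <- turnover_responses(st$occ, st$meta, "F01", n_perm = 199, seed = 3)
  expect_gt(tr$slope_z, 0)
  expect_lt(tr$p_slope_z, 0.05)
  expect_gt(tr$r2_z, 0)

  # identical compositions everywhere: all dissimilarities and slopes 0
  inc <- matrix(1, 6, 4, dimnames = list(paste0("S", 1:6), paste0("sp", 1:4)))
  occ <- occurrence_matrix(inc, setNames(rep("F", 4), colnames(inc)))
  tr0 <- turnover_responses(occ, toy_metadata(), "F", n_perm = 99, seed = 1)
  expect_equal(tr0$slope_z, 0, tolerance = 1e-10)
  expect_equal(tr0$slope_xy, 0, tolerance = 1e-10)
  expect_equal(tr0$r2_z, 0)
})

test_that("permutation p-values are well calibrated under the null", {
  # response unrelated to the predictor: p approximately uniform
  set.seed(101)
  ps <- replicate(60, {
    labs <- paste0("S", 1:10)
    mrm(rand_sym(10, labs), list(a = rand_sym(10, labs)),
        n_perm = 99)$coefficients$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_lt(mean(ps <= 0.05), 0.15)
})
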