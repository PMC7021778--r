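test_that("occurrence files are read back identically and aligned to metadata", {
  dir <- withr::local_tempdir()
  m <- rbind(S1 = c(0, 1, 1, 0), S2 = c(1, 0, 0, 1), S3 = c(1, 1, 0, 0))
  colnames(m) <- paste0("sp", 1:4)
  write.csv(cbind(site = rownames(m), as.data.frame(m)),
            file.path(dir, "occ.csv"), row.names = FALSE)
  write.csv(data.frame(species = paste0("sp", 1:4),
                       family = c("A", "A", "B", "B")),
            file.path(dir, "tax.csv"), row.names = FALSE)
  meta <- data.frame(site = c("S1", "S2", "S3"), x = 1:3, y = 3:1,
                     elevation = c(100, 500, 900), habitat_1 = c(.2, .5, .8))
  write.csv(meta, file.path(dir, "meta.csv"), row.names = FALSE)

  got <- read_occurrence(file.path(dir, "occ.csv"), file.path(dir, "tax.csv"),
                         file.path(dir, "meta.csv"))
  expect_identical(dim(got$occ$incidence), c(3L, 4L))
  expect_identical(unname(got$occ$incidence), unname(m) * 1.0)
  expect_identical(got$meta$site, got$occ$sites)

  # a site missing from the metadata is a hard error naming it
  write.csv(meta[-2, ], file.path(dir, "meta2.csv"), row.names = FALSE)
  expect_error(
    read_occurrence(file.path(dir, "occ.csv"), file.path(dir, "tax.csv"),
                    file.path(dir, "meta2.csv")),
    "S2")

  # abundance cell 2 is coerced to presence with one warning
  m2 <- m; m2["S1", "sp2"] <- 2
  write.csv(cbind(site = rownames(m2), as.data.frame(m2)),
            file.path(dir, "occ2.csv"), row.names = FALSE)
  expect_warning(
    got2 <- read_occurrence(file.path(dir, "occ2.csv"),
                            file.path(dir, "tax.csv"),
                            file.path(dir, "meta.csv")),
    "coerced")
  expect_identical(got2$occ$incidence["S1", "sp2"], 1)

  # species without taxonomy is a hard error listing the offender
  write.csv(data.frame(species = paste0("sp", 1:3),
                       family = c("A", "A", "B")),
            file.path(dir, "tax2.csv"), row.names = FALSE)
  expect_error(
    read_occurrence(file.path(dir, "occ.csv"), file.path(dir, "tax2.csv"),
                    file.path(dir, "meta.csv")),
    "sp4")
})

test_that("family filter applies inclusive thresholds and flags all families", {
  # family occupying 49 plots with 6 species is excluded; 50 plots and
  # exactly 5 species is retained
  n_sites <- 60
  inc <- matrix(0, n_sites, 11,
                dimnames = list(sprintf("S%02d", 1:n_sites),
                                sprintf("sp%02d", 1:11)))
  inc[1:49, 1:6] <- 1                      # family X: 49 plots, 6 species
  inc[1:50, 7:11] <- 1                     # family Y: 50 plots, 5 species
  tax <- setNames(rep(c("X", "Y"), c(6, 5)), colnames(inc))
  tab <- filter_families(occurrence_matrix(inc, tax))
  expect_false(tab$retained[tab$family == "X"])
  expect_true(tab$retained[tab$family == "Y"])
  expect_setequal(tab$family, c("X", "Y"))
})

test_that("occupancy flags match brute-force recounting on random matrices", {
  set.seed(11)
  for (rep in 1:3) {
    inc <- matrix(rbinom(40 * 12, 1, 0.3), 40, 12,
                  dimnames = list(sprintf("S%02d", 1:40),
                                  sprintf("sp%02d", 1:12)))
    tax <- setNames(sample(c("A", "B", "C"), 12, replace = TRUE),
                    colnames(inc))
    if (length(unique(tax)) < 3) next
    tab <- filter_families(occurrence_matrix(inc, tax),
                           min_plots = 10, min_species = 3)
    for (f in tab$family) {
      occ_brute <- sum(apply(inc[, tax == f, drop = FALSE], 1,
                             function(r) any(r > 0)))
      expect_equal(tab$occupancy[tab$family == f], occ_brute)
      expect_equal(tab$n_species[tab$family == f], sum(tax == f))
      expect_equal(tab$retained[tab$family == f],
                   occ_brute >= 10 && sum(tax == f) >= 3)
    }
  }
})

test_that("filtering is idempotent and monotone in both thresholds", {
  occ <- toy_occurrence()
  t1 <- filter_families(occ, min_plots = 2, min_species = 2)
  kept1 <- t1$family[t1$retained]
  for (mp in 1:5) {
    for (ms in 1:4) {
      tt <- filter_families(occ, mp, ms)
      stricter <- filter_families(occ, mp + 1, ms + 1)
      expect_true(all(stricter$family[stricter$retained] %in%
                        tt$family[tt$retained]))
    }
  }
  # idempotence: re-filtering the retained submatrix changes nothing
  sub <- occ$incidence[, occ$taxonomy %in% kept1, drop = FALSE]
  occ2 <- occurrence_matrix(sub, occ$taxonomy[colnames(sub)])
  t2 <- filter_families(occ2, min_plots = 2, min_species = 2)
  expect_setequal(t2$family[t2$retained], kept1)
})

test_that("trait aggregation matches a direct group-by oracle", {
  # forced examples: mean of logs, incidence fractions
  tr <- data.frame(species = paste0("sp", 1:4),
                   body_size = c(10, 100, 20, 30),
                   plant_int = c(1, 1, 1, 0))
  tax <- setNames(rep("F1", 4), tr$species)
  got <- aggregate_family_traits(tr, tax, "F1")
  expect_equal(got$body_size_mean, mean(log(tr$body_size)))
  expect_equal(got$plant_int_incidence, 0.75)

  # random table vs brute-force per-family recomputation
  set.seed(7)
  tr2 <- data.frame(species = paste0("sp", 1:20),
                    wing = rnorm(20, 50, 5),
                    body_size = rlnorm(20, 2, 0.4),
                    herbivore = rbinom(20, 1, 0.5))
  tax2 <- setNames(rep(c("A", "B"), each = 10), tr2$species)
  got2 <- aggregate_family_traits(tr2, tax2, c("A", "B"))
  for (f in c("A", "B")) {
    sub <- tr2[tax2[tr2$species] == f, ]
    row <- got2[got2$family == f, ]
    expect_equal(row$wing_mean, mean(sub$wing))
    expect_equal(row$wing_se, sd(sub$wing) / sqrt(nrow(sub)))
    expect_equal(row$body_size_mean, mean(log(sub$body_size)))
    expect_equal(row$herbivore_incidence, mean(sub$herbivore))
    expect_gte(row$herbivore_incidence, 0)
    expect_lte(row$herbivore_incidence, 1)
  }

  # single-species family: SE 0 with a warning
  tax3 <- setNames(c(rep("A", 19), "B"), tr2$species)
  expect_warning(got3 <- aggregate_family_traits(tr2, tax3, c("A", "B")),
                 "single-species")
  expect_equal(got3$wing_se[got3$family == "B"], 0)
})

test_that("higher-level features equal union-of-rows oracles", {
  occ <- toy_occurrence()
  filt <- filter_families(occ, min_plots = 1, min_species = 1)
  hl <- higher_level_features(occ, filt)
  expect_equal(hl$richness[hl$family == "A"], 3)
  # occupancy = nonzero count of the OR of member columns
  for (f in hl$family) {
    or_vec <- apply(occ$incidence[, occ$taxonomy == f, drop = FALSE], 1, max)
    expect_equal(hl$occupancy[hl$family == f], sum(or_vec))
  }
  expect_lte(max(hl$occupancy), length(occ$sites))
  expect_lte(sum(hl$richness), length(occ$species))
})
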