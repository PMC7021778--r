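# Synthetic studies with recorded ground truth: ultrametric family
# phylogeny, Brownian-evolved response parameters, landscape, and
# presence-absence occurrence matrices.

#' Simulate an ultrametric pure-birth family phylogeny
#'
#' Pure-birth topology with branch lengths rescaled so the root-to-tip depth
#' equals `depth_ma` exactly. Tips are labeled F01, F02, ...
#'
#' @param n_tips number of families (>= 2).
#' @param depth_ma tree depth in Ma (default 300).
#' @param seed RNG seed.
#' @return an ultrametric `phylo`.
#' @export
simulate_tree <- function(n_tips, depth_ma = 300, seed = NULL) {
  stopifnot(n_tips >= 2)
  tr <- if (n_tips == 2) {
    ape::read.tree(text = sprintf("(F01:%g,F02:%g);", depth_ma, depth_ma))
  } else {
    t0 <- with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
    depth <- max(ape::node.depth.edgelength(t0))
    t0$edge.length <- t0$edge.length * depth_ma / depth
    t0$tip.label <- sprintf("F%02d", seq_len(n_tips))
    t0
  }
  tr
}

#' Simulate Brownian-motion trait evolution on a tree
#'
#' Each replicate is one multivariate-normal draw with mean `root_value` and
#' covariance `sigma2 * C`, C the shared branch-length matrix.
#'
#' @param tree a `phylo`.
#' @param sigma2 Brownian rate (>= 0; 0 returns the root value at all tips).
#' @param root_value root state (default 0).
#' @param n_reps number of independent replicates (default 1).
#' @param seed RNG seed.
#' @return matrix of tips x replicates, rownames = tip labels.
#' @export
simulate_bm_traits <- function(tree, sigma2 = 1, root_value = 0, n_reps = 1,
                               seed = NULL) {
  stopifnot(sigma2 >= 0)
  n <- length(tree$tip.label)
  if (sigma2 == 0)
    return(matrix(root_value, n, n_reps, dimnames = list(tree$tip.label, NULL)))
  C <- bm_covariance(tree)[tree$tip.label, tree$tip.label]
  L <- t(chol(sigma2 * C))
  Z <- with_seed(seed, matrix(stats::rnorm(n * n_reps), n, n_reps))
  Y <- root_value + L %*% Z
  rownames(Y) <- tree$tip.label
  Y
}

#' Simulate a mountain landscape of survey sites
#'
#' Coordinates uniform on a square, elevations uniform over the gradient,
#' and habitat cover proportions from an elevation-drifting composition, so
#' habitat dissimilarity correlates with elevational distance when
#' `drift > 0` (and is independent at `drift = 0`).
#'
#' @param n_sites number of sites (>= 20).
#' @param elev_range elevation range in m (default 0-2400).
#' @param n_habitats number of habitat types (default 4).
#' @param extent_km side of the square study area in km (default 100).
#' @param drift strength of the elevation-composition coupling (default 1.5).
#' @param seed RNG seed.
#' @return a `site_metadata` data.frame with `site`, `x`, `y` (km),
#'   `elevation` (m) and `habitat_*` columns summing to 1 per site.
#' @export
simulate_landscape <- function(n_sites, elev_range = c(0, 2400),
                               n_habitats = 4, extent_km = 100, drift = 1.5,
                               seed = NULL) {
  stopifnot(n_sites >= 20)
  with_seed(seed, {
    x <- stats::runif(n_sites, 0, extent_km)
    y <- stats::runif(n_sites, 0, extent_km)
    elev <- stats::runif(n_sites, elev_range[1], elev_range[2])
    # habitat loadings spread along the gradient; softmax composition
    load <- seq(-1, 1, length.out = n_habitats)
    e01 <- (elev - elev_range[1]) / diff(elev_range) * 2 - 1
    lin <- drift * outer(e01, load) +
      matrix(stats::rnorm(n_sites * n_habitats, sd = 0.3),
             n_sites, n_habitats)
    w <- exp(lin)
    cover <- w / rowSums(w)
    meta <- data.frame(site = sprintf("S%03d", seq_len(n_sites)),
                       x = x, y = y, elevation = elev,
                       stringsAsFactors = FALSE)
    for (h in seq_len(n_habitats))
      meta[[sprintf("habitat_%d", h)]] <- cover[, h]
    site_metadata(meta)
  })
}

#' Ground-truth family response parameters evolving on a tree
#'
#' The family diversity-peak elevations evolve under Brownian motion with
#' rate `sigma2_peak` from a root at mid-gradient (clamped to the central 90%
#' of the gradient so every true peak stays inside the observed range); curve
#' widths, richness amplitudes and turnover rates are drawn around realistic
#' mid-gradient community values.
#'
#' @param tree family phylogeny.
#' @param elev_range elevation range of the landscape (m).
#' @param sigma2_peak Brownian rate of the peak elevation (m^2 / Ma; default
#'   1200, i.e. tip SD ~ 600 m on a 300-Ma tree).
#' @param width_range range of family curve widths (m, default 300-700).
#' @param amplitude_range range of peak occupancy probabilities (default
#'   0.35-0.7).
#' @param turnover_xy_range geographic decay rates (1/km, default 0.01-0.08).
#' @param turnover_z_range elevational decay rates (1/m, default
#'   0.0005-0.004).
#' @param seed RNG seed.
#' @return object of class `synthetic_truth`: `tree`, `params` data.frame
#'   (family, peak, width, amplitude, turnover_xy, turnover_z), `sigma2_peak`,
#'   `elev_range`, `seed`.
#' @export
simulate_truth <- function(tree, elev_range = c(0, 2400), sigma2_peak = 1200,
                           width_range = c(300, 700),
                           amplitude_range = c(0.35, 0.7),
                           turnover_xy_range = c(0.01, 0.08),
                           turnover_z_range = c(0.0005, 0.004),
                           seed = NULL) {
  n <- length(tree$tip.label)
  seeds <- derive_seeds(if (is.null(seed)) 1L else seed, 2)
  root <- mean(elev_range)
  peaks <- simulate_bm_traits(tree, sigma2 = sigma2_peak, root_value = root,
                              seed = seeds[1])[, 1]
  lo <- elev_range[1] + 0.05 * diff(elev_range)
  hi <- elev_range[2] - 0.05 * diff(elev_range)
  peaks <- pmin(pmax(peaks, lo), hi)
  params <- with_seed(seeds[2], data.frame(
    family = tree$tip.label,
    peak = unname(peaks),
    width = stats::runif(n, width_range[1], width_range[2]),
    amplitude = stats::runif(n, amplitude_range[1], amplitude_range[2]),
    turnover_xy = stats::runif(n, turnover_xy_range[1], turnover_xy_range[2]),
    turnover_z = stats::runif(n, turnover_z_range[1], turnover_z_range[2]),
    stringsAsFactors = FALSE))
  structure(list(tree = tree, params = params, sigma2_peak = sigma2_peak,
                 elev_range = elev_range, seed = seed),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth:", nrow(x$params), "families, sigma2_peak =",
      x$sigma2_peak, "\n")
  print(utils::head(x$params, 6), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Simulate family occurrence matrices from ground-truth parameters
#'
#' Each family gets `species_per_family` species whose elevational optima are
#' drawn around the family's true peak with the family's width; the
#' probability that species s occupies site i is
#' `amplitude * exp(-(turnover_z * (elev_i - opt_s))^2 / 2)
#'  * exp(-turnover_xy * d_xy(i, center_s))`,
#' i.e. a Gaussian elevational niche whose bandwidth is the reciprocal of the
#' family's elevational turnover rate (species replace each other along
#' elevation at rate `turnover_z`), times exponential geographic decay around
#' a species-specific center. Family richness therefore peaks near the true
#' peak elevation (curve width ~ sqrt(width^2 + 1/turnover_z^2)), while
#' composition decays with geographic distance (rate `turnover_xy`) and with
#' elevational distance (rate `turnover_z`). A family realizing zero
#' occurrences is regenerated once, then errors.
#'
#' @param truth a `synthetic_truth`.
#' @param meta a `site_metadata` landscape.
#' @param species_per_family species per family (default 12).
#' @param seed RNG seed.
#' @return an `occurrence_matrix` with taxonomy `<family>_sp<k>` -> family.
#' @export
simulate_communities <- function(truth, meta, species_per_family = 12,
                                 seed = NULL) {
  params <- truth$params
  n_fam <- nrow(params)
  n_sites <- nrow(meta)
  seeds <- derive_seeds(if (is.null(seed)) 1L else seed, n_fam)
  cols <- list()
  taxonomy <- character(0)
  for (f in seq_len(n_fam)) {
    pr <- params[f, ]
    draw_family <- function(s) with_seed(s, {
      opt <- stats::rnorm(species_per_family, pr$peak, pr$width)
      cx <- stats::runif(species_per_family, min(meta$x), max(meta$x))
      cy <- stats::runif(species_per_family, min(meta$y), max(meta$y))
      p <- sapply(seq_len(species_per_family), function(sp) {
        dz <- abs(meta$elevation - opt[sp])
        dxy <- sqrt((meta$x - cx[sp])^2 + (meta$y - cy[sp])^2)
        pr$amplitude * exp(-(pr$turnover_z * dz)^2 / 2) *
          exp(-pr$turnover_xy * dxy)
      })
      matrix(stats::rbinom(length(p), 1, p), n_sites, species_per_family)
    })
    m <- draw_family(seeds[f])
    if (sum(m) == 0) m <- draw_family(seeds[f] + 1L)
    if (sum(m) == 0)
      stop("family with zero realized occurrences after regeneration: ",
           pr$family)
    colnames(m) <- sprintf("%s_sp%02d", pr$family, seq_len(species_per_family))
    cols[[f]] <- m
    taxonomy <- c(taxonomy,
                  stats::setNames(rep(pr$family, species_per_family),
                                  colnames(m)))
  }
  inc <- do.call(cbind, cols)
  rownames(inc) <- meta$site
  occurrence_matrix(inc, taxonomy)
}

#' Simulate a complete synthetic study
#'
#' One call producing tree, ground truth, landscape and occurrence matrix
#' from a single master seed (named substreams per stage).
#'
#' @param n_families number of families (default 12).
#' @param n_sites number of sites (default 300).
#' @param species_per_family species per family (default 12).
#' @param depth_ma tree depth (default 300 Ma).
#' @param seed master seed (required for reproducibility).
#' @param landscape named list of extra arguments for [simulate_landscape()]
#'   (e.g. `drift`, `n_habitats`).
#' @param ... passed on to [simulate_truth()].
#' @return list with `tree`, `truth`, `meta`, `occ`, `seed`.
#' @export
simulate_study <- function(n_families = 12, n_sites = 300,
                           species_per_family = 12, depth_ma = 300,
                           seed = 1, landscape = list(), ...) {
  seeds <- derive_seeds(seed, 4)
  tree <- simulate_tree(n_families, depth_ma = depth_ma, seed = seeds[1])
  meta <- do.call(simulate_landscape,
                  c(list(n_sites = n_sites, seed = seeds[2]), landscape))
  truth <- simulate_truth(tree, elev_range = range(meta$elevation),
                          seed = seeds[3], ...)
  occ <- simulate_communities(truth, meta,
                              species_per_family = species_per_family,
                              seed = seeds[4])
  list(tree = tree, truth = truth, meta = meta, occ = occ, seed = seed)
}

#' Write a synthetic study to disk in the package's CSV dialects
#'
#' Emits the occurrence matrix, taxonomy, site metadata and tree (Newick) in
#' exactly the formats [read_occurrence()] consumes, plus the ground truth as
#' JSON.
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "occurrence.csv"),
             taxonomy = file.path(dir, "taxonomy.csv"),
             metadata = file.path(dir, "sites.csv"),
             tree = file.path(dir, "tree.nwk"),
             truth = file.path(dir, "truth.json"))
  inc <- as.data.frame(study$occ$incidence)
  utils::write.csv(cbind(site = rownames(inc), inc), paths["matrix"],
                   row.names = FALSE)
  utils::write.csv(data.frame(species = names(study$occ$taxonomy),
                              family = unname(study$occ$taxonomy)),
                   paths["taxonomy"], row.names = FALSE)
  utils::write.csv(as.data.frame(study$meta), paths["metadata"],
                   row.names = FALSE)
  ape::write.tree(study$tree, paths["tree"])
  jsonlite::write_json(
    list(params = study$truth$params, sigma2_peak = study$truth$sigma2_peak,
         elev_range = study$truth$elev_range, seed = study$seed),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
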