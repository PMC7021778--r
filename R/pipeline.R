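# Full-analysis orchestration: filter -> representativeness -> per-family
# alpha/beta responses -> phylogenetic-signal suite -> power analysis ->
# C-score -> PGLS model tables.

#' Analysis configuration
#'
#' Collects every threshold, permutation count and the mandatory master seed
#' in one validated object; [run_full_analysis()] derives all stage seeds
#' from it.
#'
#' @param min_plots,min_species family filter thresholds (defaults 50 / 5).
#' @param alpha significance level used throughout (default 0.05).
#' @param n_perm_mrm permutations per MRM (default 999).
#' @param n_perm_signal permutations / simulations for K and D (default 1000).
#' @param n_sim_pmc simulated datasets per model in the power analysis
#'   (default 1000).
#' @param basis_dim spline basis dimension (default 10).
#' @param seed master seed (mandatory).
#' @param out_dir optional output directory for CSV/JSON reports.
#' @return a `run_config` list.
#' @export
run_config <- function(min_plots = 50, min_species = 5, alpha = 0.05,
                       n_perm_mrm = 999, n_perm_signal = 1000,
                       n_sim_pmc = 1000, basis_dim = 10, seed,
                       out_dir = NULL) {
  stopifnot(min_plots >= 1, min_species >= 1, alpha > 0, alpha <= 1,
            n_perm_mrm >= 1, n_perm_signal >= 1, n_sim_pmc >= 1)
  if (missing(seed) || is.null(seed)) stop("a master seed is mandatory")
  structure(list(min_plots = min_plots, min_species = min_species,
                 alpha = alpha, n_perm_mrm = n_perm_mrm,
                 n_perm_signal = n_perm_signal, n_sim_pmc = n_sim_pmc,
                 basis_dim = basis_dim, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

# The eight diversity variables and how each enters the signal suite:
# whether it carries an SE (-> SE-weighted K, Cohen's d) or not (raw
# differences).
diversity_variables <- function() {
  data.frame(
    variable = c("peak", "edf_raw", "edf_corrected",
                 "slope_xy", "slope_z", "slope_hab",
                 "r2_xy", "r2_z", "r2_hab"),
    se_col = c("peak_se", NA, NA, "se_xy", "se_z", "se_hab", NA, NA, NA),
    stringsAsFactors = FALSE)
}

# Signal suite (K + distance regression + pmc) for one variable.
signal_suite_one <- function(values, se, subtree, patristic, cfg, seeds) {
  out <- list()
  out$K <- tryCatch(
    blomberg_k(values, subtree, se = se, n_perm = cfg$n_perm_signal,
               seed = seeds[1]),
    error = function(e) e$message)
  out$distreg <- tryCatch({
    es <- if (is.null(se)) effect_size_matrix(values, kind = "raw_difference")
          else effect_size_matrix(values, se, kind = "cohens_d")
    signal_distance_regression(es, patristic, n_perm = cfg$n_perm_mrm,
                               seed = seeds[2])
  }, error = function(e) e$message)
  out$pmc <- tryCatch(
    pmc_power(values, subtree, se = se, n_sim = cfg$n_sim_pmc,
              seed = seeds[3], alpha = cfg$alpha),
    error = function(e) e$message)
  out
}

#' Run the complete analysis on one study
#'
#' Pipeline: family filter and D-statistic representativeness test; per
#' retained family the alpha responses (raw and corrected edf, diversity
#' peak) and the six turnover responses; Blomberg's K, effect-size distance
#' regression and WN-vs-BM Monte Carlo power per diversity variable; the
#' family C-score matrix regressed on patristic distance; and PGLS model
#' tables (when trait predictors are given) for the variables showing signal
#' under both K and the distance regression. Stage failures are isolated per
#' family / variable and recorded, never fatal. Results are written as
#' CSV/JSON when `config$out_dir` is set.
#'
#' @param occ an `occurrence_matrix`.
#' @param meta a `site_metadata` table.
#' @param tree family phylogeny covering (at least) every family in the
#'   taxonomy, tips labeled by family.
#' @param config a [run_config()].
#' @param traits optional family-level predictor data.frame (rownames or a
#'   `family` column matching the retained families) for the PGLS stage.
#' @return object of class `divsignal_result`: `filter`,
#'   `representativeness`, `alpha`, `beta`, `responses` (merged table),
#'   `signal`, `cscore`, `pgls`, `errors`, `log`.
#' @export
run_full_analysis <- function(occ, meta, tree, config, traits = NULL) {
  stopifnot(inherits(config, "run_config"))
  errors <- list()
  note <- function(stage, msg) errors[[stage]] <<- msg
  seeds <- derive_seeds(config$seed, 6)

  filter <- filter_families(occ, config$min_plots, config$min_species)
  feats <- higher_level_features(occ, filter)
  retained <- filter$family[filter$retained]

  # representativeness: are widespread+rich families phylogenetically random?
  repres <- tryCatch({
    pool <- intersect(tree$tip.label, feats$family)
    flag <- stats::setNames(feats$widespread, feats$family)[pool]
    d_statistic(flag, ape::keep.tip(tree, pool),
                n_perm = config$n_perm_signal, seed = seeds[1])
  }, error = function(e) {
    note("representativeness", e$message)
    NULL
  })

  if (length(retained) == 0) {
    res <- structure(list(filter = filter, representativeness = repres,
                          alpha = NULL, beta = NULL, responses = NULL,
                          signal = NULL, cscore = NULL, pgls = NULL,
                          errors = errors,
                          log = list(config = unclass(config),
                                     seeds = seeds,
                                     note = "no families retained")),
                     class = "divsignal_result")
    if (!is.null(config$out_dir)) write_results(res, config$out_dir)
    return(res)
  }

  fam_seeds <- derive_seeds(seeds[2], length(retained))
  alpha_tab <- NULL
  beta_tab <- NULL
  for (i in seq_along(retained)) {
    f <- retained[i]
    a <- tryCatch(
      alpha_responses(occ, meta, f, basis_dim = config$basis_dim,
                      alpha = config$alpha),
      error = function(e) { note(paste0("alpha:", f), e$message); NULL })
    b <- tryCatch(
      turnover_responses(occ, meta, f, n_perm = config$n_perm_mrm,
                         seed = fam_seeds[i], alpha = config$alpha),
      error = function(e) { note(paste0("beta:", f), e$message); NULL })
    if (!is.null(a)) alpha_tab <- rbind(alpha_tab, a)
    if (!is.null(b)) beta_tab <- rbind(beta_tab, b)
  }
  responses <- if (!is.null(alpha_tab) && !is.null(beta_tab))
    merge(alpha_tab,
          beta_tab[, setdiff(names(beta_tab), "n_sites"), drop = FALSE],
          by = "family")
  else NULL

  signal <- NULL
  signal_tab <- NULL
  if (!is.null(responses) && nrow(responses) >= 4) {
    keep <- intersect(tree$tip.label, responses$family)
    subtree <- ape::keep.tip(tree, keep)
    patr <- patristic_matrix(subtree)
    rows <- responses[match(subtree$tip.label, responses$family), ]
    vars <- diversity_variables()
    var_seeds <- derive_seeds(seeds[3], 3 * nrow(vars))
    signal <- list()
    for (v in seq_len(nrow(vars))) {
      vn <- vars$variable[v]
      if (!vn %in% names(rows)) next
      vals <- stats::setNames(rows[[vn]], rows$family)
      se <- if (!is.na(vars$se_col[v]))
        stats::setNames(rows[[vars$se_col[v]]], rows$family) else NULL
      if (stats::sd(vals) == 0) {
        note(paste0("signal:", vn), "constant variable")
        next
      }
      signal[[vn]] <- signal_suite_one(vals, se, subtree, patr, config,
                                       var_seeds[(3 * v - 2):(3 * v)])
      k_ok <- inherits(signal[[vn]]$K, "k_result")
      dr_ok <- inherits(signal[[vn]]$distreg, "distreg_result")
      signal_tab <- rbind(signal_tab, data.frame(
        variable = vn,
        K = if (k_ok) signal[[vn]]$K$K else NA_real_,
        K_p = if (k_ok) signal[[vn]]$K$p else NA_real_,
        dist_slope = if (dr_ok) signal[[vn]]$distreg$slope else NA_real_,
        dist_R2 = if (dr_ok) signal[[vn]]$distreg$r2 else NA_real_,
        dist_p = if (dr_ok) signal[[vn]]$distreg$p else NA_real_,
        delta_obs = if (inherits(signal[[vn]]$pmc, "pmc_result"))
          signal[[vn]]$pmc$delta_obs else NA_real_,
        preferred_model = if (inherits(signal[[vn]]$pmc, "pmc_result"))
          signal[[vn]]$pmc$preferred_model else NA_character_,
        used_se = !is.na(vars$se_col[v]),
        stringsAsFactors = FALSE))
    }
  }

  cscore <- tryCatch({
    if (length(retained) >= 2 && !is.null(signal_tab)) {
      cm <- family_cscore_matrix(occ, intersect(tree$tip.label, retained))
      patr_ret <- patristic_matrix(ape::keep.tip(tree, rownames(cm)))
      list(matrix = cm,
           distreg = signal_distance_regression(
             cm, patr_ret, n_perm = config$n_perm_mrm, seed = seeds[4]))
    } else NULL
  }, error = function(e) { note("cscore", e$message); NULL })

  pgls <- NULL
  if (!is.null(traits) && !is.null(signal_tab)) {
    bearing <- signal_tab$variable[
      !is.na(signal_tab$K_p) & signal_tab$K_p < config$alpha &
      !is.na(signal_tab$dist_p) & signal_tab$dist_p < config$alpha]
    if (length(bearing)) {
      traits <- as.data.frame(traits)
      if ("family" %in% names(traits)) {
        rownames(traits) <- traits$family
        traits$family <- NULL
      }
      keep <- intersect(tree$tip.label, responses$family)
      subtree <- ape::keep.tip(tree, keep)
      rows <- responses[match(subtree$tip.label, responses$family), ]
      pgls <- list()
      for (vn in bearing) {
        y <- stats::setNames(rows[[vn]], rows$family)
        se_col <- diversity_variables()$se_col[
          diversity_variables()$variable == vn]
        w <- if (!is.na(se_col)) rows[[se_col]]^2 else NULL
        pgls[[vn]] <- tryCatch(
          model_selection(y, traits[rows$family, , drop = FALSE],
                          tree = subtree, weights = w),
          error = function(e) { note(paste0("pgls:", vn), e$message); NULL })
      }
    }
  }

  res <- structure(list(
    filter = filter, representativeness = repres,
    alpha = alpha_tab, beta = beta_tab, responses = responses,
    signal = signal, signal_table = signal_tab, cscore = cscore, pgls = pgls,
    errors = errors,
    log = list(config = unclass(config), seeds = seeds,
               retained = retained)
  ), class = "divsignal_result")
  if (!is.null(config$out_dir)) write_results(res, config$out_dir)
  res
}

# Serialize the result bundle: CSV tables + one machine-readable JSON.
write_results <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$filter, file.path(dir, "family_filter.csv"),
                   row.names = FALSE)
  if (!is.null(res$responses))
    utils::write.csv(res$responses, file.path(dir, "responses.csv"),
                     row.names = FALSE)
  if (!is.null(res$signal_table))
    utils::write.csv(res$signal_table, file.path(dir, "signal.csv"),
                     row.names = FALSE)
  cfg <- res$log$config
  cfg$out_dir <- NULL  # machine-specific path, not part of the result
  js <- list(
    config = cfg,
    retained = res$log$retained,
    representativeness = if (!is.null(res$representativeness))
      res$representativeness[c("D", "p_random", "p_brownian")] else NULL,
    signal = res$signal_table,
    pmc = lapply(res$signal, function(s)
      if (inherits(s$pmc, "pmc_result"))
        list(delta_obs = s$pmc$delta_obs, power = s$pmc$power,
             preferred_model = s$pmc$preferred_model,
             null_quantiles = unname(stats::quantile(
               s$pmc$delta_null, c(.05, .25, .5, .75, .95))),
             alt_quantiles = unname(stats::quantile(
               s$pmc$delta_alt, c(.05, .25, .5, .75, .95))),
             n_failed = s$pmc$n_failed)
      else s$pmc),
    cscore_distreg = if (!is.null(res$cscore))
      res$cscore$distreg[c("slope", "r2", "p")] else NULL,
    pgls = lapply(res$pgls, function(m)
      if (!is.null(m)) m$table[, c("predictors", "correlation", "AICc",
                                   "dAICc", "weight")] else NULL),
    errors = res$errors)
  jsonlite::write_json(js, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       dataframe = "rows")
  invisible(dir)
}

#' @export
print.divsignal_result <- function(x, ...) {
  cat("divsignal analysis:", sum(x$filter$retained), "of",
      nrow(x$filter), "families retained\n")
  if (!is.null(x$signal_table)) {
    cat("phylogenetic signal by variable:\n")
    print(x$signal_table, row.names = FALSE, digits = 3)
  }
  if (length(x$errors)) {
    cat("stage messages:\n")
    for (nm in names(x$errors)) cat("  ", nm, ": ", x$errors[[nm]], "\n",
                                    sep = "")
  }
  invisible(x)
}
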