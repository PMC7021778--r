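# Occurrence matrices, site metadata and family-level summaries.

#' Construct an occurrence matrix object
#'
#' Binary site x species incidence matrix together with a species -> family
#' taxonomy. Cells greater than zero (abundances) are coerced to presence
#' with a warning, since all downstream statistics are presence-absence.
#'
#' @param incidence numeric matrix, sites in rows, species in columns, with
#'   dimnames.
#' @param taxonomy named character vector mapping species to family.
#' @return an object of class `occurrence_matrix` with elements `incidence`,
#'   `taxonomy`, `sites`, `species`.
#' @export
occurrence_matrix <- function(incidence, taxonomy) {
  incidence <- as.matrix(incidence)
  if (is.null(rownames(incidence)) || is.null(colnames(incidence)))
    stop("incidence matrix must have site rownames and species colnames")
  if (anyDuplicated(rownames(incidence)))
    stop("duplicated site identifiers")
  if (anyDuplicated(colnames(incidence)))
    stop("duplicated species identifiers")
  if (any(!is.finite(incidence)) || any(incidence < 0))
    stop("incidence entries must be finite and non-negative")
  if (any(incidence > 1)) {
    warning("non-binary incidence values coerced to presence (1)")
    incidence[incidence > 0] <- 1
  }
  storage.mode(incidence) <- "double"
  sp <- colnames(incidence)
  missing <- setdiff(sp, names(taxonomy))
  if (length(missing))
    stop("species lacking taxonomy: ", paste(missing, collapse = ", "))
  taxonomy <- taxonomy[sp]
  structure(
    list(incidence = incidence, taxonomy = taxonomy,
         sites = rownames(incidence), species = sp),
    class = "occurrence_matrix"
  )
}

#' @export
print.occurrence_matrix <- function(x, ...) {
  cat("occurrence_matrix:", length(x$sites), "sites x", length(x$species),
      "species,", length(unique(x$taxonomy)), "families\n")
  invisible(x)
}

#' Validate site metadata
#'
#' @param meta data.frame with columns `site`, `x`, `y`, `elevation` and one
#'   or more `habitat_*` proportion columns.
#' @param sites optional character vector of site ids that must all be
#'   present.
#' @return the validated data.frame, class `site_metadata`.
#' @export
site_metadata <- function(meta, sites = NULL) {
  need <- c("site", "x", "y", "elevation")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  hab <- grep("^habitat_", names(meta), value = TRUE)
  if (anyDuplicated(meta$site)) stop("duplicated site records in metadata")
  if (any(!is.finite(meta$elevation))) stop("non-finite elevation")
  for (h in hab) {
    if (any(meta[[h]] < 0 | meta[[h]] > 1))
      stop("habitat proportions must lie in [0,1]: column ", h)
  }
  if (!is.null(sites)) {
    absent <- setdiff(sites, meta$site)
    if (length(absent))
      stop("missing site metadata for: ", paste(absent, collapse = ", "))
    meta <- meta[match(sites, meta$site), , drop = FALSE]
  }
  class(meta) <- c("site_metadata", "data.frame")
  meta
}

#' Read an occurrence matrix with taxonomy and site metadata
#'
#' Reads the three CSV/TSV inputs of a study: the site x species matrix
#' (first column the site id), the taxonomy table (`species,family`) and the
#' site metadata (`site,x,y,elevation,habitat_*`).
#'
#' @param matrix_path path to the incidence matrix file.
#' @param taxonomy_path path to the taxonomy file.
#' @param metadata_path path to the site metadata file.
#' @param sep field separator; `","` (default) or `"\t"`.
#' @param transpose set TRUE when the file stores species in rows.
#' @return list with `occ` (occurrence_matrix) and `meta` (site_metadata),
#'   sites aligned between the two.
#' @export
read_occurrence <- function(matrix_path, taxonomy_path, metadata_path,
                            sep = ",", transpose = FALSE) {
  raw <- utils::read.table(matrix_path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- as.character(raw[[1]])
  if (transpose) m <- t(m)
  tax <- utils::read.table(taxonomy_path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!all(c("species", "family") %in% names(tax)))
    stop("taxonomy file must have columns species, family")
  if (anyDuplicated(tax$species))
    stop("species mapped to more than one family: ",
         paste(unique(tax$species[duplicated(tax$species)]), collapse = ", "))
  taxonomy <- stats::setNames(tax$family, tax$species)
  occ <- occurrence_matrix(m, taxonomy)
  meta <- site_metadata(
    utils::read.table(metadata_path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE),
    sites = occ$sites
  )
  list(occ = occ, meta = meta)
}

# Per-family occupancy (sites with >= 1 member) and species richness.
family_summaries <- function(occ) {
  fams <- sort(unique(occ$taxonomy))
  n_species <- vapply(fams, function(f) sum(occ$taxonomy == f), integer(1))
  occupancy <- vapply(fams, function(f) {
    cols <- occ$incidence[, occ$taxonomy == f, drop = FALSE]
    sum(rowSums(cols) > 0)
  }, numeric(1))
  data.frame(family = fams, n_species = n_species, occupancy = occupancy,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter families by occupancy and species richness
#'
#' A family is retained when it occupies at least `min_plots` sites AND
#' contains at least `min_species` species (both thresholds inclusive).
#' Flags are returned for every family, retained or not, because the
#' representativeness test downstream needs the full set.
#'
#' @param occ an `occurrence_matrix`.
#' @param min_plots minimum number of occupied plots (default 50).
#' @param min_species minimum number of member species (default 5).
#' @return data.frame with columns `family`, `n_species`, `occupancy`,
#'   `retained`.
#' @export
filter_families <- function(occ, min_plots = 50, min_species = 5) {
  if (length(occ$species) == 0 || length(occ$sites) == 0)
    stop("empty occurrence matrix")
  tab <- family_summaries(occ)
  tab$retained <- tab$occupancy >= min_plots & tab$n_species >= min_species
  tab
}

#' Aggregate species traits to the family level
#'
#' Continuous traits are summarized as the mean and standard error over local
#' member species; columns named in `log_cols` (body size by default) are
#' natural-log-transformed before averaging. Binary (0/1) traits become
#' incidences: the fraction of member species showing the feature.
#'
#' @param species_traits data.frame with a `species` column plus trait
#'   columns (numeric continuous or 0/1 binary).
#' @param taxonomy named character vector species -> family.
#' @param families character vector of families to summarize (typically the
#'   retained set).
#' @param log_cols trait columns to log-transform before averaging.
#' @return data.frame, one row per family: `<trait>_mean`, `<trait>_se` for
#'   continuous traits, `<trait>_incidence` for binary ones, plus `n_species`.
#' @export
aggregate_family_traits <- function(species_traits, taxonomy, families,
                                    log_cols = "body_size") {
  if (!"species" %in% names(species_traits))
    stop("species_traits must have a 'species' column")
  trait_cols <- setdiff(names(species_traits), "species")
  fam_of <- taxonomy[species_traits$species]
  single <- character(0)
  rows <- lapply(families, function(f) {
    sub <- species_traits[!is.na(fam_of) & fam_of == f, , drop = FALSE]
    if (nrow(sub) == 0) stop("no trait records for family ", f)
    out <- list(family = f, n_species = nrow(sub))
    for (tc in trait_cols) {
      v <- sub[[tc]]
      is_binary <- all(v %in% c(0, 1))
      if (is_binary) {
        out[[paste0(tc, "_incidence")]] <- mean(v)
      } else {
        if (tc %in% log_cols) {
          if (any(v <= 0)) stop("non-positive values in log-transformed trait ", tc)
          v <- log(v)
        }
        out[[paste0(tc, "_mean")]] <- mean(v)
        if (length(v) == 1L) {
          single <<- union(single, f)
          out[[paste0(tc, "_se")]] <- 0
        } else {
          out[[paste0(tc, "_se")]] <- stats::sd(v) / sqrt(length(v))
        }
      }
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  if (length(single))
    warning("single-species families given SE = 0: ",
            paste(single, collapse = ", "))
  do.call(rbind, rows)
}

#' Higher-level family features: richness, occupancy, widespread flag
#'
#' Regional species richness (member-species count), occupancy (number of
#' plots with at least one member present) and the binary widespread flag
#' (retained by the family filter or not), the input to the D-statistic
#' representativeness test.
#'
#' @param occ an `occurrence_matrix`.
#' @param filter result of [filter_families()]; recomputed with defaults
#'   when omitted.
#' @return data.frame with `family`, `richness`, `occupancy`, `widespread`.
#' @export
higher_level_features <- function(occ, filter = NULL) {
  if (is.null(filter)) filter <- filter_families(occ)
  data.frame(family = filter$family,
             richness = filter$n_species,
             occupancy = filter$occupancy,
             widespread = as.integer(filter$retained),
             stringsAsFactors = FALSE)
}
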