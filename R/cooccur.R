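# Family-level co-existence: the C-score checkerboard index.

#' C-score between two occupancy vectors
#'
#' Reciprocal-distribution (checkerboard) index between two binary site
#' occupancy vectors: with R_i, R_j the occupied-site counts and S the shared
#' sites, C = (R_i - S)(R_j - S) / (R_i R_j). 0 means full sympatry
#' (identical or nested occupancies), 1 full allopatry (disjoint).
#'
#' @param occupancy_i,occupancy_j binary vectors over the same sites.
#' @return value in \[0, 1\].
#' @export
c_score <- function(occupancy_i, occupancy_j) {
  stopifnot(length(occupancy_i) == length(occupancy_j))
  oi <- as.numeric(occupancy_i > 0)
  oj <- as.numeric(occupancy_j > 0)
  ri <- sum(oi)
  rj <- sum(oj)
  if (ri == 0 || rj == 0) stop("empty occupancy vector")
  s <- sum(oi * oj)
  ((ri - s) * (rj - s)) / (ri * rj)
}

#' Pairwise C-score matrix over families
#'
#' Family occupancy is the union (OR) of its member species' occurrences;
#' C-scores are computed on those family-level vectors. The matrix feeds
#' [signal_distance_regression()] against patristic distances to ask whether
#' co-existence tracks evolutionary relatedness.
#'
#' @param occ an `occurrence_matrix`.
#' @param families families to include (>= 2), e.g. the retained set.
#' @return symmetric zero-diagonal matrix with entries in \[0, 1\].
#' @export
family_cscore_matrix <- function(occ, families) {
  if (length(families) < 2) stop("need >= 2 families")
  vecs <- vapply(families, function(f) {
    as.numeric(rowSums(occ$incidence[, occ$taxonomy == f, drop = FALSE]) > 0)
  }, numeric(length(occ$sites)))
  k <- length(families)
  out <- matrix(0, k, k, dimnames = list(families, families))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      out[i, j] <- out[j, i] <- c_score(vecs[, i], vecs[, j])
    }
  }
  out
}
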