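# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Restores the caller's `.Random.seed` afterwards so no analysis stage
#' consults (or disturbs) global RNG state.
#'
#' @param seed integer seed, or NULL to use the current RNG state.
#' @param expr expression to evaluate.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive reproducible child seeds from one master seed
#'
#' All randomness in the pipeline flows from one master seed via named
#' substreams, so removing one stage never shifts another stage's draws.
#'
#' @param seed master seed (integer).
#' @param n number of child seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1)
  with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

# Lower-triangle vectorization of a square symmetric matrix (column-major),
# the common currency of the distance-matrix regressions.
lower_vec <- function(m) m[lower.tri(m)]

# Solve with a symmetric positive-definite matrix via Cholesky; returns
# list(solve = function(b), logdet = log|A|).
chol_solver <- function(A) {
  R <- chol(A)
  list(
    solve = function(b) backsolve(R, forwardsolve(t(R), b)),
    logdet = 2 * sum(log(diag(R)))
  )
}

# Generate all permutations of 1..n (n small) as a list; used for exact
# permutation inference on <= 5 objects.
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# Match a named vector of tip values against a tree's tip labels, erroring
# on mismatch. Returns the values ordered as tree$tip.label.
align_to_tips <- function(values, tree, what = "values") {
  if (is.null(names(values)))
    stop(what, " must be named by tip label")
  missing <- setdiff(tree$tip.label, names(values))
  if (length(missing))
    stop(what, " missing for tips: ", paste(missing, collapse = ", "))
  values[tree$tip.label]
}
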