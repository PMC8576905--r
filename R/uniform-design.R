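#' Uniform experimental layouts by the good-lattice-point method
#'
#' A uniform layout \eqn{U_n(n^s)} places \eqn{n} experimental runs over
#' \eqn{s} factors so that every column is a permutation of the levels
#' \eqn{1..n} and the points scatter as uniformly as possible over the unit
#' cube. Columns are generated by the good-lattice-point (GLP) rule
#' \eqn{u_{ij} = (i \cdot h_j) \bmod N}, one column per generator \eqn{h_j}
#' coprime to the lattice modulus \eqn{N}; among all admissible column
#' subsets the constructor returns the one with minimal centered L2
#' discrepancy.
#'
#' For even \eqn{n} the layout is built from the odd \eqn{(n+1)}-run lattice
#' (modulus \eqn{N = n+1}): its final row is constant at \eqn{n+1} in every
#' column, and deleting that row leaves each column a permutation of
#' \eqn{1..n}.
#'
#' The subset search is exhaustive when the number of candidate subsets is at
#' most 2000 and otherwise greedy forward selection, both with a fixed
#' tie-break on the lowest generator index, so the construction is
#' deterministic at any scale.
#'
#' @param n_runs number of experimental runs \eqn{n} (at least 2).
#' @param n_factors number of factors \eqn{s}; at most the number of
#'   admissible GLP generators (Euler phi of the lattice modulus).
#' @return An object of class `uniform_layout`: a list with `n_runs`,
#'   `n_factors`, `matrix` (an `n_runs` x `n_factors` integer matrix, each
#'   column a permutation of `1:n_runs`), and `generators` (the chosen GLP
#'   generators).
#' @examples
#' good_lattice_layout(12, 6)
#' @export
good_lattice_layout <- function(n_runs, n_factors) {
  stopifnot(length(n_runs) == 1L, length(n_factors) == 1L)
  n_runs <- as.integer(n_runs)
  n_factors <- as.integer(n_factors)
  if (is.na(n_runs) || n_runs < 2L)
    stop("'n_runs' must be an integer >= 2", call. = FALSE)
  if (is.na(n_factors) || n_factors < 1L)
    stop("'n_factors' must be a positive integer", call. = FALSE)

  modulus <- if (n_runs %% 2L == 0L) n_runs + 1L else n_runs
  gens <- glp_generators(modulus)
  if (n_factors > length(gens))
    stop(sprintf(paste0(
      "capacity exceeded: a %d-run good-lattice layout admits at most %d ",
      "factor columns (generators coprime to %d), but %d were requested"),
      n_runs, length(gens), modulus, n_factors), call. = FALSE)

  cols <- vapply(gens, function(h) {
    u <- (seq_len(modulus) * h) %% modulus
    u[u == 0L] <- modulus
    u[seq_len(n_runs)]          # even n: drop the all-max final row
  }, integer(n_runs))

  keep <- select_columns(cols, n_factors, n_runs)
  structure(
    list(n_runs = n_runs, n_factors = n_factors,
         matrix = cols[, keep, drop = FALSE],
         generators = gens[keep]),
    class = "uniform_layout")
}

glp_generators <- function(m) {
  h <- seq_len(m - 1L)
  h[vapply(h, function(x) gcd2(x, m) == 1L, logical(1L))]
}

gcd2 <- function(a, b) {
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  a
}

# Choose s of the candidate GLP columns minimizing centered L2 discrepancy.
# Exhaustive for <= 2000 subsets, greedy forward selection beyond; ties go to
# the lexicographically smallest generator-index set.
select_columns <- function(cols, s, n_runs) {
  k <- ncol(cols)
  if (s == k) return(seq_len(k))
  x <- (cols - 0.5) / n_runs
  terms <- cd2_terms(x)
  n_subsets <- choose(k, s)
  if (n_subsets <= 2000) {
    subsets <- utils::combn(k, s)
    scores <- apply(subsets, 2L, function(j) cd2_from_terms(terms, j))
    subsets[, which.min(scores)]   # which.min: first minimum = lowest indices
  } else {
    chosen <- integer(0)
    for (step in seq_len(s)) {
      rest <- setdiff(seq_len(k), chosen)
      sc <- vapply(rest, function(j) cd2_from_terms(terms, c(chosen, j)),
                   numeric(1L))
      chosen <- c(chosen, rest[which.min(sc)])
    }
    sort(chosen)
  }
}

# Per-column pieces of Hickernell's centered L2 discrepancy for points x in
# [0,1]^s:
#   CD2^2 = (13/12)^s - (2/n) sum_i prod_j a_ij + (1/n^2) sum_il prod_j b_ilj
# with a_ij = 1 + |x_ij - .5|/2 - |x_ij - .5|^2/2 and
# b_ilj = 1 + (|x_ij - .5| + |x_lj - .5| - |x_ij - x_lj|)/2.
cd2_terms <- function(x) {
  n <- nrow(x)
  a <- array(0, dim(x)); b <- array(0, c(n, n, ncol(x)))
  for (j in seq_len(ncol(x))) {
    d <- abs(x[, j] - 0.5)
    a[, j] <- 1 + d / 2 - d^2 / 2
    b[, , j] <- 1 + (outer(d, d, `+`) - abs(outer(x[, j], x[, j], `-`))) / 2
  }
  list(a = a, b = b, n = n)
}

cd2_from_terms <- function(terms, j) {
  n <- terms$n
  ap <- apply(terms$a[, j, drop = FALSE], 1L, prod)
  bp <- apply(terms$b[, , j, drop = FALSE], c(1L, 2L), prod)
  val2 <- (13 / 12)^length(j) - (2 / n) * sum(ap) + sum(bp) / n^2
  sqrt(max(val2, 0))
}

#' Collapse a uniform layout onto fewer levels per factor
#'
#' Pseudo-level collapsing maps level \eqn{\ell} of an \eqn{n}-level column
#' onto \eqn{\lceil \ell m / n \rceil} of \eqn{m} target levels; when
#' \eqn{m} divides \eqn{n} every collapsed level appears exactly \eqn{n/m}
#' times, producing a balanced mixed-level design.
#'
#' @param layout a `uniform_layout`.
#' @param target_levels integer vector of target level counts \eqn{m_j}, one
#'   per factor; each must divide `layout$n_runs`.
#' @param factor_names optional column labels (default `X1..Xs`).
#' @return An object of class `mixed_level_design`: a list with `n_runs`,
#'   `levels_per_factor`, `matrix` (column `j` has entries in `1:m_j`), and
#'   `factor_names`.
#' @export
collapse_levels <- function(layout, target_levels, factor_names = NULL) {
  stopifnot(inherits(layout, "uniform_layout"))
  target_levels <- as.integer(target_levels)
  if (length(target_levels) != layout$n_factors)
    stop("'target_levels' must have one entry per factor", call. = FALSE)
  bad <- which(layout$n_runs %% target_levels != 0L | target_levels < 1L)
  if (length(bad))
    stop(sprintf(
      "target level count %d for column %d does not divide n_runs = %d",
      target_levels[bad[1L]], bad[1L], layout$n_runs), call. = FALSE)
  m <- layout$matrix
  for (j in seq_len(ncol(m)))
    m[, j] <- ceiling(m[, j] * target_levels[j] / layout$n_runs)
  mixed_level_design(m, target_levels, factor_names)
}

mixed_level_design <- function(matrix, levels_per_factor,
                               factor_names = NULL) {
  if (is.null(factor_names)) factor_names <- paste0("X", seq_len(ncol(matrix)))
  storage.mode(matrix) <- "integer"
  dimnames(matrix) <- NULL
  d <- structure(
    list(n_runs = nrow(matrix),
         levels_per_factor = as.integer(levels_per_factor),
         matrix = matrix, factor_names = factor_names),
    class = "mixed_level_design")
  validate_mixed_design(d)
  d
}

validate_mixed_design <- function(d) {
  for (j in seq_along(d$levels_per_factor)) {
    m <- d$levels_per_factor[j]
    cnt <- tabulate(d$matrix[, j], nbins = m)
    if (any(d$matrix[, j] < 1L | d$matrix[, j] > m))
      stop(sprintf("column %d has entries outside 1..%d", j, m),
           call. = FALSE)
    if (d$n_runs %% m == 0L && any(cnt != d$n_runs %/% m))
      stop(sprintf("column %d is not balanced (%s)", j,
                   paste(cnt, collapse = ",")), call. = FALSE)
  }
  invisible(d)
}

#' Centered L2 discrepancy of a design
#'
#' Hickernell's closed-form centered L2 discrepancy of the design points
#' mapped to the unit cube via \eqn{x = (\ell - 0.5)/m} (level \eqn{\ell} of
#' \eqn{m}). Lower values mean a more uniform scatter; the value is invariant
#' under row reordering.
#'
#' @param design a `uniform_layout` or `mixed_level_design`.
#' @return The non-negative discrepancy value.
#' @export
centered_l2_discrepancy <- function(design) {
  if (inherits(design, "uniform_layout")) {
    x <- (design$matrix - 0.5) / design$n_runs
  } else if (inherits(design, "mixed_level_design")) {
    x <- sweep(design$matrix - 0.5, 2L, design$levels_per_factor, `/`)
  } else stop("unsupported design object", call. = FALSE)
  if (nrow(x) == 0L) stop("empty design", call. = FALSE)
  terms <- cd2_terms(x)
  cd2_from_terms(terms, seq_len(ncol(x)))
}

#' The canonical 12-run, 6-factor mixed-level reference design
#'
#' The fixed \eqn{U_{12}(12^6)}-derived mixed-level layout used by the
#' reference OCT tuning experiment this package reproduces: 12 runs over the
#' six residual-network hyperparameters X1..X6 with 2, 2, 4, 2, 4 and 2
#' levels. Shipped as a verbatim fixture (level indices); realize it against
#' [default_space()] to obtain concrete hyperparameter values.
#'
#' @return A `mixed_level_design` with 12 runs and 6 factors.
#' @examples
#' d <- reference_design()
#' realize(d, default_space())[[4]]
#' @export
reference_design <- function() {
  m <- matrix(c(
    # X1 X2 X3 X4 X5 X6   (level indices)
    1L, 2L, 2L, 2L, 1L, 2L,
    2L, 2L, 4L, 1L, 1L, 1L,
    1L, 2L, 1L, 1L, 1L, 2L,
    2L, 2L, 3L, 2L, 2L, 1L,
    1L, 2L, 4L, 1L, 2L, 1L,
    2L, 2L, 2L, 1L, 2L, 2L,
    1L, 1L, 3L, 2L, 3L, 1L,
    2L, 1L, 1L, 2L, 3L, 2L,
    1L, 1L, 2L, 1L, 3L, 2L,
    2L, 1L, 4L, 2L, 4L, 1L,
    1L, 1L, 1L, 2L, 4L, 2L,
    2L, 1L, 3L, 1L, 4L, 1L), nrow = 12L, byrow = TRUE)
  mixed_level_design(m, c(2L, 2L, 4L, 2L, 4L, 2L))
}

#' Write / read a design as CSV
#'
#' Designs are written with header `run,X1,...,Xs` and 1-based integer level
#' indices, one row per run (comma-separated, UTF-8, Unix newlines), so the
#' files diff bit-exactly. With `space` given, a "realized" CSV with concrete
#' level values is written instead.
#'
#' @param design a `mixed_level_design` (or `uniform_layout`, written with
#'   `m_j = n` levels).
#' @param path output file.
#' @param space optional list of [factor_spec()]s; when supplied the cells
#'   hold realized level values rather than indices.
#' @return `path`, invisibly.
#' @export
write_design_csv <- function(design, path, space = NULL) {
  if (inherits(design, "uniform_layout"))
    design <- mixed_level_design(design$matrix,
                                 rep(design$n_runs, design$n_factors))
  m <- design$matrix
  cells <- if (is.null(space)) {
    apply(m, 1L, function(r) paste(r, collapse = ","))
  } else {
    stopifnot(length(space) == ncol(m))
    apply(m, 1L, function(r) paste(
      vapply(seq_along(r), function(j) as.character(space[[j]]$levels[r[j]]),
             character(1L)), collapse = ","))
  }
  lines <- c(paste(c("run", design$factor_names), collapse = ","),
             paste(seq_len(nrow(m)), cells, sep = ","))
  writeLines(lines, path, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_design_csv
#' @param levels_per_factor level counts for the columns being read; defaults
#'   to the per-column maxima.
#' @export
read_design_csv <- function(path, levels_per_factor = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  if (is.null(levels_per_factor))
    levels_per_factor <- apply(m, 2L, max)
  nm <- colnames(m)
  dimnames(m) <- NULL
  mixed_level_design(m, levels_per_factor, factor_names = nm)
}

#' @export
print.uniform_layout <- function(x, ...) {
  cat(sprintf("Uniform layout U_%d(%d^%d), GLP generators: %s\n",
              x$n_runs, x$n_runs, x$n_factors,
              paste(x$generators, collapse = " ")))
  print(x$matrix)
  invisible(x)
}

#' @export
print.mixed_level_design <- function(x, ...) {
  cat(sprintf("Mixed-level design: %d runs, levels (%s)\n", x$n_runs,
              paste(x$levels_per_factor, collapse = ",")))
  m <- x$matrix
  dimnames(m) <- list(seq_len(nrow(m)), x$factor_names)
  print(m)
  invisible(x)
}
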