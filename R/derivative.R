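#' First-derivative operator for a sampled time course
#'
#' Builds the square matrix `A` (units 1/hour) that estimates the first
#' derivative of a series sampled on `grid` from the sampled values
#' themselves. Row 1 is identically zero: the net rate of change of every
#' transcript is taken to be nil at time zero, when the stimulus is applied.
#' Every other row is a finite-difference stencil whose weights sum to zero,
#' so the operator annihilates constants.
#'
#' For the default 7-point expression grid (0 to 21 h, 3.5 h spacing) the
#' operator is a fixed rational-valued matrix: rows 4, 5 and 7 are the
#' standard 5-point central and 3-point backward stencils at spacing 3.5 h,
#' while rows 2 and 3 are smoothed early-time estimators (they trade exactness
#' on linear trends for noise damping near the stimulus). For any other grid
#' the weights are generated as Lagrange-interpolation derivative stencils
#' over a local window of up to 5 nodes, which handles unequal spacing.
#'
#' @param grid A [time_grid()] with at least 3 points.
#' @return An object of class `gwtm_derivop`: list with `matrix` (n x n) and
#'   `grid`.
#' @examples
#' A <- build_derivative_operator(expression_grid())
#' rowSums(A$matrix)       # all (numerically) zero
#' A$matrix %*% rep(1, 7)  # annihilates constants
#' @export
build_derivative_operator <- function(grid) {
  if (!inherits(grid, "gwtm_grid")) stop("grid must be a gwtm_grid")
  n <- length(grid)
  if (n < 3L) stop("derivative operator needs at least 3 grid points")
  t <- as.numeric(grid)
  if (any(diff(t) <= 0)) stop("grid times must be strictly increasing")
  if (n == 7L && isTRUE(all.equal(t, seq(0, 21, by = 3.5)))) {
    A <- default_expression_operator()
  } else {
    A <- matrix(0, n, n)
    for (i in 2:n) {
      lo <- max(1L, i - 2L)
      hi <- min(n, i + 2L)
      if (hi - lo + 1L < 3L) {  # widen window at short grids
        lo <- max(1L, hi - 2L)
        hi <- min(n, lo + 2L)
      }
      idx <- lo:hi
      A[i, idx] <- lagrange_derivative_weights(t[idx], t[i])
    }
  }
  rs <- rowSums(A)
  if (any(abs(rs) >= 1e-12)) {
    stop("internal error: derivative operator rows do not sum to zero")
  }
  structure(list(matrix = A, grid = grid), class = "gwtm_derivop")
}

# Weights w such that sum_j w_j y(t_j) ~ y'(x0): derivative of the Lagrange
# interpolating polynomial through the nodes, evaluated at x0 (a node).
lagrange_derivative_weights <- function(nodes, x0) {
  m <- length(nodes)
  w <- numeric(m)
  for (j in seq_len(m)) {
    denom <- prod(nodes[j] - nodes[-j])
    s <- 0
    for (k in seq_len(m)[-j]) {
      s <- s + prod(x0 - nodes[-c(j, k)])
    }
    w[j] <- s / denom
  }
  w
}

# Fixed operator for 7 equally spaced points, 0..21 h. Exact rationals.
default_expression_operator <- function() {
  matrix(c(
    0,        0,      0,     0,      0,     0,     0,
    -17/63,   1/7,    1/7,  -1/63,   0,     0,     0,
    31/252,  -8/21,   1/7,   8/63,  -1/84,  0,     0,
    0,        1/42,  -4/21,  0,      4/21, -1/42,  0,
    0,        0,      1/42, -4/21,   0,     4/21, -1/42,
    0,        0,      0,     1/21,  -2/7,   1/7,   2/21,
    0,        0,      0,     0,      1/7,  -4/7,   3/7
  ), nrow = 7, byrow = TRUE)
}

#' @export
print.gwtm_derivop <- function(x, ...) {
  cat(sprintf("<gwtm_derivop: %d x %d on %s grid>\n",
              nrow(x$matrix), ncol(x$matrix), grid_label(x$grid)))
  invisible(x)
}

#' Export a derivative operator as TSV for inspection
#'
#' @param op A [build_derivative_operator()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_derivative_operator <- function(op, path) {
  stopifnot(inherits(op, "gwtm_derivop"))
  utils::write.table(op$matrix, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = format_grid_times(op$grid))
  invisible(path)
}
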