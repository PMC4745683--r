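#' Per-transcript kinetic parameters
#'
#' The discrete kinetic model describes each transcript's concentration x(t)
#' by dx/dt = B + S f(t) - D x: basal production `B` (intensity/hour),
#' sensitivity `S` (intensity/hour) to a shared regulator activity f, and
#' first-order degradation `D` (1/hour). `x_d0` is the fitted initial level
#' of the transcription-shutoff (degradation) series.
#'
#' @param B Basal production rate, >= 0.
#' @param S Sensitivity to the shared activity, >= 0.
#' @param D Degradation rate, >= 0 (must be > 0 for the expression model).
#' @param x_d0 Initial level of the degradation series, >= 0 (default `NA`
#'   until fitted).
#' @param d_max Upper bound on D enforced at construction (1/hour).
#' @return Object of class `gwtm_params`.
#' @export
kinetic_params <- function(B, S, D, x_d0 = NA_real_, d_max = 5) {
  vals <- c(B = B, S = S, D = D)
  if (anyNA(vals) || any(!is.finite(vals))) stop("B, S, D must be finite")
  if (any(vals < 0)) stop("B, S, D must be non-negative")
  if (D > d_max) stop("D = ", D, " exceeds the configured bound ", d_max, "/h")
  if (!is.na(x_d0) && x_d0 < 0) stop("x_d0 must be non-negative")
  structure(list(B = B, S = S, D = D, x_d0 = x_d0), class = "gwtm_params")
}

#' Shared regulator activity profile
#'
#' A hidden, dimensionless activity f over the expression grid, shared by
#' co-regulated transcripts. Convention: f(0) = 0 (no activity before the
#' stimulus) and max f = 1 (scale is absorbed into each transcript's S).
#'
#' @param f Numeric vector of activity values, one per expression grid time.
#' @param grid The expression [time_grid()].
#' @param normalize If `TRUE` (default) rescale so the maximum is 1; a flat
#'   zero profile is left as is.
#' @return Object of class `gwtm_activity`: numeric vector with `grid`
#'   attribute.
#' @export
activity_profile <- function(f, grid, normalize = TRUE) {
  f <- as.numeric(f)
  if (length(f) != length(grid)) stop("f length must match grid")
  if (anyNA(f) || any(!is.finite(f))) stop("f must be finite")
  if (any(f < 0)) stop("f must be non-negative")
  if (f[1L] != 0) stop("f(0) must be 0 (pre-stimulus activity convention)")
  if (normalize && max(f) > 0) f <- f / max(f)
  structure(f, grid = grid, class = "gwtm_activity")
}

#' Predict an expression time course from the kinetic model
#'
#' Solves the discrete model (A + D I) x = B 1 + S f for the transcript
#' concentration series x on the expression grid, where A is the derivative
#' operator. Because row 1 of A is zero, x(0) = B / D exactly: the transcript
#' starts at its pre-stimulus steady state.
#'
#' @param params A [kinetic_params()] with D > 0.
#' @param f An [activity_profile()] on the operator's grid.
#' @param op A [build_derivative_operator()] result.
#' @return Numeric vector of intensities on the expression grid.
#' @export
predict_expression <- function(params, f, op) {
  stopifnot(inherits(params, "gwtm_params"), inherits(op, "gwtm_derivop"))
  n <- nrow(op$matrix)
  if (length(f) != n) stop("f length must match operator grid")
  if (params$D <= 0) {
    stop("D must be > 0: with D = 0 the system (A + D I) is singular ",
         "because the operator annihilates constants")
  }
  M <- op$matrix + diag(params$D, n)
  rhs <- params$B + params$S * as.numeric(f)
  sol <- tryCatch(solve(M, rhs), error = function(e) {
    stop("singular kinetic system (D = ", params$D, "): ",
         conditionMessage(e))
  })
  as.numeric(sol)
}

#' Predict a transcription-shutoff (degradation) time course
#'
#' After transcription arrest, production ceases and the transcript decays
#' exponentially: x_d(t) = x_d0 exp(-D t). The degradation grid is unequally
#' spaced, so the continuous closed form is used rather than a discrete
#' operator.
#'
#' @param params A [kinetic_params()] with `x_d0` set (or pass `x_d0`).
#' @param grid The degradation [time_grid()] (starts at 0).
#' @param x_d0 Optional override for the initial level.
#' @return Numeric vector of intensities on the degradation grid.
#' @export
predict_degradation <- function(params, grid, x_d0 = NULL) {
  stopifnot(inherits(params, "gwtm_params"))
  if (params$D < 0) stop("D must be non-negative")
  x0 <- if (is.null(x_d0)) params$x_d0 else x_d0
  if (is.na(x0)) stop("x_d0 is not set")
  x0 * exp(-params$D * as.numeric(grid))
}

#' Compound production profile
#'
#' The compound production G(t) = dx/dt + D x estimates, from a measured (or
#' predicted) series, the total production rate feeding the transcript. Under
#' the kinetic model G = B + S f: an affine transform of the hidden regulator
#' activity, which makes G the natural quantity for visualising and
#' comparing transcriptional activities across genes with different decay
#' rates.
#'
#' @param x Numeric intensity series on the operator's grid.
#' @param D Degradation rate (1/hour), >= 0.
#' @param op A [build_derivative_operator()] result.
#' @return Object of class `gwtm_gprofile`: numeric vector (intensity/hour)
#'   on the expression grid.
#' @export
compound_production <- function(x, D, op) {
  stopifnot(inherits(op, "gwtm_derivop"))
  x <- as.numeric(x)
  if (length(x) != nrow(op$matrix)) {
    stop("series length ", length(x), " does not match operator size ",
         nrow(op$matrix))
  }
  if (D < 0) stop("D must be non-negative")
  g <- as.numeric(op$matrix %*% x) + D * x
  structure(g, grid = op$grid, class = "gwtm_gprofile")
}
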