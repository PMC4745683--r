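#' Empirical decay-rate estimate from a shutoff series
#'
#' Ordinary least squares of log(x) on time; the decay rate is the negated
#' slope, clamped at zero (a transcript cannot have a negative decay rate;
#' an increasing series yields 0). Closed-form and robust at 4 points; used
#' for initialization and QC, since pair fitting re-estimates D.
#'
#' @param series Numeric intensity series, all values > 0.
#' @param grid The degradation [time_grid()].
#' @return List with `D_hat` (1/hour), `r2` (fit quality in log space) and
#'   `ok` (`FALSE` when the series contains non-positive values, in which
#'   case `D_hat` is `NA` and the gene should be excluded downstream).
#' @export
estimate_decay_rate <- function(series, grid) {
  series <- as.numeric(series)
  t <- as.numeric(grid)
  if (length(series) != length(t)) stop("series length must match grid")
  if (any(!is.finite(series)) || any(series <= 0)) {
    return(list(D_hat = NA_real_, r2 = NA_real_, ok = FALSE))
  }
  y <- log(series)
  fit <- stats::lm.fit(cbind(1, t), y)
  slope <- fit$coefficients[2L]
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  list(D_hat = max(0, -slope), r2 = max(0, min(1, r2)), ok = TRUE)
}

#' Normalize transcription-shutoff arrays against a stable gene set
#'
#' After transcription arrest the total RNA pool shrinks, so per-array
#' total-intensity normalization would bias decay rates downward. Instead,
#' the arrays are rescaled iteratively against the genes that decay least:
#' (1) scale each array by the current factors; (2) fit a per-gene
#' log-linear decay; (3) take the slowest-decaying quartile as the stable
#' reference set; (4) re-estimate each array's factor so the stable set's
#' median log-ratio to the t = 0 array is zero. Iterate to a fixed point.
#' The t = 0 array's factor is pinned at 1. Deterministic given the input.
#'
#' @param raw A degradation [time_course_matrix()] (>= 2 arrays, >= 20
#'   genes). All-zero or non-positive gene rows are dropped with a warning.
#' @param max_iter Maximum iterations (default 50).
#' @param tol Convergence tolerance on the relative change of any factor
#'   (default 1e-3).
#' @param stable_frac Fraction of genes taken as the stable set (default
#'   0.25, the slowest-decaying quartile).
#' @return List of class `gwtm_degnorm`: `normalized` (a `gwtm_tcm`),
#'   `scale_factors` (one per array, first = 1), `stable_set` (gene ids),
#'   `iterations`, `converged`.
#' @export
normalize_degradation_arrays <- function(raw, max_iter = 50L, tol = 1e-3,
                                         stable_frac = 0.25) {
  stopifnot(inherits(raw, "gwtm_tcm"))
  n_arr <- ncol(raw$values)
  if (n_arr < 2L) stop("need at least 2 arrays to normalize")
  pos <- apply(raw$values, 1L, function(v) all(v > 0))
  if (any(!pos)) {
    warning(sum(!pos), " gene(s) with non-positive values dropped ",
            "from normalization")
  }
  vals <- raw$values[pos, , drop = FALSE]
  if (nrow(vals) < 20L) stop("need at least 20 usable genes, have ", nrow(vals))
  t <- as.numeric(raw$grid)
  n_stable <- max(2L, ceiling(stable_frac * nrow(vals)))

  factors <- rep(1, n_arr)
  converged <- FALSE
  iter <- 0L
  stable <- character(0)
  logv <- log(vals)
  X <- cbind(1, t)
  for (iter in seq_len(max_iter)) {
    scaled_log <- sweep(logv, 2L, log(factors), `+`)
    # per-gene log-linear slope, vectorized across genes
    slopes <- stats::lm.fit(X, t(scaled_log))$coefficients[2L, ]
    d_hat <- pmax(0, -slopes)
    ord <- order(d_hat, rownames(vals))  # id tie-break for determinism
    stable <- rownames(vals)[ord[seq_len(n_stable)]]
    srows <- scaled_log[stable, , drop = FALSE]
    delta <- apply(srows, 2L, function(col) stats::median(col - srows[, 1L]))
    new_factors <- unname(factors * exp(-delta))
    new_factors <- new_factors / new_factors[1L]  # pin t = 0 at 1
    change <- max(abs(new_factors - factors) / factors)
    factors <- new_factors
    if (change < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("degradation normalization did not converge in ", max_iter,
            " iterations; returning last iterate")
  }
  norm_vals <- sweep(raw$values[pos, , drop = FALSE], 2L, factors, `*`)
  normalized <- time_course_matrix(norm_vals, raw$grid,
                                   gene_ids = rownames(vals))
  structure(list(normalized = normalized, scale_factors = factors,
                 stable_set = stable, iterations = iter,
                 converged = converged),
            class = "gwtm_degnorm")
}

#' Decay census: transcripts passing a fold-decay threshold per time point
#'
#' For each time point after shutoff, counts the genes whose level has
#' fallen by more than `fold` relative to the t = 0 array (vs-baseline
#' census) and relative to the previous array (transition census). Genes
#' with a zero denominator at a time point are excluded there with a
#' warning.
#'
#' @param deg A degradation [time_course_matrix()].
#' @param fold Fold threshold > 1 (default 1.5); strict inequality.
#' @return Data frame with columns `time`, `vs_baseline`, `vs_previous`
#'   (counts; the t = 0 row is 0 by construction).
#' @export
decay_census <- function(deg, fold = 1.5) {
  stopifnot(inherits(deg, "gwtm_tcm"))
  if (fold <= 1) stop("fold must be > 1")
  v <- deg$values
  t <- as.numeric(deg$grid)
  n_t <- length(t)
  vs_base <- integer(n_t)
  vs_prev <- integer(n_t)
  warned <- FALSE
  for (j in 2:n_t) {
    ok_b <- v[, j] > 0 & v[, 1L] > 0
    ok_p <- v[, j] > 0 & v[, j - 1L] > 0
    if (any(!ok_b) || any(!ok_p)) warned <- TRUE
    vs_base[j] <- sum(v[ok_b, 1L] / v[ok_b, j] > fold)
    vs_prev[j] <- sum(v[ok_p, j - 1L] / v[ok_p, j] > fold)
  }
  if (warned) warning("genes with zero values excluded from decay census")
  data.frame(time = t, vs_baseline = vs_base, vs_previous = vs_prev)
}
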