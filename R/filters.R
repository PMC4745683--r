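#' Expression range of a series
#'
#' Max minus min of a series, in the (non-log) intensity units of the
#' matrix. Used as a minimum-variation filter before modelling.
#'
#' @param series Non-empty numeric series.
#' @return The range (max - min), a single number in intensity units.
#' @export
expression_range <- function(series) {
  series <- as.numeric(series)
  if (length(series) == 0L) stop("series is empty")
  max(series) - min(series)
}

#' Select up-regulated genes for kinetic modelling
#'
#' A gene enters the modelling set iff all three rules hold:
#' \enumerate{
#'   \item range rule: `max(x) - min(x) >= range_min`;
#'   \item up-regulation rule: `max_t x(t) / x(0) > up_fold` (strict) at
#'     some time point;
#'   \item floor rule: `min_t x(t) >= floor_frac * x(0)` — never
#'     substantially below the starting level, excluding genes that are
#'     also down-regulated.
#' }
#' Genes with `x(0) <= 0` are excluded with a reason.
#'
#' @param expr An expression [time_course_matrix()].
#' @param range_min Minimum range in intensity units (default 1.5).
#' @param up_fold Fold threshold for up-regulation, strict (default 1.5,
#'   i.e. up by more than 50 percent).
#' @param floor_frac Allowed floor as a fraction of the t = 0 level
#'   (default 0.1).
#' @return A `gwtm_filter` report: `selected` (gene ids), `excluded` (gene
#'   ids), `reasons` (named character, first failed rule per excluded
#'   gene), `thresholds`.
#' @export
select_upregulated <- function(expr, range_min = 1.5, up_fold = 1.5,
                               floor_frac = 0.1) {
  stopifnot(inherits(expr, "gwtm_tcm"))
  v <- expr$values
  reasons <- character(0)
  sel <- logical(nrow(v))
  for (i in seq_len(nrow(v))) {
    id <- expr$gene_ids[i]
    x <- v[i, ]
    if (x[1L] <= 0) {
      reasons[id] <- "nonpositive_baseline"
    } else if (max(x) - min(x) < range_min) {
      reasons[id] <- "range_below_min"
    } else if (!(max(x) / x[1L] > up_fold)) {
      reasons[id] <- "not_upregulated"
    } else if (min(x) < floor_frac * x[1L]) {
      reasons[id] <- "below_floor"
    } else {
      sel[i] <- TRUE
    }
  }
  filter_report(expr$gene_ids[sel], reasons,
                list(range_min = range_min, up_fold = up_fold,
                     floor_frac = floor_frac))
}

#' Select down-regulated genes
#'
#' A gene is down-regulated iff it falls to `1/down_fold` of its starting
#' level or lower at one or more time points (inclusive threshold: "at
#' least" `down_fold`-fold down).
#'
#' @param expr An expression [time_course_matrix()].
#' @param down_fold Fold threshold, inclusive (default 1.5).
#' @return A `gwtm_filter` report (see [select_upregulated()]).
#' @export
select_downregulated <- function(expr, down_fold = 1.5) {
  stopifnot(inherits(expr, "gwtm_tcm"))
  v <- expr$values
  reasons <- character(0)
  sel <- logical(nrow(v))
  for (i in seq_len(nrow(v))) {
    id <- expr$gene_ids[i]
    x <- v[i, ]
    if (x[1L] <= 0) {
      reasons[id] <- "nonpositive_baseline"
    } else if (min(x) / x[1L] <= 1 / down_fold) {
      sel[i] <- TRUE
    } else {
      reasons[id] <- "not_downregulated"
    }
  }
  filter_report(expr$gene_ids[sel], reasons, list(down_fold = down_fold))
}

filter_report <- function(selected, reasons, thresholds) {
  structure(list(selected = selected, excluded = names(reasons),
                 reasons = reasons, thresholds = thresholds),
            class = "gwtm_filter")
}

#' @export
print.gwtm_filter <- function(x, ...) {
  cat(sprintf("<gwtm_filter: %d selected, %d excluded>\n",
              length(x$selected), length(x$excluded)))
  invisible(x)
}

#' Fold-change census over a time course
#'
#' For each time point, counts the genes whose level changed by strictly
#' more than `fold` up or down, both relative to the t = 0 point
#' (vs-baseline) and relative to the previous point (transition). Genes
#' with a zero denominator at a comparison are excluded there with a
#' warning.
#'
#' @param expr An expression [time_course_matrix()].
#' @param fold Fold threshold > 1 (default 2); strict inequality.
#' @return Data frame with columns `time`, `up_vs_baseline`,
#'   `down_vs_baseline`, `up_vs_previous`, `down_vs_previous`.
#' @export
fold_change_census <- function(expr, fold = 2) {
  stopifnot(inherits(expr, "gwtm_tcm"))
  if (fold <= 1) stop("fold must be > 1")
  v <- expr$values
  t <- as.numeric(expr$grid)
  n_t <- length(t)
  up_b <- down_b <- up_p <- down_p <- integer(n_t)
  warned <- FALSE
  for (j in 2:n_t) {
    ok_b <- v[, 1L] > 0
    ok_p <- v[, j - 1L] > 0
    if (any(!ok_b) || any(!ok_p)) warned <- TRUE
    rb <- v[ok_b, j] / v[ok_b, 1L]
    rp <- v[ok_p, j] / v[ok_p, j - 1L]
    up_b[j] <- sum(rb > fold)
    down_b[j] <- sum(rb < 1 / fold)
    up_p[j] <- sum(rp > fold)
    down_p[j] <- sum(rp < 1 / fold)
  }
  if (warned) warning("genes with zero baseline excluded from census")
  data.frame(time = t, up_vs_baseline = up_b, down_vs_baseline = down_b,
             up_vs_previous = up_p, down_vs_previous = down_p)
}
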