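#' Time grid for a sampled series
#'
#' A `gwtm_grid` holds the ordered observation times (hours) of either an
#' expression time course (time from stimulus) or a degradation time course
#' (time from transcription arrest). Times must start at 0 and be strictly
#' increasing.
#'
#' @param times Numeric vector of observation times in hours.
#' @param label Either `"expression"` or `"degradation"`.
#' @return An object of class `gwtm_grid`: a numeric vector with a `label`
#'   attribute.
#' @examples
#' expression_grid()
#' time_grid(c(0, 1, 2, 5.5), "degradation")
#' @export
time_grid <- function(times, label = c("expression", "degradation")) {
  label <- match.arg(label)
  times <- as.numeric(times)
  if (length(times) < 2L) {
    stop("a time grid needs at least 2 points")
  }
  if (anyNA(times) || any(!is.finite(times))) {
    stop("grid times must be finite")
  }
  if (times[1L] != 0) {
    stop("grid must start at time 0, got ", times[1L])
  }
  if (any(diff(times) <= 0)) {
    stop("grid times must be strictly increasing")
  }
  structure(times, label = label, class = "gwtm_grid")
}

#' @rdname time_grid
#' @details `expression_grid()` returns the default 7-point expression grid
#'   (0 to 21 h in 3.5 h steps); `degradation_grid()` returns the default
#'   4-point transcription-shutoff grid (0, 1, 2, 5.5 h after arrest).
#' @export
expression_grid <- function() {
  time_grid(seq(0, 21, by = 3.5), "expression")
}

#' @rdname time_grid
#' @export
degradation_grid <- function() {
  time_grid(c(0, 1, 2, 5.5), "degradation")
}

#' @export
print.gwtm_grid <- function(x, ...) {
  cat(sprintf("<gwtm_grid: %s, %d points: %s h>\n",
              attr(x, "label"), length(x),
              paste(format(unclass(x)), collapse = ", ")))
  invisible(x)
}

grid_label <- function(grid) attr(grid, "label")
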