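#' Gene-by-time matrix of non-log intensities
#'
#' The central data container: a genes x time-points matrix of non-log
#' normalized intensities together with a per-entry standard deviation and
#' the time grid. Intensities are linear-scale (the kinetic model is linear
#' in concentration, not log concentration); any log-scale input must be
#' exponentiated before construction.
#'
#' @param values Numeric matrix, genes in rows, time points in columns, all
#'   entries finite and non-negative. Row names are the gene identifiers.
#' @param grid A [time_grid()] whose length equals `ncol(values)`.
#' @param sd Optional matrix of per-entry standard deviations (same shape as
#'   `values`, all entries strictly positive). If `NULL`, filled from the
#'   intensity error model `sd = a + b * value` (see [sd_error_model()]).
#' @param gene_ids Optional character vector of gene identifiers; defaults to
#'   `rownames(values)`. Must be unique.
#' @param sd_a,sd_b Error-model coefficients used when `sd` is `NULL`:
#'   additive floor `a` (intensity units) and proportional term `b`
#'   (coefficient of variation).
#' @return An object of class `gwtm_tcm` with components `values`, `sd`,
#'   `grid`, `gene_ids`.
#' @seealso [read_time_course()], [write_time_course()]
#' @export
time_course_matrix <- function(values, grid, sd = NULL, gene_ids = NULL,
                               sd_a = 1, sd_b = 0.1) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- rownames(values)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != nrow(values)) {
    stop("gene_ids length does not match row count")
  }
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup) > 0L) {
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  }
  if (!inherits(grid, "gwtm_grid")) stop("grid must be a gwtm_grid")
  if (ncol(values) != length(grid)) {
    stop("matrix has ", ncol(values), " columns but grid has ",
         length(grid), " time points")
  }
  if (nrow(values) > 0L && (anyNA(values) || any(!is.finite(values)))) {
    stop("values must be finite")
  }
  if (nrow(values) > 0L && any(values < 0)) stop("values must be non-negative")
  if (is.null(sd)) {
    sd <- sd_error_model(values, a = sd_a, b = sd_b)
  }
  sd <- as.matrix(sd)
  storage.mode(sd) <- "double"
  if (!all(dim(sd) == dim(values))) stop("sd shape does not match values")
  if (nrow(sd) > 0L && any(!is.finite(sd) | sd <= 0)) {
    stop("sd entries must be strictly positive and finite")
  }
  rownames(values) <- gene_ids
  rownames(sd) <- gene_ids
  colnames(values) <- colnames(sd) <- format_grid_times(grid)
  structure(list(values = values, sd = sd, grid = grid, gene_ids = gene_ids),
            class = "gwtm_tcm")
}

#' Intensity error model
#'
#' Standard deviation assigned to a measured intensity when no replicate
#' estimate is available: `sd = a + b * intensity`, an additive floor plus a
#' proportional (coefficient-of-variation) term. Used identically for
#' expression and degradation matrices.
#'
#' @param values Numeric vector or matrix of intensities.
#' @param a Additive floor in intensity units (default 1).
#' @param b Proportional term, a CV (default 0.1).
#' @return Object of the same shape as `values`.
#' @export
sd_error_model <- function(values, a = 1, b = 0.1) {
  if (a <= 0 && b <= 0) stop("error model needs a > 0 or b > 0")
  a + b * values
}

format_grid_times <- function(grid) {
  paste0("t", format(unclass(grid), trim = TRUE))
}

#' @export
print.gwtm_tcm <- function(x, ...) {
  cat(sprintf("<gwtm_tcm: %d genes x %d %s time points>\n",
              nrow(x$values), length(x$grid), grid_label(x$grid)))
  invisible(x)
}

#' @export
dim.gwtm_tcm <- function(x) dim(x$values)

#' Subset a time-course matrix by gene
#'
#' @param tcm A [time_course_matrix()].
#' @param genes Character vector of gene ids (order preserved) or a
#'   logical/integer row index.
#' @return A `gwtm_tcm` restricted to the requested genes.
#' @export
subset_genes <- function(tcm, genes) {
  stopifnot(inherits(tcm, "gwtm_tcm"))
  if (is.character(genes)) {
    missing <- setdiff(genes, tcm$gene_ids)
    if (length(missing) > 0L) {
      stop("gene id(s) not present: ", paste(missing, collapse = ", "))
    }
    idx <- match(genes, tcm$gene_ids)
  } else {
    idx <- genes
  }
  time_course_matrix(tcm$values[idx, , drop = FALSE], tcm$grid,
                     sd = tcm$sd[idx, , drop = FALSE],
                     gene_ids = tcm$gene_ids[idx])
}

#' Read a time-course matrix from a tab-separated file
#'
#' Expects a header row of times, first column the gene identifier. Values
#' must be numeric; duplicated gene ids and column/grid mismatches are hard
#' errors. If the file carries no sd columns the error model fills them in.
#'
#' @param path File path.
#' @inheritParams time_course_matrix
#' @return A `gwtm_tcm` with rows in file order.
#' @export
read_time_course <- function(path, grid, sd_a = 1, sd_b = 0.1) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) - 1L != length(grid)) {
    stop("file ", path, " has ", ncol(raw) - 1L,
         " data columns but grid has ", length(grid))
  }
  ids <- raw[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate gene id(s) in ", path, ": ", paste(dup, collapse = ", "))
  }
  vals <- matrix(NA_real_, nrow(raw), length(grid))
  for (j in seq_len(length(grid))) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad) > 0L) {
      stop("non-numeric cell in ", path, " at row ", bad[1L],
           " (gene ", ids[bad[1L]], "), column ", j + 1L)
    }
    vals[, j] <- num
  }
  time_course_matrix(vals, grid, gene_ids = ids, sd_a = sd_a, sd_b = sd_b)
}

#' Write a time-course matrix to a tab-separated file
#'
#' Row order is preserved so that write followed by read is the identity on
#' values and gene order. Only the intensity values are written; sd is
#' reconstructed from the error model on read.
#'
#' @param tcm A [time_course_matrix()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_time_course <- function(tcm, path) {
  stopifnot(inherits(tcm, "gwtm_tcm"))
  df <- data.frame(gene_id = tcm$gene_ids,
                   as.data.frame(tcm$values, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a gene-to-cluster assignment table
#'
#' Two-column tab-separated table with genes sorted lexicographically.
#' Cluster sizes are reported as a message.
#'
#' @param assignments Named vector (names = gene ids, values = cluster
#'   labels); every gene has exactly one label.
#' @param path Output file path.
#' @param quiet Suppress the cluster-size message.
#' @return Invisibly, the table of cluster sizes.
#' @export
write_cluster_table <- function(assignments, path, quiet = FALSE) {
  if (length(assignments) > 0L && is.null(names(assignments))) {
    stop("assignments must be named by gene id")
  }
  ids <- sort(names(assignments))
  df <- data.frame(gene_id = ids,
                   cluster = as.character(assignments[ids]),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sizes <- table(df$cluster)
  if (!quiet && length(sizes) > 0L) {
    message("cluster sizes: ",
            paste(sprintf("%s=%d", names(sizes), as.integer(sizes)),
                  collapse = ", "))
  }
  invisible(sizes)
}
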