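#' Reference set of two labelled replicate groups
#'
#' Two populations (e.g. the starting and ending precursor stages of a
#' differentiation step) measured in replicate over a common gene
#' universe; the raw material for the differential-expression gradient
#' used by [cca_scores()].
#'
#' @param start,end Numeric matrices, genes x replicates (>= 2 replicates
#'   each), identical rownames (gene ids), non-log intensities.
#' @param labels Character vector of two distinct group names.
#' @return Object of class `gwtm_refset`.
#' @export
reference_set <- function(start, end, labels = c("start", "end")) {
  start <- as.matrix(start); end <- as.matrix(end)
  if (is.null(rownames(start)) || is.null(rownames(end))) {
    stop("reference matrices need gene ids as rownames")
  }
  if (!identical(rownames(start), rownames(end))) {
    stop("the two groups must share one gene universe (same rownames)")
  }
  if (ncol(start) < 2L || ncol(end) < 2L) {
    stop("each group needs at least 2 replicates")
  }
  if (length(labels) != 2L || labels[1L] == labels[2L]) {
    stop("labels must be two distinct group names")
  }
  structure(list(start = start, end = end, labels = labels),
            class = "gwtm_refset")
}

#' Moderated t-statistics with empirical-Bayes variance shrinkage
#'
#' Two-group per-gene t-test on log2 intensities in which the per-gene
#' sample variance is shrunk toward a pooled prior: the posterior variance
#' is `(d0 s0^2 + dg s2_g) / (d0 + dg)` where the prior degrees of freedom
#' d0 and prior variance s0^2 are estimated by moment matching on the
#' distribution of log sample variances (mean and variance of
#' `log(s2_g)`, matched to the scaled-F model via digamma/trigamma).
#' P-values come from the t distribution with `d0 + dg` degrees of
#' freedom, Benjamini-Hochberg adjusted. As `d0 -> Inf` (forceable via
#' `prior_df`) the statistic reduces to an ordinary t with the common
#' prior variance.
#'
#' @param ref A [reference_set()].
#' @param prior_df Optional override for d0; `Inf` forces complete
#'   shrinkage to the pooled prior variance.
#' @return Data frame (one row per gene): `gene_id`, `log_ratio` (mean
#'   log2 end - mean log2 start), `t`, `df`, `p_value`, `adj_p`,
#'   `s2_post`; attributes `d0` and `s0_2`.
#' @export
moderated_t <- function(ref, prior_df = NULL) {
  stopifnot(inherits(ref, "gwtm_refset"))
  l1 <- log2(pmax(ref$start, .Machine$double.eps))
  l2 <- log2(pmax(ref$end, .Machine$double.eps))
  n1 <- ncol(l1); n2 <- ncol(l2)
  m1 <- rowMeans(l1); m2 <- rowMeans(l2)
  dg <- n1 + n2 - 2
  s2 <- (rowSums((l1 - m1)^2) + rowSums((l2 - m2)^2)) / dg
  mom <- fit_f_dist(s2, dg)
  d0 <- if (is.null(prior_df)) mom$d0 else prior_df
  s0_2 <- mom$s0_2
  s2_post <- if (is.infinite(d0)) {
    rep(s0_2, length(s2))
  } else {
    (d0 * s0_2 + dg * s2) / (d0 + dg)
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tval <- (m2 - m1) / se
  df_total <- if (is.infinite(d0)) Inf else d0 + dg
  p <- 2 * stats::pt(-abs(tval), df = df_total)
  data.frame(gene_id = rownames(ref$start), log_ratio = m2 - m1,
             t = tval, df = df_total, p_value = p,
             adj_p = stats::p.adjust(p, method = "BH"),
             s2_post = s2_post, row.names = NULL,
             stringsAsFactors = FALSE) -> out
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  out
}

# Moment-matching fit of the scaled-F model for sample variances: if
# s2_g ~ s0^2 F(dg, d0), then z = log(s2_g) has
#   E z   = log(s0^2) + digamma(dg/2) - log(dg/2)
#           - digamma(d0/2) + log(d0/2)
#   Var z = trigamma(dg/2) + trigamma(d0/2).
# d0 solves trigamma(d0/2) = Var(z) - trigamma(dg/2) (Newton on the
# monotone trigamma); a non-positive right-hand side means no excess
# spread, i.e. d0 = Inf.
fit_f_dist <- function(s2, dg) {
  ok <- is.finite(s2) & s2 > 0
  z <- log(s2[ok])
  if (length(z) < 2L) stop("too few positive variances to fit the prior")
  e <- z - digamma(dg / 2) + log(dg / 2)
  target <- stats::var(z) - trigamma(dg / 2)
  if (!is.finite(target) || target <= 1e-8) {
    return(list(d0 = Inf, s0_2 = exp(mean(e))))
  }
  d0 <- 2 * trigamma_inverse(target)
  s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_2 = s0_2)
}

# invert trigamma by Newton iteration (cf. the standard eBayes recipe)
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Build the differential-expression gradient for constrained ordination
#'
#' Selects the `top_n` most differentially expressed genes between the two
#' reference populations (by adjusted p, ties broken by |t| then gene id)
#' and assigns each its group log2-ratio as the per-gene environmental
#' value, oriented so genes higher in the end population are positive.
#'
#' @param ref A [reference_set()].
#' @param top_n Number of genes to keep (default 2000); if more than
#'   available, all genes are used with a warning.
#' @param mt Optional precomputed [moderated_t()] table.
#' @return Object of class `gwtm_gradient`: `genes`, `values` (named
#'   log-ratios), `top_n`.
#' @export
build_gradient <- function(ref, top_n = 2000L, mt = NULL) {
  if (top_n < 1L) stop("top_n must be at least 1")
  if (is.null(mt)) mt <- moderated_t(ref)
  ok <- is.finite(mt$t)
  mt <- mt[ok, , drop = FALSE]
  if (top_n > nrow(mt)) {
    warning("top_n = ", top_n, " exceeds ", nrow(mt),
            " genes with a finite statistic; using all")
    top_n <- nrow(mt)
  }
  ord <- order(mt$adj_p, -abs(mt$t), mt$gene_id)
  top <- mt[ord[seq_len(top_n)], , drop = FALSE]
  values <- top$log_ratio
  names(values) <- top$gene_id
  structure(list(genes = top$gene_id, values = values, top_n = top_n),
            class = "gwtm_gradient")
}

#' Score samples along a differentiation gradient (CCA, one variable)
#'
#' Canonical correspondence analysis of the gene x sample intensity table
#' constrained by one per-gene environmental variable (the reference
#' log-ratio): the table is chi-square standardized,
#' `Q = diag(r)^(-1/2) (P - r c') diag(c)^(-1/2)` with `P` the table
#' normalized to unit sum and `r`, `c` the row/column masses; the rows of
#' `Q` are projected onto the (r-weighted, centred) environmental variable;
#' the SVD of the projection yields the single constrained axis. Sample
#' scores are reported on that axis, oriented so the last sample scores at
#' least as high as the first; the constrained inertia (squared singular
#' value) measures how much of the total inertia (sum of squares of `Q`)
#' the gradient explains.
#'
#' @param expr Expression [time_course_matrix()] (or plain gene x sample
#'   matrix with dimnames); restricted internally to the gradient genes.
#'   Genes of the gradient absent from `expr`, and zero-sum rows/columns,
#'   are dropped with a warning.
#' @param gradient A [build_gradient()] result.
#' @return Object of class `gwtm_cca`: `scores` (named per-sample score),
#'   `total_inertia`, `constrained_inertia`, `gene_contrib` (named |row
#'   score x mass| per gene, for top-contributor lists), `n_genes`.
#' @export
cca_scores <- function(expr, gradient) {
  stopifnot(inherits(gradient, "gwtm_gradient"))
  Y <- if (inherits(expr, "gwtm_tcm")) expr$values else as.matrix(expr)
  if (is.null(rownames(Y))) stop("expression table needs gene rownames")
  if (is.null(colnames(Y))) colnames(Y) <- paste0("s", seq_len(ncol(Y)))
  common <- intersect(gradient$genes, rownames(Y))
  if (length(common) < length(gradient$genes)) {
    warning(length(gradient$genes) - length(common),
            " gradient gene(s) absent from the expression table")
  }
  if (length(common) < 2L) stop("fewer than 2 gradient genes available")
  Y <- Y[common, , drop = FALSE]
  z <- gradient$values[common]
  if (any(Y < 0)) stop("expression table must be non-negative")
  keep_r <- rowSums(Y) > 0
  keep_c <- colSums(Y) > 0
  if (any(!keep_r) || any(!keep_c)) {
    warning("dropping ", sum(!keep_r), " zero row(s) and ",
            sum(!keep_c), " zero column(s)")
    Y <- Y[keep_r, keep_c, drop = FALSE]
    z <- z[keep_r]
  }
  if (stats::sd(z) == 0) stop("environmental variable is constant")
  P <- Y / sum(Y)
  r <- rowSums(P)
  cm <- colSums(P)
  Q <- (P - r %o% cm) / sqrt(r %o% cm)
  total <- sum(Q^2)
  # weighted least-squares projection of Q's rows onto the centred gradient
  zc <- z - sum(r * z)
  xw <- sqrt(r) * zc
  H <- xw %o% xw / sum(xw^2)
  Qfit <- H %*% Q
  sv <- svd(Qfit, nu = 1L, nv = 1L)
  lambda <- sv$d[1L]^2
  v <- sv$v[, 1L]
  scores <- v / sqrt(cm)                      # chi-square metric col scores
  if (scores[length(scores)] < scores[1L]) {
    scores <- -scores
    sv$u[, 1L] <- -sv$u[, 1L]
  }
  names(scores) <- colnames(Y)
  contrib <- abs(sv$u[, 1L] * sqrt(r))
  names(contrib) <- rownames(Y)
  structure(list(scores = scores, total_inertia = total,
                 constrained_inertia = lambda, gene_contrib = contrib,
                 n_genes = nrow(Y)),
            class = "gwtm_cca")
}

#' Top gradient-contributing genes of a CCA
#'
#' Genes ranked by their absolute mass-weighted score on the constrained
#' axis; used to intersect high-contribution genes with annotation lists
#' (e.g. transcription factors).
#'
#' @param cca A [cca_scores()] result.
#' @param m Number of genes to return (default 1000).
#' @return Character vector of gene ids, highest contribution first.
#' @export
top_cca_contributors <- function(cca, m = 1000L) {
  stopifnot(inherits(cca, "gwtm_cca"))
  ord <- order(-cca$gene_contrib, names(cca$gene_contrib))
  names(cca$gene_contrib)[ord[seq_len(min(m, length(ord)))]]
}
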