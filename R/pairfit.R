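#' Bundle the data for one transcript pair
#'
#' Collects the two genes' expression series (+ sd, expression grid) and
#' degradation series (+ sd, degradation grid) into the unit the joint model
#' is fitted to.
#'
#' @param expr Expression [time_course_matrix()].
#' @param deg Degradation [time_course_matrix()] over the same genes.
#' @param gene_a,gene_b Gene ids present in both matrices.
#' @return Object of class `gwtm_pairdata`.
#' @export
pair_data <- function(expr, deg, gene_a, gene_b) {
  stopifnot(inherits(expr, "gwtm_tcm"), inherits(deg, "gwtm_tcm"))
  if (gene_a == gene_b) stop("a pair needs two distinct genes")
  for (g in c(gene_a, gene_b)) {
    if (!g %in% expr$gene_ids) stop("gene ", g, " not in expression matrix")
    if (!g %in% deg$gene_ids) stop("gene ", g, " not in degradation matrix")
  }
  pick <- function(tcm, g) {
    i <- match(g, tcm$gene_ids)
    list(values = tcm$values[i, ], sd = tcm$sd[i, ])
  }
  structure(list(genes = c(gene_a, gene_b),
                 expr = list(pick(expr, gene_a), pick(expr, gene_b)),
                 deg = list(pick(deg, gene_a), pick(deg, gene_b)),
                 expr_grid = expr$grid, deg_grid = deg$grid),
            class = "gwtm_pairdata")
}

#' Weighted residual vector of the joint pair model
#'
#' Concatenates, over both genes, the expression residuals (model solution
#' of (A + D I) x = B 1 + S f against the observed series) and the
#' degradation residuals (x_d0 exp(-D t) against the observed shutoff
#' series), each divided by the per-point standard deviation. The residual
#' sum of squares is the squared norm of this vector.
#'
#' @param params_pair List of two [kinetic_params()] (with `x_d0` set).
#' @param f An [activity_profile()] on the expression grid.
#' @param data A [pair_data()].
#' @param op Derivative operator on the expression grid.
#' @return Numeric residual vector (2 genes x (expression + degradation
#'   points); 22 components on the default grids).
#' @export
pair_residual <- function(params_pair, f, data, op) {
  stopifnot(inherits(data, "gwtm_pairdata"))
  td <- as.numeric(data$deg_grid)
  out <- numeric(0)
  for (k in 1:2) {
    p <- params_pair[[k]]
    xe <- predict_expression(p, f, op)
    xd <- predict_degradation(p, data$deg_grid)
    out <- c(out,
             (xe - data$expr[[k]]$values) / data$expr[[k]]$sd,
             (xd - data$deg[[k]]$values) / data$deg[[k]]$sd)
  }
  out
}

#' Fitting configuration for the joint pair model
#'
#' @param n_starts Number of deterministic multi-start initializations
#'   (default 3; values above 3 add seeded random activity starts).
#' @param d_min,d_max Bounds on the degradation rate D (1/hour).
#' @param f_max Upper bound on the raw activity values during optimization
#'   (scale is renormalized to max 1 afterwards).
#' @param intensity_cap_mult Upper bounds for B, S and x_d0 as a multiple of
#'   the pair's maximum observed intensity.
#' @param maxiter,ftol,ptol Levenberg-Marquardt control settings passed to
#'   the optimizer.
#' @param seed Global seed from which per-pair seeds are derived.
#' @return A list of class `gwtm_fitcfg`.
#' @export
fit_config <- function(n_starts = 3L, d_min = 1e-3, d_max = 5, f_max = 2,
                       intensity_cap_mult = 10, maxiter = 100L,
                       ftol = 1e-10, ptol = 1e-10, seed = 1L) {
  stopifnot(n_starts >= 1L, d_min > 0, d_max > d_min, f_max > 0)
  structure(list(n_starts = as.integer(n_starts), d_min = d_min,
                 d_max = d_max, f_max = f_max,
                 intensity_cap_mult = intensity_cap_mult,
                 maxiter = as.integer(maxiter), ftol = ftol, ptol = ptol,
                 seed = as.integer(seed)),
            class = "gwtm_fitcfg")
}

# Deterministic per-pair seed from the sorted gene ids and the global seed,
# so results do not depend on execution order or chunking.
pair_seed <- function(gene_a, gene_b, seed) {
  ids <- sort(c(gene_a, gene_b))
  h <- 0
  for (ch in utf8ToInt(paste(ids, collapse = "\r"))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((h + as.numeric(seed) * 2654435761) %% 2147483647)
}

#' Fit the joint kinetic model to a transcript pair
#'
#' Minimizes the residual sum of squares of [pair_residual()] over the two
#' genes' kinetic parameters (B, S, D, x_d0 each) and the shared activity
#' profile f (f(0) = 0 fixed), using bounded Levenberg-Marquardt with a
#' small set of deterministic multi-starts. After convergence the activity
#' scale is fixed by renormalizing max f to 1 and absorbing the scale into
#' each gene's S, which leaves the fit (and the RSS) unchanged but makes
#' G = B + S f well defined per gene.
#'
#' Starts: D is initialized from the empirical log-linear decay rate; the
#' activity is initialized from the normalized compound production of gene
#' 1, of gene 2, and from a linear ramp. The returned fit is the best
#' start.
#'
#' @param data A [pair_data()].
#' @param op Derivative operator on the expression grid.
#' @param cfg A [fit_config()].
#' @return Object of class `gwtm_pairfit`: `rss`, `params` (list of two
#'   [kinetic_params()]), `f` ([activity_profile()]), `converged`,
#'   `n_starts_used`, `genes`.
#' @export
fit_pair <- function(data, op, cfg = fit_config()) {
  stopifnot(inherits(data, "gwtm_pairdata"), inherits(op, "gwtm_derivop"))
  A <- op$matrix
  n <- nrow(A)
  nf <- n - 1L
  td <- as.numeric(data$deg_grid)
  obs <- unlist(lapply(1:2, function(k)
    c(data$expr[[k]]$values, data$deg[[k]]$values)))
  wts <- unlist(lapply(1:2, function(k)
    c(data$expr[[k]]$sd, data$deg[[k]]$sd)))
  max_int <- max(obs)
  cap <- cfg$intensity_cap_mult * max_int

  # theta = (B1,S1,D1,xd01, B2,S2,D2,xd02, f[2..n])
  resid_fn <- function(theta) {
    f <- c(0, theta[8L + seq_len(nf)])
    pred <- numeric(0)
    for (k in 1:2) {
      o <- (k - 1L) * 4L
      B <- theta[o + 1L]; S <- theta[o + 2L]
      D <- theta[o + 3L]; xd0 <- theta[o + 4L]
      xe <- solve(A + diag(D, n), B + S * f)
      pred <- c(pred, xe, xd0 * exp(-D * td))
    }
    (pred - obs) / wts
  }

  lower <- c(rep(c(0, 0, cfg$d_min, 0), 2L), rep(0, nf))
  upper <- c(rep(c(cap, cap, cfg$d_max, cap), 2L), rep(cfg$f_max, nf))

  # gene-level initial guesses
  init_gene <- function(k) {
    dh <- estimate_decay_rate(data$deg[[k]]$values, data$deg_grid)$D_hat
    if (is.na(dh)) dh <- 0.5
    D0 <- min(max(dh, cfg$d_min * 2), cfg$d_max * 0.9)
    x0 <- data$expr[[k]]$values[1L]
    B0 <- max(D0 * x0, 1e-6)
    g <- as.numeric(A %*% data$expr[[k]]$values) + D0 * data$expr[[k]]$values
    S0 <- max(max(g) - min(g), 0.05 * max_int, 1e-6)
    list(B = B0, S = min(S0, cap), D = D0,
         xd0 = max(data$deg[[k]]$values[1L], 1e-6), g = g)
  }
  gi <- lapply(1:2, init_gene)
  f_from_g <- function(g) {
    f <- pmax(g - g[1L], 0)
    if (max(f) > 0) f <- f / max(f)
    f[-1L]
  }
  t_expr <- as.numeric(data$expr_grid)
  f_starts <- list(f_from_g(gi[[1L]]$g), f_from_g(gi[[2L]]$g),
                   (t_expr / max(t_expr))[-1L])
  if (cfg$n_starts > 3L) {
    rng <- pair_seed(data$genes[1L], data$genes[2L], cfg$seed)
    extra <- withr_seed(rng, function() {
      lapply(seq_len(cfg$n_starts - 3L), function(i) stats::runif(nf))
    })
    f_starts <- c(f_starts, extra)
  }
  f_starts <- f_starts[seq_len(min(cfg$n_starts, length(f_starts)))]

  best <- NULL
  n_used <- 0L
  for (fs in f_starts) {
    theta0 <- c(gi[[1L]]$B, gi[[1L]]$S, gi[[1L]]$D, gi[[1L]]$xd0,
                gi[[2L]]$B, gi[[2L]]$S, gi[[2L]]$D, gi[[2L]]$xd0,
                pmin(pmax(fs, 0), cfg$f_max))
    fit <- tryCatch(
      suppressWarnings(  # non-convergence is recorded via the info flag
      minpack.lm::nls.lm(par = theta0, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = cfg$maxiter, ftol = cfg$ftol,
                           ptol = cfg$ptol))),
      error = function(e) NULL)
    if (is.null(fit)) next
    n_used <- n_used + 1L
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(rss = rss, theta = fit$par,
                   converged = fit$info %in% 1:4)
    }
  }
  if (is.null(best)) {
    return(structure(list(rss = Inf, params = NULL, f = NULL,
                          converged = FALSE, n_starts_used = 0L,
                          genes = data$genes),
                     class = "gwtm_pairfit"))
  }
  th <- best$theta
  f_raw <- c(0, th[8L + seq_len(nf)])
  scale <- max(f_raw)
  f_norm <- if (scale > 0) f_raw / scale else f_raw
  params <- lapply(1:2, function(k) {
    o <- (k - 1L) * 4L
    kinetic_params(B = th[o + 1L],
                   S = th[o + 2L] * (if (scale > 0) scale else 1),
                   D = th[o + 3L], x_d0 = th[o + 4L], d_max = cfg$d_max)
  })
  structure(list(rss = best$rss, params = params,
                 f = activity_profile(f_norm, data$expr_grid,
                                      normalize = FALSE),
                 converged = best$converged, n_starts_used = n_used,
                 genes = data$genes),
            class = "gwtm_pairfit")
}

# run fn() under a temporary RNG state seeded with seed
withr_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' @export
print.gwtm_pairfit <- function(x, ...) {
  cat(sprintf("<gwtm_pairfit %s ~ %s: rss = %.4g, converged = %s>\n",
              x$genes[1L], x$genes[2L], x$rss, x$converged))
  invisible(x)
}

#' All-pairs RSS dissimilarity matrix
#'
#' Fits the joint pair model to every unordered gene pair and stores the
#' minimized RSS as a symmetric dissimilarity with a zero diagonal. Small
#' RSS means the two transcripts can plausibly share one regulator
#' activity. Per-pair seeds derive from the sorted gene ids and the global
#' seed, so the result is independent of execution order and chunking; the
#' optional checkpoint file makes long runs resumable.
#'
#' @param expr,deg Expression and degradation [time_course_matrix()]s.
#' @param genes Gene ids to include (default: all genes of `expr`).
#' @param op Derivative operator on the expression grid.
#' @param cfg A [fit_config()].
#' @param chunks Split the pair list into this many chunks (computation is
#'   chunk-order independent; exposed mainly to verify that contract).
#' @param checkpoint Optional path of an append-only checkpoint TSV; on
#'   resume, pairs already present are not re-fitted. Refuses to resume if
#'   the stored config hash differs.
#' @param progress Emit a message every `progress` pairs (0 = silent).
#' @return Object of class `gwtm_rssmat`: `rss` (symmetric matrix),
#'   `genes`, `seed`, `config_hash`.
#' @export
rss_matrix <- function(expr, deg, genes = NULL, op, cfg = fit_config(),
                       chunks = 1L, checkpoint = NULL, progress = 0L) {
  stopifnot(inherits(expr, "gwtm_tcm"), inherits(deg, "gwtm_tcm"))
  if (is.null(genes)) genes <- expr$gene_ids
  if (length(genes) < 2L) stop("need at least 2 genes")
  n <- length(genes)
  cfg_hash <- config_hash(cfg)
  pairs <- utils::combn(genes, 2L)
  done <- new.env(parent = emptyenv())
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    lines <- readLines(checkpoint)
    if (length(lines) > 0L) {
      head_line <- lines[1L]
      stored <- sub("^# config_hash=", "", head_line)
      if (!startsWith(head_line, "# config_hash=") || stored != cfg_hash) {
        stop("checkpoint ", checkpoint,
             " was written under a different configuration; refusing to resume")
      }
      for (ln in lines[-1L]) {
        fields <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
        if (length(fields) == 3L) {
          assign(paste(fields[1L], fields[2L], sep = "\r"),
                 as.numeric(fields[3L]), envir = done)
        }
      }
    }
  } else if (!is.null(checkpoint)) {
    writeLines(paste0("# config_hash=", cfg_hash), checkpoint)
  }
  M <- matrix(0, n, n, dimnames = list(genes, genes))
  idx <- seq_len(ncol(pairs))
  chunk_id <- rep(seq_len(chunks), length.out = length(idx))
  count <- 0L
  for (ck in seq_len(chunks)) {
    for (p in idx[chunk_id == ck]) {
      ga <- pairs[1L, p]; gb <- pairs[2L, p]
      key <- paste(sort(c(ga, gb)), collapse = "\r")
      if (!is.null(checkpoint) && !is.null(done[[key]])) {
        r <- done[[key]]
      } else {
        pd <- pair_data(expr, deg, ga, gb)
        r <- fit_pair(pd, op, cfg)$rss
        if (!is.null(checkpoint)) {
          s <- sort(c(ga, gb))
          cat(sprintf("%s\t%s\t%.17g\n", s[1L], s[2L], r),
              file = checkpoint, append = TRUE)
        }
      }
      M[ga, gb] <- M[gb, ga] <- r
      count <- count + 1L
      if (progress > 0L && count %% progress == 0L) {
        message("fitted ", count, " / ", ncol(pairs), " pairs")
      }
    }
  }
  structure(list(rss = M, genes = genes, seed = cfg$seed,
                 config_hash = cfg_hash),
            class = "gwtm_rssmat")
}

#' Persist / load an RSS matrix as (gene_i, gene_j, rss) triples
#'
#' @param rssmat A [rss_matrix()] result.
#' @param path TSV path.
#' @return `write_rss_matrix` returns `path` invisibly; `read_rss_matrix`
#'   returns a `gwtm_rssmat`.
#' @export
write_rss_matrix <- function(rssmat, path) {
  stopifnot(inherits(rssmat, "gwtm_rssmat"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%d config_hash=%s", rssmat$seed,
                     rssmat$config_hash), con)
  writeLines("gene_i\tgene_j\trss", con)
  g <- rssmat$genes
  for (i in seq_along(g)[-length(g)]) {
    for (j in (i + 1L):length(g)) {
      writeLines(sprintf("%s\t%s\t%.17g", g[i], g[j], rssmat$rss[i, j]), con)
    }
  }
  invisible(path)
}

#' @rdname write_rss_matrix
#' @param path TSV path written by `write_rss_matrix`.
#' @export
read_rss_matrix <- function(path) {
  lines <- readLines(path, n = 1L)
  meta <- regmatches(lines, regexec("# seed=(-?\\d+) config_hash=(\\S+)",
                                    lines))[[1L]]
  df <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  genes <- sort(unique(c(df$gene_i, df$gene_j)))
  M <- matrix(0, length(genes), length(genes),
              dimnames = list(genes, genes))
  M[cbind(df$gene_i, df$gene_j)] <- df$rss
  M[cbind(df$gene_j, df$gene_i)] <- df$rss
  structure(list(rss = M, genes = genes,
                 seed = if (length(meta) == 3L) as.integer(meta[2L]) else NA,
                 config_hash = if (length(meta) == 3L) meta[3L] else NA),
            class = "gwtm_rssmat")
}
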