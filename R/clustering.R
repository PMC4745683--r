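#' Ward clustering of the RSS dissimilarity
#'
#' Agglomerative clustering of genes using the square root of the pairwise
#' RSS as the distance, merged under Ward's minimum variance criterion (the
#' classical Lance-Williams update applied to the provided distances,
#' `hclust(method = "ward.D")`; `"ward.D2"` available as a variant). Genes
#' are ordered lexicographically before clustering so ties break
#' deterministically. The top 2-way split of the dendrogram — the two major
#' transcriptional responses — is reported alongside the k-cluster cut.
#'
#' @param rssmat A [rss_matrix()] result (or any symmetric non-negative
#'   matrix with gene dimnames wrapped in a list as `list(rss = M,
#'   genes = rownames(M))`).
#' @param k Number of clusters, 2 <= k <= n.
#' @param method `"ward.D"` (classical Lance-Williams Ward on the given
#'   distances, default) or `"ward.D2"`.
#' @return Object of class `gwtm_clust`: `labels` (named integer vector,
#'   clusters numbered in `cutree` order), `top_split` (named 2-level
#'   cut), `hclust` (the dendrogram), `k`.
#' @export
ward_cluster <- function(rssmat, k, method = c("ward.D", "ward.D2")) {
  method <- match.arg(method)
  M <- rssmat$rss
  genes <- rssmat$genes
  if (!all(is.finite(M))) stop("RSS matrix has non-finite entries")
  if (any(M < 0)) stop("RSS matrix has negative entries")
  if (max(abs(M - t(M))) > 1e-8) stop("RSS matrix is not symmetric")
  n <- length(genes)
  if (k < 2L || k > n) stop("k must be in [2, ", n, "]")
  ord <- order(genes)
  M <- M[ord, ord]
  genes <- genes[ord]
  d <- stats::as.dist(sqrt(M))
  hc <- stats::hclust(d, method = method)
  hc$labels <- genes
  labels <- stats::cutree(hc, k = k)
  top <- stats::cutree(hc, k = 2L)
  structure(list(labels = labels, top_split = top, hclust = hc, k = k),
            class = "gwtm_clust")
}

#' @export
print.gwtm_clust <- function(x, ...) {
  cat(sprintf("<gwtm_clust: %d genes in %d clusters (%s)>\n",
              length(x$labels), x$k,
              paste(table(x$labels), collapse = "/")))
  invisible(x)
}

#' Per-cluster mean normalized compound-production profiles
#'
#' For every clustered gene, computes the compound production
#' G = A x + D x from its expression series and fitted degradation rate,
#' min-max normalizes each gene's G to [0, 1] (genes with a degenerate
#' zero-range G are skipped with a warning), and averages within each
#' cluster. Clusters are then relabelled by the time their mean G profile
#' first reaches half of its maximum, earliest first, so cluster 1 is the
#' earliest transcriptional activity.
#'
#' @param assignment A [ward_cluster()] result.
#' @param expr Expression [time_course_matrix()] covering the clustered
#'   genes.
#' @param D_hat Named numeric vector of per-gene degradation rates (e.g.
#'   consensus from the pair fits, or [estimate_decay_rate()]).
#' @param op Derivative operator on the expression grid.
#' @return Object of class `gwtm_gprofiles`: `profiles` (k x time matrix of
#'   mean normalized G), `labels` (relabelled assignment), `onset` (time to
#'   half-maximum per cluster), `skipped` (gene ids with no usable G).
#' @export
cluster_g_profiles <- function(assignment, expr, D_hat, op) {
  stopifnot(inherits(assignment, "gwtm_clust"), inherits(expr, "gwtm_tcm"))
  genes <- names(assignment$labels)
  t <- as.numeric(op$grid)
  norm_g <- matrix(NA_real_, length(genes), length(t),
                   dimnames = list(genes, NULL))
  skipped <- character(0)
  for (g in genes) {
    if (!g %in% names(D_hat) || is.na(D_hat[g])) {
      skipped <- c(skipped, g)
      next
    }
    x <- expr$values[match(g, expr$gene_ids), ]
    gg <- compound_production(x, D_hat[g], op)
    nz <- minmax_norm(as.numeric(gg))
    if (is.null(nz)) {
      skipped <- c(skipped, g)
      next
    }
    norm_g[g, ] <- nz
  }
  if (length(skipped) > 0L) {
    warning(length(skipped), " gene(s) skipped (missing D or zero-range G)")
  }
  k <- assignment$k
  prof <- matrix(NA_real_, k, length(t))
  for (cl in seq_len(k)) {
    members <- genes[assignment$labels == cl & !(genes %in% skipped)]
    if (length(members) > 0L) {
      prof[cl, ] <- colMeans(norm_g[members, , drop = FALSE])
    }
  }
  onset <- apply(prof, 1L, time_to_half_max, t = t)
  ord <- order(onset)
  relabel <- match(assignment$labels, ord)
  names(relabel) <- genes
  structure(list(profiles = prof[ord, , drop = FALSE], labels = relabel,
                 onset = onset[ord], skipped = skipped),
            class = "gwtm_gprofiles")
}

# First time (linear interpolation between grid points) a profile reaches
# half of its maximum.
time_to_half_max <- function(p, t) {
  if (all(is.na(p))) return(Inf)
  half <- (max(p) + min(p)) / 2
  for (i in seq_along(p)) {
    if (p[i] >= half) {
      if (i == 1L) return(t[1L])
      frac <- (half - p[i - 1L]) / (p[i] - p[i - 1L])
      return(t[i - 1L] + frac * (t[i] - t[i - 1L]))
    }
  }
  Inf
}

#' Cluster down-regulated genes into waves by expression correlation
#'
#' Average-linkage hierarchical clustering of the expression profiles on
#' the distance 1 - r (Pearson), cut at height 1 - `r_threshold`, so genes
#' in one wave correlate at least `r_threshold` with their wave on
#' average. Clusters smaller than `min_size` are reported as unassigned
#' (label `NA`). Waves are numbered by the time of steepest decline of
#' their mean normalized profile, earliest first. An alternative mode
#' links genes by connected components of the graph with edges at
#' r >= `r_threshold`.
#'
#' @param expr Expression [time_course_matrix()] restricted to the
#'   down-regulated genes.
#' @param r_threshold Pearson correlation threshold (default 0.8).
#' @param min_size Minimum wave size (default 5).
#' @param mode `"average"` (default) or `"components"`.
#' @return Object of class `gwtm_waves`: `labels` (named integer, `NA` =
#'   unassigned), `profiles` (wave x time mean normalized profiles),
#'   `excluded` (zero-variance gene ids).
#' @export
pearson_cluster_downregulated <- function(expr, r_threshold = 0.8,
                                          min_size = 5L,
                                          mode = c("average", "components")) {
  mode <- match.arg(mode)
  stopifnot(inherits(expr, "gwtm_tcm"))
  v <- expr$values
  vars <- apply(v, 1L, stats::var)
  excluded <- expr$gene_ids[vars <= 0]
  if (length(excluded) > 0L) {
    warning(length(excluded), " zero-variance gene(s) excluded")
  }
  keep <- expr$gene_ids[vars > 0]
  if (length(keep) < 2L) stop("need at least 2 genes with variance")
  vv <- v[keep, , drop = FALSE]
  r <- stats::cor(t(vv))
  if (mode == "average") {
    d <- stats::as.dist(1 - r)
    hc <- stats::hclust(d, method = "average")
    hc$labels <- keep
    raw <- stats::cutree(hc, h = 1 - r_threshold)
  } else {
    adj <- r >= r_threshold
    raw <- graph_components(adj)
    names(raw) <- keep
  }
  sizes <- table(raw)
  good <- names(sizes)[sizes >= min_size]
  labels <- ifelse(as.character(raw) %in% good, raw, NA_integer_)
  names(labels) <- keep
  # mean normalized profile per wave; order by steepest-decline time
  t <- as.numeric(expr$grid)
  waves <- sort(unique(labels[!is.na(labels)]))
  prof <- t(vapply(waves, function(w) {
    members <- keep[!is.na(labels) & labels == w]
    m <- vv[members, , drop = FALSE]
    m <- m / m[, 1L]  # normalize to baseline
    colMeans(m)
  }, numeric(length(t))))
  decline_t <- apply(prof, 1L, function(p) t[which.min(diff(p)) + 1L])
  ord <- order(decline_t)
  relabel <- match(labels, waves[ord])
  names(relabel) <- keep
  structure(list(labels = relabel, profiles = prof[ord, , drop = FALSE],
                 excluded = excluded),
            class = "gwtm_waves")
}

# connected components of a logical adjacency matrix (depth-first)
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      stack <- i
      while (length(stack) > 0L) {
        v <- stack[[length(stack)]]
        stack <- stack[-length(stack)]
        if (comp[v] == 0L) {
          comp[v] <- cur
          stack <- c(stack, which(adj[v, ] & comp == 0L))
        }
      }
    }
  }
  comp
}

#' Intersect a gene set with a transcription-factor list
#'
#' Case-insensitive exact-symbol matching, with optional per-cluster
#' counts.
#'
#' @param genes Character vector of gene ids.
#' @param tf_list Character vector of transcription-factor symbols.
#' @param clusters Optional named cluster labels over `genes`.
#' @return List: `tfs` (the matching gene ids, in `genes` spelling),
#'   `per_cluster` (table of counts, `NULL` when no clusters given).
#' @export
intersect_tfs <- function(genes, tf_list, clusters = NULL) {
  hit <- tolower(genes) %in% tolower(tf_list)
  tfs <- genes[hit]
  per_cluster <- NULL
  if (!is.null(clusters)) {
    per_cluster <- table(clusters[tfs])
  }
  list(tfs = tfs, per_cluster = per_cluster)
}

#' Export a dendrogram in Newick format
#'
#' @param hc An `hclust` object with labels.
#' @param path Output path.
#' @return Invisibly, the Newick string.
#' @export
write_dendrogram_newick <- function(hc, path) {
  stopifnot(inherits(hc, "hclust"))
  build <- function(i) {
    if (i < 0L) return(hc$labels[-i])
    h <- hc$height[i]
    kids <- hc$merge[i, ]
    sub <- vapply(kids, build, character(1L))
    sprintf("(%s,%s):%g", sub[1L], sub[2L], h)
  }
  nwk <- paste0(build(nrow(hc$merge)), ";")
  writeLines(nwk, path)
  invisible(nwk)
}
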