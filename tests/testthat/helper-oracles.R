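# Independent oracles and shared fixtures for the test suite.

# --- brute-force Lance-Williams Ward agglomeration ---------------------------
# Direct implementation of the recursive Ward update on a distance matrix:
# at each step merge the pair with minimal current distance, then update
# d(k, ij) = [(n_i+n_k) d(k,i) + (n_j+n_k) d(k,j) - n_k d(i,j)] /
#            (n_i+n_j+n_k).
# Returns the merge heights and the sequence of merged member sets.
ward_oracle <- function(d) {
  D <- as.matrix(d)
  n <- nrow(D)
  active <- seq_len(n)
  members <- lapply(seq_len(n), identity)
  sizes <- rep(1L, n)
  heights <- numeric(n - 1L)
  merges <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    best <- c(NA, NA)
    best_d <- Inf
    for (ii in seq_along(active)[-length(active)]) {
      for (jj in (ii + 1L):length(active)) {
        a <- active[ii]; b <- active[jj]
        if (D[a, b] < best_d) {
          best_d <- D[a, b]
          best <- c(a, b)
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    heights[step] <- best_d
    merges[[step]] <- sort(c(members[[i]], members[[j]]))
    ni <- sizes[i]; nj <- sizes[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- sizes[k]
      D[i, k] <- D[k, i] <-
        ((ni + nk) * D[k, i] + (nj + nk) * D[k, j] - nk * D[i, j]) /
        (ni + nj + nk)
    }
    members[[i]] <- sort(c(members[[i]], members[[j]]))
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  list(heights = heights, merges = merges)
}

# member sets in merge order from an hclust tree, for comparison
hclust_merge_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    get_set <- function(x) if (x < 0L) -x else sets[[x]]
    sets[[i]] <- sort(c(get_set(hc$merge[i, 1L]),
                        get_set(hc$merge[i, 2L])))
  }
  sets
}

# --- rank-based AUC of x (scores for positives) vs y (negatives) -------------
auc_oracle <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# --- RK4 integration of dx/dt = -D x (decay oracle) --------------------------
rk4_decay <- function(x0, D, times, h = 1e-3) {
  f <- function(x) -D * x
  out <- numeric(length(times))
  x <- x0
  t <- 0
  for (i in seq_along(times)) {
    while (t < times[i] - 1e-12) {
      step <- min(h, times[i] - t)
      k1 <- f(x); k2 <- f(x + step / 2 * k1)
      k3 <- f(x + step / 2 * k2); k4 <- f(x + step * k3)
      x <- x + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + step
    }
    out[i] <- x
  }
  out
}

# --- degradation arrays with a truly stable quartile and known loss ----------
make_loss_fixture <- function(n = 80, loss = c(1, 0.8, 0.6, 0.4),
                              seed = 9, noise_cv = 0.03) {
  set.seed(seed)
  dg <- degradation_grid()
  t <- as.numeric(dg)
  ids <- sprintf("d%03d", 1:n)
  stable <- seq_len(n / 4)  # planted 25% stable subset
  D <- ifelse(seq_len(n) %in% stable, 0,
              log(2) / runif(n, 0.8, 6))
  base <- runif(n, 50, 400)
  v <- outer(base, rep(1, 4)) * exp(-D %o% t)
  v <- v * exp(matrix(rnorm(n * 4, 0, noise_cv), n, 4))
  v <- sweep(v, 2, loss, `*`)
  rownames(v) <- ids
  list(tcm = time_course_matrix(v, dg), loss = loss, stable = ids[stable])
}

# --- cached expensive cohorts (computed once per test run) -------------------
.fixtures <- new.env(parent = emptyenv())

cohort_fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# 60-gene cohort, 3 well-separated activities, CV 10%, with its RSS matrix
three_group_cohort <- function() {
  cohort_fixture("three_group", function() {
    cfg <- synth_config(n_down = 0L, n_flat = 0L,
                        activities = c("early_maintained", "early_short",
                                       "late_continuous"))
    sim <- simulate_dataset(cfg, seed = 1L)
    op <- build_derivative_operator(expression_grid())
    rss <- rss_matrix(sim$expression, sim$degradation, op = op,
                      cfg = fit_config(seed = 1L))
    list(sim = sim, rss = rss, op = op)
  })
}

# generator-default cohort (60 up over 5 activities, 30 down, 30 flat)
default_cohort <- function() {
  cohort_fixture("default", function() {
    sim <- simulate_dataset(synth_config(), seed = 1L)
    op <- build_derivative_operator(expression_grid())
    up <- select_upregulated(sim$expression)
    genes <- intersect(up$selected,
                       sim$truth$gene_id[sim$truth$class == "up"])
    rss <- rss_matrix(sim$expression, sim$degradation, genes = genes,
                      op = op, cfg = fit_config(seed = 1L))
    list(sim = sim, rss = rss, op = op, up = up)
  })
}

# small noise-free dataset reused by several unit tests
noisefree_sim <- function() {
  cohort_fixture("noisefree", function() {
    cfg <- synth_config(n_up = 15L, n_down = 6L, n_flat = 4L,
                        noise_cv = 0)
    simulate_dataset(cfg, seed = 42L)
  })
}

adjusted_rand <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(a, b))
  }
  # closed-form ARI fallback
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}
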