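op7 <- build_derivative_operator(expression_grid())

# dissimilarity with planted blocks: within-block rss w2, between b2
planted_rss <- function(sizes, within = 1, between = 100, seed = 1,
                        jitter = 0.05) {
  set.seed(seed)
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  ids <- sprintf("p%02d", seq_len(n))
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      base <- if (lab[i] == lab[j]) within else between
      M[i, j] <- M[j, i] <- base * (1 + runif(1, -jitter, jitter))
    }
  }
  list(rss = M, genes = ids, labels = setNames(lab, ids))
}

test_that("well-separated blocks are recovered exactly at k = 2", {
  fx <- planted_rss(c(6, 9))
  cl <- ward_cluster(fx, k = 2)
  expect_equal(adjusted_rand(cl$labels, fx$labels[names(cl$labels)]), 1)
})

test_that("k = n puts every gene in its own cluster", {
  fx <- planted_rss(c(3, 4))
  cl <- ward_cluster(fx, k = 7)
  expect_equal(length(unique(cl$labels)), 7L)
})

test_that("ward agglomeration matches a brute-force Lance-Williams oracle", {
  fx <- planted_rss(c(10, 12, 8), within = 2, between = 40, jitter = 0.4,
                    seed = 5)
  d <- sqrt(fx$rss[sort(fx$genes), sort(fx$genes)])
  cl <- ward_cluster(fx, k = 3)
  oracle <- ward_oracle(as.dist(d))
  expect_equal(cl$hclust$height, oracle$heights, tolerance = 1e-10)
  expect_identical(hclust_merge_sets(cl$hclust), oracle$merges)
})

test_that("merge heights are monotone non-decreasing", {
  fx <- planted_rss(c(7, 9, 6), within = 3, between = 25, jitter = 0.6,
                    seed = 8)
  cl <- ward_cluster(fx, k = 3)
  expect_true(all(diff(cl$hclust$height) >= -1e-12))
})

test_that("cluster contents are invariant under gene permutation", {
  fx <- planted_rss(c(5, 5, 5), seed = 3)
  cl <- ward_cluster(fx, k = 3)
  set.seed(4)
  perm <- sample(length(fx$genes))
  fx_p <- list(rss = fx$rss[perm, perm], genes = fx$genes[perm])
  cl_p <- ward_cluster(fx_p, k = 3)
  genes <- sort(fx$genes)
  expect_equal(adjusted_rand(cl$labels[genes], cl_p$labels[genes]), 1)
})

test_that("ward clustering validates its input", {
  fx <- planted_rss(c(3, 3))
  bad <- fx
  bad$rss[1, 2] <- NA
  expect_error(ward_cluster(bad, k = 2), "non-finite")
  expect_error(ward_cluster(fx, k = 1), "k must be")
  expect_error(ward_cluster(fx, k = 99), "k must be")
})

test_that("a cluster of identical genes averages to any member's profile", {
  x <- c(50, 80, 120, 150, 160, 165, 168)
  v <- rbind(a = x, b = x, c = x)
  expr <- time_course_matrix(v, expression_grid())
  fake <- list(rss = matrix(0.1, 3, 3, dimnames = list(c("a", "b", "c"),
                                                       c("a", "b", "c"))),
               genes = c("a", "b", "c"))
  diag(fake$rss) <- 0
  cl <- ward_cluster(fake, k = 2)
  d_hat <- c(a = 0.5, b = 0.5, c = 0.5)
  gp <- cluster_g_profiles(cl, expr, d_hat, op7)
  member <- as.numeric(compound_production(x, 0.5, op7))
  member <- (member - min(member)) / (max(member) - min(member))
  for (row in seq_len(nrow(gp$profiles))) {
    expect_equal(unname(gp$profiles[row, ]), member, tolerance = 1e-12)
  }
})

test_that("flat-expression genes are skipped in G profile averaging", {
  v <- rbind(a = rep(100, 7), b = c(50, 80, 120, 150, 160, 165, 168))
  expr <- time_course_matrix(v, expression_grid())
  fake <- list(rss = matrix(c(0, 1, 1, 0), 2, 2,
                            dimnames = list(c("a", "b"), c("a", "b"))),
               genes = c("a", "b"))
  cl <- ward_cluster(fake, k = 2)
  expect_warning(
    gp <- cluster_g_profiles(cl, expr, c(a = 0.3, b = 0.3), op7),
    "skipped")
  expect_true("a" %in% gp$skipped)
})

test_that("clusters relabel by onset: earliest mean activity first", {
  sim <- noisefree_sim()
  tr <- sim$truth
  up <- tr$gene_id[tr$class == "up"]
  # build a 2-cluster assignment: early_maintained vs late_continuous
  early <- tr$gene_id[which(tr$activity == "early_maintained")]
  late <- tr$gene_id[which(tr$activity == "late_continuous")]
  genes <- c(late, early)  # deliberately late-first input order
  M <- matrix(50, length(genes), length(genes),
              dimnames = list(genes, genes))
  M[late, late] <- 1
  M[early, early] <- 1
  diag(M) <- 0
  cl <- ward_cluster(list(rss = M, genes = genes), k = 2)
  d_hat <- setNames(tr$D[match(genes, tr$gene_id)], genes)
  gp <- cluster_g_profiles(cl, sim$expression, d_hat, op7)
  expect_true(all(gp$labels[early] == 1L))
  expect_true(all(gp$labels[late] == 2L))
  expect_lt(gp$onset[1], gp$onset[2])
})

test_that("affine copies of one wave shape form a single cluster", {
  t <- as.numeric(expression_grid())
  shape <- 1 - plogis((t - 10) / 2)
  v <- rbind(a = 100 * shape + 20, b = 350 * shape + 5, c = 40 * shape + 60)
  expr <- time_course_matrix(v, expression_grid())
  w <- pearson_cluster_downregulated(expr, min_size = 2L)
  expect_equal(length(unique(w$labels)), 1L)
})

test_that("anti-correlated families split into two waves at r = 0.8", {
  t <- as.numeric(expression_grid())
  s1 <- 1 - plogis((t - 5) / 1.5)
  s2 <- rev(s1)
  mk <- function(s, n, base) {
    m <- t(vapply(seq_len(n), function(i) base * (s * (1 + 0.02 * i) + 0.2),
                  numeric(length(t))))
    m
  }
  v <- rbind(mk(s1, 5, 100), mk(s2, 5, 80))
  rownames(v) <- sprintf("w%02d", 1:10)
  expr <- time_course_matrix(v, expression_grid())
  w <- pearson_cluster_downregulated(expr, min_size = 2L)
  labs <- w$labels
  expect_equal(length(unique(labs)), 2L)
  expect_equal(length(unique(labs[1:5])), 1L)
  expect_equal(length(unique(labs[6:10])), 1L)
})

test_that("zero-variance genes are excluded from wave clustering", {
  t <- as.numeric(expression_grid())
  v <- rbind(a = rep(5, 7), b = 1 - plogis((t - 8) / 2) + 0.1,
             c = 1 - plogis((t - 9) / 2) + 0.1)
  expr <- time_course_matrix(v, expression_grid())
  expect_warning(w <- pearson_cluster_downregulated(expr, min_size = 2L),
                 "zero-variance")
  expect_identical(w$excluded, "a")
})

test_that("connected-components mode groups chains linked at r >= 0.8", {
  sim <- noisefree_sim()
  down <- sim$truth$gene_id[sim$truth$class == "down"]
  expr <- subset_genes(sim$expression, down)
  avg <- pearson_cluster_downregulated(expr, min_size = 2L)
  comp <- pearson_cluster_downregulated(expr, min_size = 2L,
                                        mode = "components")
  tr_w <- sim$truth$wave[match(down, sim$truth$gene_id)]
  expect_gte(adjusted_rand(avg$labels, tr_w), 0.8)
  expect_gte(adjusted_rand(comp$labels, tr_w), 0.8)
})

test_that("TF intersection matches case-insensitively and conserves counts", {
  expect_identical(intersect_tfs(c("a", "b", "c"), c("B", "d"))$tfs, "b")
  expect_length(intersect_tfs(c("a", "b"), character(0))$tfs, 0L)
  genes <- c("Id3", "Gata3", "Actb", "Myb")
  clusters <- setNames(c(1L, 2L, 1L, 2L), genes)
  res <- intersect_tfs(genes, c("ID3", "gata3", "MYB"), clusters)
  expect_equal(sum(res$per_cluster), length(res$tfs))
})

test_that("dendrograms export to parseable Newick", {
  fx <- planted_rss(c(3, 4))
  cl <- ward_cluster(fx, k = 2)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(cl$hclust, path)
  skip_if_not_installed("ape")
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, fx$genes)
})
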