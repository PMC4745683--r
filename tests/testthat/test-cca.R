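# small deterministic reference set builder
make_ref <- function(n_genes = 200, reps = 3, shift_idx = integer(0),
                     shift = 1, sd_log2 = 0.3, seed = 17) {
  set.seed(seed)
  ids <- sprintf("r%03d", seq_len(n_genes))
  mu <- runif(n_genes, 6, 11)  # log2 means
  mu_end <- mu
  mu_end[shift_idx] <- mu_end[shift_idx] + shift
  draw <- function(m) {
    out <- vapply(seq_len(reps),
                  function(j) 2^(m + rnorm(n_genes, 0, sd_log2)),
                  numeric(n_genes))
    rownames(out) <- ids
    out
  }
  reference_set(draw(mu), draw(mu_end))
}

test_that("identical groups give null statistics and p near one", {
  set.seed(2)
  m <- 2^matrix(rnorm(100 * 6, 8, 0.4), 100, 6)
  rownames(m) <- sprintf("g%03d", 1:100)
  ref <- reference_set(m[, 1:3], m[, 1:3])
  mt <- moderated_t(ref)
  expect_true(all(abs(mt$t) < 1e-10))
  expect_true(all(mt$adj_p > 0.99))
})

test_that("forcing d0 to infinity reduces to an ordinary t with the
           pooled prior variance", {
  ref <- make_ref(n_genes = 150, shift_idx = 1:10)
  mt_inf <- moderated_t(ref, prior_df = Inf)
  s0_2 <- attr(mt_inf, "s0_2")
  l1 <- log2(ref$start); l2 <- log2(ref$end)
  tt <- (rowMeans(l2) - rowMeans(l1)) / sqrt(s0_2 * (1/3 + 1/3))
  expect_equal(mt_inf$t, unname(tt), tolerance = 1e-10)
  expect_true(all(is.infinite(mt_inf$df)))
})

test_that("moderated statistics track limma's eBayes on the same data", {
  skip_if_not_installed("limma")
  ref <- make_ref(n_genes = 300, shift_idx = 1:25, shift = 1.2)
  mt <- moderated_t(ref)
  y <- log2(cbind(ref$start, ref$end))
  design <- cbind(1, rep(c(0, 1), each = 3))
  fit <- limma::eBayes(limma::lmFit(y, design))
  # same shrinkage machinery: prior df and statistics agree closely
  expect_equal(attr(mt, "d0"), fit$df.prior, tolerance = 0.05)
  expect_gt(cor(mt$t, fit$t[, 2]), 0.999)
  expect_gt(cor(-log10(mt$p_value), -log10(fit$p.value[, 2])), 0.999)
})

test_that("planted differential genes rank at the top", {
  ref <- make_ref(n_genes = 400, shift_idx = 1:20, shift = 1.5)
  mt <- moderated_t(ref)
  top20 <- mt$gene_id[order(mt$adj_p, -abs(mt$t))][1:20]
  expect_gte(length(intersect(top20, sprintf("r%03d", 1:20))), 18)
})

test_that("gradient construction selects, orients and bounds", {
  ref <- make_ref(n_genes = 50, shift_idx = 1:5, shift = 2)
  expect_error(build_gradient(ref, top_n = 0), "at least 1")
  grad <- build_gradient(ref, top_n = 10)
  expect_length(grad$genes, 10L)
  expect_true(all(sprintf("r%03d", 1:5) %in% grad$genes))
  # end-group-high genes carry positive environmental values
  expect_true(all(grad$values[sprintf("r%03d", 1:5)] > 0))
  expect_warning(g_all <- build_gradient(ref, top_n = 500), "using all")
  expect_length(g_all$genes, 50L)
})

test_that("samples copying the start mean carry no gradient signal", {
  ref <- make_ref(n_genes = 100, shift_idx = 1:30, shift = 1.5)
  grad <- build_gradient(ref, top_n = 50)
  m <- rowMeans(ref$start)
  Y <- cbind(s1 = m, s2 = m, s3 = m, s4 = m)
  cca <- cca_scores(Y, grad)
  expect_lt(cca$constrained_inertia / max(cca$total_inertia, 1e-12), 1e-6)
})

test_that("interpolated samples score monotonically along the gradient
           and agree with an independent CCA implementation", {
  ref <- make_ref(n_genes = 20, shift_idx = 1:8, shift = 2, seed = 23)
  grad <- build_gradient(ref, top_n = 20)
  fracs <- seq(0, 1, length.out = 6)
  m_s <- rowMeans(ref$start); m_e <- rowMeans(ref$end)
  Y <- vapply(fracs, function(w) (1 - w) * m_s + w * m_e,
              numeric(20))
  colnames(Y) <- paste0("s", seq_along(fracs))
  rownames(Y) <- rownames(ref$start)
  cca <- cca_scores(Y, grad)
  expect_true(all(diff(cca$scores) > 0))
  skip_if_not_installed("vegan")
  vg <- vegan::cca(X = Y[grad$genes, ], Y = data.frame(z = grad$values))
  vg_scores <- vegan::scores(vg, display = "species", choices = 1)[, 1]
  expect_gt(abs(cor(as.numeric(cca$scores), vg_scores)), 0.999)
  expect_equal(cca$constrained_inertia / cca$total_inertia,
               unname(vg$CCA$eig[1] / vg$tot.chi), tolerance = 1e-6)
})

test_that("constrained inertia never exceeds total inertia", {
  ref <- make_ref(n_genes = 60, shift_idx = 1:20, shift = 1.2, seed = 31)
  grad <- build_gradient(ref, top_n = 40)
  set.seed(5)
  for (i in 1:5) {
    Y <- matrix(runif(40 * 5, 1, 100), 40, 5,
                dimnames = list(grad$genes, paste0("s", 1:5)))
    cca <- cca_scores(Y, grad)
    expect_lte(cca$constrained_inertia, cca$total_inertia + 1e-12)
  }
})

test_that("scores are invariant to a global intensity rescaling", {
  ref <- make_ref(n_genes = 30, shift_idx = 1:10, seed = 41)
  grad <- build_gradient(ref, top_n = 30)
  set.seed(6)
  Y <- matrix(runif(30 * 4, 1, 50), 30, 4,
              dimnames = list(grad$genes, paste0("s", 1:4)))
  a <- cca_scores(Y, grad)
  b <- cca_scores(Y * 12.5, grad)
  expect_equal(a$scores, b$scores, tolerance = 1e-10)
  expect_equal(a$total_inertia, b$total_inertia, tolerance = 1e-10)
})

test_that("degenerate ordination inputs are rejected or dropped", {
  ref <- make_ref(n_genes = 30, shift_idx = 1:10, seed = 43)
  grad <- build_gradient(ref, top_n = 30)
  Y <- matrix(runif(30 * 4, 1, 50), 30, 4,
              dimnames = list(grad$genes, paste0("s", 1:4)))
  Y[3, ] <- 0
  expect_warning(cca_scores(Y, grad), "zero row")
  flat <- grad
  flat$values[] <- 1
  expect_error(suppressWarnings(cca_scores(Y, flat)), "constant")
  expect_error(reference_set(matrix(1, 3, 1), matrix(1, 3, 2)),
               "rownames|replicates")
})

test_that("top contributors are ranked by mass-weighted axis loading", {
  ref <- make_ref(n_genes = 40, shift_idx = 1:15, shift = 2, seed = 47)
  grad <- build_gradient(ref, top_n = 40)
  m_s <- rowMeans(ref$start); m_e <- rowMeans(ref$end)
  Y <- vapply(seq(0, 1, 0.25), function(w) (1 - w) * m_s + w * m_e,
              numeric(40))
  rownames(Y) <- rownames(ref$start)
  cca <- cca_scores(Y, grad)
  top <- top_cca_contributors(cca, 10)
  expect_length(top, 10L)
  expect_true(all(top %in% names(cca$gene_contrib)))
  expect_equal(cca$gene_contrib[top[1]], max(cca$gene_contrib),
               ignore_attr = TRUE)
})
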