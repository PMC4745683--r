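op7 <- build_derivative_operator(expression_grid())

# exact model-generated pair sharing one activity, zero noise
make_exact_pair <- function(f_vals = c(0, 0.6, 1, 0.9, 0.7, 0.5, 0.4),
                            p1 = kinetic_params(20, 120, 0.8, x_d0 = NA),
                            p2 = kinetic_params(35, 200, 0.25, x_d0 = NA)) {
  f <- activity_profile(f_vals, expression_grid(), normalize = FALSE)
  build <- function(p) {
    xe <- predict_expression(p, f, op7)
    xd0 <- xe[4]  # level near the arrest time
    list(params = kinetic_params(p$B, p$S, p$D, x_d0 = xd0),
         expr = xe,
         deg = xd0 * exp(-p$D * as.numeric(degradation_grid())))
  }
  g1 <- build(p1); g2 <- build(p2)
  expr <- time_course_matrix(rbind(a = g1$expr, b = g2$expr),
                             expression_grid())
  deg <- time_course_matrix(rbind(a = g1$deg, b = g2$deg),
                            degradation_grid())
  list(data = pair_data(expr, deg, "a", "b"), f = f,
       params = list(g1$params, g2$params), expr = expr, deg = deg)
}

test_that("the residual vector is zero at the generating parameters", {
  fx <- make_exact_pair()
  r <- pair_residual(fx$params, fx$f, fx$data, op7)
  expect_length(r, 22L)
  expect_lt(max(abs(r)), 1e-10)
})

test_that("perturbing one observation by 2 sd adds exactly 4 to the rss", {
  fx <- make_exact_pair()
  expr2 <- fx$expr
  v <- expr2$values
  v["a", 3] <- v["a", 3] + 2 * expr2$sd["a", 3]
  expr_pert <- time_course_matrix(v, expression_grid(),
                                  sd = expr2$sd)
  d2 <- pair_data(expr_pert, fx$deg, "a", "b")
  r <- pair_residual(fx$params, fx$f, d2, op7)
  expect_equal(sum(r^2), 4, tolerance = 1e-8)
})

test_that("vector-norm and explicit-loop rss computations agree", {
  fx <- make_exact_pair()
  set.seed(8)
  pp <- list(kinetic_params(10, 50, 0.5, x_d0 = 60),
             kinetic_params(30, 80, 1.2, x_d0 = 90))
  r <- pair_residual(pp, fx$f, fx$data, op7)
  loop <- 0
  for (k in 1:2) {
    pe <- predict_expression(pp[[k]], fx$f, op7)
    pd <- predict_degradation(pp[[k]], degradation_grid())
    loop <- loop +
      sum((pe - fx$data$expr[[k]]$values)^2 / fx$data$expr[[k]]$sd^2) +
      sum((pd - fx$data$deg[[k]]$values)^2 / fx$data$deg[[k]]$sd^2)
  }
  expect_equal(sum(r^2), loop, tolerance = 1e-12)
})

test_that("a noise-free co-regulated pair fits to near-zero rss with
           accurate decay rates", {
  fx <- make_exact_pair()
  fit <- fit_pair(fx$data, op7)
  expect_lt(fit$rss, 1e-4)
  expect_lt(abs(fit$params[[1]]$D - 0.8) / 0.8, 0.05)
  expect_lt(abs(fit$params[[2]]$D - 0.25) / 0.25, 0.05)
  expect_equal(max(as.numeric(fit$f)), 1)
  expect_equal(as.numeric(fit$f)[1], 0)
})

test_that("maximally different activities fit at least 10x worse than a
           shared one", {
  # early pulse vs late ramp, noise-free
  early <- c(0, 1, 0.6, 0.25, 0.1, 0.05, 0)
  late <- c(0, 0.02, 0.08, 0.2, 0.45, 0.75, 1)
  f_e <- activity_profile(early, expression_grid(), normalize = FALSE)
  f_l <- activity_profile(late, expression_grid(), normalize = FALSE)
  mk <- function(p, f) {
    xe <- predict_expression(p, f, op7)
    list(expr = xe, deg = xe[4] * exp(-p$D * as.numeric(degradation_grid())))
  }
  p1 <- kinetic_params(20, 150, 0.9)
  p2 <- kinetic_params(30, 180, 0.7)
  g1 <- mk(p1, f_e); g2 <- mk(p2, f_l)
  expr <- time_course_matrix(rbind(a = g1$expr, b = g2$expr),
                             expression_grid())
  deg <- time_course_matrix(rbind(a = g1$deg, b = g2$deg),
                            degradation_grid())
  cross <- fit_pair(pair_data(expr, deg, "a", "b"), op7)
  shared <- fit_pair(make_exact_pair()$data, op7)
  expect_gt(cross$rss, 10 * max(shared$rss, 1e-3))
})

test_that("the fitted rss is symmetric under pair order", {
  fx <- make_exact_pair()
  sim <- noisefree_sim()
  cfg <- fit_config(seed = 1L)
  f_ab <- fit_pair(pair_data(sim$expression, sim$degradation,
                             "gene001", "gene006"), op7, cfg)
  f_ba <- fit_pair(pair_data(sim$expression, sim$degradation,
                             "gene006", "gene001"), op7, cfg)
  expect_lt(abs(f_ab$rss - f_ba$rss) / max(f_ab$rss, 1e-12), 1e-6)
})

test_that("optimization never worsens the best evaluated start", {
  sim <- noisefree_sim()
  pd <- pair_data(sim$expression, sim$degradation, "gene002", "gene007")
  fit <- fit_pair(pd, op7)
  # the linear-ramp start is always in the evaluated set; its raw rss
  # bounds the final one from above
  f_ramp <- activity_profile(as.numeric(expression_grid()) / 21,
                             expression_grid(), normalize = FALSE)
  d1 <- estimate_decay_rate(pd$deg[[1]]$values, degradation_grid())$D_hat
  d2 <- estimate_decay_rate(pd$deg[[2]]$values, degradation_grid())$D_hat
  start <- list(
    kinetic_params(max(d1 * pd$expr[[1]]$values[1], 1e-6), 1, max(d1, 2e-3),
                   x_d0 = pd$deg[[1]]$values[1]),
    kinetic_params(max(d2 * pd$expr[[2]]$values[1], 1e-6), 1, max(d2, 2e-3),
                   x_d0 = pd$deg[[2]]$values[1]))
  start_rss <- sum(pair_residual(start, f_ramp, pd, op7)^2)
  expect_lte(fit$rss, start_rss + 1e-9)
})

test_that("rss matrices are symmetric, zero-diagonal and complete", {
  sim <- noisefree_sim()
  genes <- sim$truth$gene_id[1:4]
  rss <- rss_matrix(sim$expression, sim$degradation, genes = genes,
                    op = op7, cfg = fit_config(seed = 1L))
  M <- rss$rss
  expect_equal(dim(M), c(4L, 4L))
  expect_identical(diag(M), setNames(rep(0, 4), genes))
  expect_equal(M, t(M))
  expect_true(all(M >= 0) && all(is.finite(M)))
})

test_that("chunked computation reproduces the single-chunk matrix", {
  sim <- noisefree_sim()
  genes <- sim$truth$gene_id[1:6]
  cfg <- fit_config(seed = 1L)
  one <- rss_matrix(sim$expression, sim$degradation, genes = genes,
                    op = op7, cfg = cfg, chunks = 1L)
  seven <- rss_matrix(sim$expression, sim$degradation, genes = genes,
                      op = op7, cfg = cfg, chunks = 7L)
  expect_identical(one$rss, seven$rss)
})

test_that("checkpointed runs resume to an identical matrix and refuse a
           mismatched configuration", {
  sim <- noisefree_sim()
  genes <- sim$truth$gene_id[1:5]
  cfg <- fit_config(seed = 1L)
  ck <- withr::local_tempfile(fileext = ".tsv")
  full <- rss_matrix(sim$expression, sim$degradation, genes = genes,
                     op = op7, cfg = cfg, checkpoint = ck)
  # truncate the checkpoint to simulate an interrupted run, then resume
  lines <- readLines(ck)
  writeLines(lines[1:(1 + 4)], ck)
  resumed <- rss_matrix(sim$expression, sim$degradation, genes = genes,
                        op = op7, cfg = cfg, checkpoint = ck)
  expect_equal(resumed$rss, full$rss, tolerance = 1e-12)
  expect_error(
    rss_matrix(sim$expression, sim$degradation, genes = genes, op = op7,
               cfg = fit_config(seed = 2L), checkpoint = ck),
    "refusing to resume")
})

test_that("rss matrices round-trip through the triple TSV format", {
  sim <- noisefree_sim()
  genes <- sim$truth$gene_id[1:4]
  rss <- rss_matrix(sim$expression, sim$degradation, genes = genes,
                    op = op7, cfg = fit_config(seed = 1L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rss_matrix(rss, path)
  back <- read_rss_matrix(path)
  expect_equal(back$rss[rss$genes, rss$genes], rss$rss, tolerance = 1e-15)
})
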