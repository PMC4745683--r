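#' Five reference transcriptional activity shapes
#'
#' Parameterized activity profiles on the expression grid emulating the
#' temporal classes observed downstream of a differentiation stimulus:
#' (1) early maintained — fast rise then plateau; (2) early short — fast
#' rise then decay to below 0.2 of peak; (3) early intermediate — fast rise
#' then decay to about half of peak; (4) late continuous — slow monotone
#' rise peaking at the last time point; (5) late short — late rise peaking
#' around 17.5 h then declining. All satisfy f(0) = 0 and max f = 1, and
#' the shapes are mutually distinguishable (pairwise Pearson correlation
#' below 0.95).
#'
#' @param grid The expression [time_grid()].
#' @return Named list of five [activity_profile()]s
#'   (`early_maintained`, `early_short`, `early_intermediate`,
#'   `late_continuous`, `late_short`).
#' @export
make_activity_profiles <- function(grid) {
  t <- as.numeric(grid)
  tmax <- max(t)
  shapes <- list(
    early_maintained   = 1 - exp(-t / 1.5),
    early_short        = (t / 3) * exp(1 - t / 3),
    early_intermediate = (1 - exp(-t / 1.2)) * (0.35 + 0.65 * exp(-t / 6)),
    late_continuous    = (t / tmax)^2 * (3 - 2 * t / tmax),
    late_short         = pmax(exp(-((t - 17.5) / 4)^2) -
                                exp(-(17.5 / 4)^2), 0)
  )
  lapply(shapes, activity_profile, grid = grid, normalize = TRUE)
}

#' Configuration of the synthetic time-course generator
#'
#' Defaults emulate the study design the analysis assumes: a 7-point
#' expression course (0-21 h), transcription arrested at 10 h with a
#' 4-point shutoff chase (0, 1, 2, 5.5 h), heterogeneous per-gene decay
#' (half-lives 0.5-20 h, log-uniform), genes driven by five shared
#' activities, three sigmoid down-regulation waves, and multiplicative
#' log-normal measurement noise at 10 percent CV.
#'
#' @param n_up,n_down,n_flat Gene counts per class (up-regulated genes are
#'   spread evenly over the five activities, down-regulated over the three
#'   waves).
#' @param halflife_range Half-life range in hours, drawn log-uniform.
#' @param baseline_range Baseline (t = 0) intensity range, log-uniform.
#' @param noise_cv Multiplicative log-normal noise CV (0 disables noise).
#' @param shutoff_time Time (h) of transcription arrest on the expression
#'   clock.
#' @param wave_mids Sigmoid midpoints (h) of the three down-regulation
#'   waves.
#' @param wave_width Sigmoid width (h) of the declines.
#' @param down_floor Final level of down-regulated genes as a fraction of
#'   baseline (must be below 1/1.5 so the down filter finds them).
#' @param up_fold_target Minimum noise-free peak/baseline ratio enforced
#'   for up-regulated genes (kept strictly above the 1.5 filter).
#' @param loss_factors Optional per-array multipliers applied to the
#'   degradation arrays (length of the degradation grid, first entry 1) to
#'   emulate global RNA loss and exercise normalization.
#' @param activities Names of the activity profiles driving the
#'   up-regulated genes (default: all five of
#'   [make_activity_profiles()]); a cohort with fewer, well-separated
#'   activities is the cleaner benchmark for pairwise discrimination.
#' @param sd_a,sd_b Error-model coefficients stored in the emitted
#'   matrices.
#' @return List of class `gwtm_synthcfg`.
#' @export
synth_config <- function(n_up = 60L, n_down = 30L, n_flat = 30L,
                         halflife_range = c(0.5, 20), baseline_range = c(50, 500),
                         noise_cv = 0.10, shutoff_time = 10,
                         wave_mids = c(3.5, 10.5, 17.5), wave_width = 1.5,
                         down_floor = 0.2, up_fold_target = 1.6,
                         loss_factors = NULL, activities = NULL,
                         sd_a = 1, sd_b = 0.1) {
  if (n_up < 0 || n_down < 0 || n_flat < 0) stop("gene counts must be >= 0")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (any(halflife_range <= 0) || diff(halflife_range) < 0) {
    stop("invalid halflife_range")
  }
  structure(list(n_up = as.integer(n_up), n_down = as.integer(n_down),
                 n_flat = as.integer(n_flat),
                 halflife_range = halflife_range,
                 baseline_range = baseline_range, noise_cv = noise_cv,
                 shutoff_time = shutoff_time, wave_mids = wave_mids,
                 wave_width = wave_width, down_floor = down_floor,
                 up_fold_target = up_fold_target,
                 loss_factors = loss_factors, activities = activities,
                 sd_a = sd_a, sd_b = sd_b),
            class = "gwtm_synthcfg")
}

#' Simulate an expression + degradation dataset with known truth
#'
#' Up-regulated genes follow the discrete kinetic model
#' x = (A + D I)^(-1) (B 1 + S f) with one of the five shared activities;
#' their shutoff series comes from fine-grained ODE integration of
#' dx/dt = B + S f(t) - D x up to the arrest time, then exponential decay
#' sampled on the degradation grid. Down-regulated genes are sigmoid
#' declines in three waves; unchanged genes are flat. Multiplicative
#' log-normal noise (mean-preserving) is applied to every entry.
#'
#' @param cfg A [synth_config()].
#' @param seed Integer seed; identical (cfg, seed) gives identical output.
#' @return List of class `gwtm_synthdata`: `expression` and `degradation`
#'   ([time_course_matrix()]s), `truth` (data frame: gene_id, class,
#'   activity, wave, B, S, D, baseline), `activities` (the five profiles),
#'   `seed`.
#' @export
simulate_dataset <- function(cfg = synth_config(), seed = 1L) {
  stopifnot(inherits(cfg, "gwtm_synthcfg"))
  egrid <- expression_grid()
  dgrid <- degradation_grid()
  op <- build_derivative_operator(egrid)
  acts <- make_activity_profiles(egrid)
  if (!is.null(cfg$activities)) {
    missing <- setdiff(cfg$activities, names(acts))
    if (length(missing) > 0L) {
      stop("unknown activity name(s): ", paste(missing, collapse = ", "))
    }
    acts <- acts[cfg$activities]
  }
  t_e <- as.numeric(egrid)
  t_d <- as.numeric(dgrid)
  withr_seed(derive_seed(seed, 101L), function() {
    n_tot <- cfg$n_up + cfg$n_down + cfg$n_flat
    ids <- sprintf("gene%03d", seq_len(n_tot))
    expr <- matrix(NA_real_, n_tot, length(t_e), dimnames = list(ids, NULL))
    degm <- matrix(NA_real_, n_tot, length(t_d), dimnames = list(ids, NULL))
    truth <- data.frame(gene_id = ids, class = NA_character_,
                        activity = NA_character_, wave = NA_integer_,
                        B = NA_real_, S = NA_real_, D = NA_real_,
                        baseline = NA_real_, stringsAsFactors = FALSE)
    draw_lu <- function(rng) exp(stats::runif(1, log(rng[1]), log(rng[2])))
    row <- 0L
    # up-regulated genes: round-robin over the five activities
    for (i in seq_len(cfg$n_up)) {
      row <- row + 1L
      a <- ((i - 1L) %% length(acts)) + 1L
      f <- as.numeric(acts[[a]])
      repeat {
        D <- log(2) / draw_lu(cfg$halflife_range)
        x0 <- draw_lu(cfg$baseline_range)
        B <- D * x0
        S <- B * stats::runif(1, 1.5, 4)
        x <- NULL
        for (tries in 1:25) {
          x <- solve(op$matrix + diag(D, length(t_e)), B + S * f)
          if (max(x) / x[1L] > cfg$up_fold_target) break
          S <- S * 1.4
        }
        if (max(x) / x[1L] > cfg$up_fold_target &&
            min(x) >= 0.12 * x[1L] &&
            max(x) - min(x) >= 2) break
      }
      expr[row, ] <- x
      x_arrest <- integrate_kinetics(B, S, D, f, t_e, cfg$shutoff_time)
      degm[row, ] <- x_arrest * exp(-D * t_d)
      truth[row, c("class", "activity")] <- c("up", names(acts)[a])
      truth[row, c("B", "S", "D", "baseline")] <- c(B, S, D, x0)
    }
    # down-regulated genes: sigmoid declines in three waves
    for (i in seq_len(cfg$n_down)) {
      row <- row + 1L
      w <- ((i - 1L) %% length(cfg$wave_mids)) + 1L
      x0 <- draw_lu(cfg$baseline_range)
      D <- log(2) / draw_lu(cfg$halflife_range)
      prof <- cfg$down_floor +
        (1 - cfg$down_floor) *
        (1 - stats::plogis((t_e - cfg$wave_mids[w]) / cfg$wave_width)) /
        (1 - stats::plogis(-cfg$wave_mids[w] / cfg$wave_width))
      x <- x0 * prof
      expr[row, ] <- x
      x_arrest <- stats::approx(t_e, x, xout = cfg$shutoff_time)$y
      degm[row, ] <- x_arrest * exp(-D * t_d)
      truth[row, "class"] <- "down"
      truth[row, "wave"] <- w
      truth[row, c("D", "baseline")] <- c(D, x0)
    }
    # unchanged genes
    for (i in seq_len(cfg$n_flat)) {
      row <- row + 1L
      x0 <- draw_lu(cfg$baseline_range)
      D <- log(2) / draw_lu(cfg$halflife_range)
      expr[row, ] <- x0
      degm[row, ] <- x0 * exp(-D * t_d)
      truth[row, "class"] <- "flat"
      truth[row, c("D", "baseline")] <- c(D, x0)
    }
    if (!is.null(cfg$loss_factors)) {
      if (length(cfg$loss_factors) != length(t_d)) {
        stop("loss_factors must have one entry per degradation array")
      }
      degm <- sweep(degm, 2L, cfg$loss_factors, `*`)
    }
    if (cfg$noise_cv > 0) {
      sig <- sqrt(log(1 + cfg$noise_cv^2))
      noise <- function(m) {
        m * exp(matrix(stats::rnorm(length(m), -sig^2 / 2, sig),
                       nrow(m), ncol(m)))
      }
      expr <- noise(expr)
      degm <- noise(degm)
    }
    structure(list(
      expression = time_course_matrix(expr, egrid, sd_a = cfg$sd_a,
                                      sd_b = cfg$sd_b),
      degradation = time_course_matrix(degm, dgrid, sd_a = cfg$sd_a,
                                       sd_b = cfg$sd_b),
      truth = truth, activities = acts, seed = seed),
      class = "gwtm_synthdata")
  })
}

# Integrate dx/dt = B + S f(t) - D x from the pre-stimulus steady state
# x(0) = B/D up to t_end, with f linearly interpolated on the grid.
integrate_kinetics <- function(B, S, D, f, t_grid, t_end) {
  f_fun <- stats::approxfun(t_grid, f, rule = 2L)
  out <- deSolve::ode(y = c(x = B / D), times = c(0, t_end),
                      func = function(t, y, parms) {
                        list(B + S * f_fun(t) - D * y)
                      }, parms = NULL, method = "lsoda",
                      rtol = 1e-8, atol = 1e-8)
  unname(out[nrow(out), "x"])
}

#' Simulate two reference populations with planted differential expression
#'
#' A start group and an end group of replicate profiles over one gene
#' universe; a chosen fraction of genes receives a log2 shift (random
#' sign) of `effect_sd_units` times the replicate noise sd in the end
#' group. Replicate noise is log-normal on the log2 scale.
#'
#' @param n_genes Gene count (default 2000).
#' @param reps Replicates per group (default 3, minimum 2).
#' @param de_frac Fraction of genes with a planted shift (default 0.05).
#' @param effect_sd_units Planted shift in units of the replicate sd
#'   (default 3).
#' @param rep_sd_log2 Replicate noise sd on the log2 scale (default 0.35).
#' @param baseline_range Baseline intensity range, log-uniform.
#' @param seed Integer seed.
#' @return List: `ref` (a [reference_set()]), `de_genes` (planted ids),
#'   `truth` (data frame gene_id / planted / shift).
#' @export
simulate_reference_populations <- function(n_genes = 2000L, reps = 3L,
                                           de_frac = 0.05,
                                           effect_sd_units = 3,
                                           rep_sd_log2 = 0.35,
                                           baseline_range = c(50, 2000),
                                           seed = 1L) {
  if (reps < 2L) stop("each group needs at least 2 replicates")
  if (de_frac < 0 || de_frac > 1) stop("de_frac must be in [0, 1]")
  withr_seed(derive_seed(seed, 202L), function() {
    ids <- sprintf("ref%04d", seq_len(n_genes))
    base_log2 <- stats::runif(n_genes, log2(baseline_range[1]),
                              log2(baseline_range[2]))
    n_de <- round(de_frac * n_genes)
    de_idx <- sort(sample.int(n_genes, n_de))
    shift <- numeric(n_genes)
    shift[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) *
      effect_sd_units * rep_sd_log2
    draw <- function(mu_log2) {
      m <- vapply(seq_len(reps), function(j) {
        2^(mu_log2 + stats::rnorm(n_genes, 0, rep_sd_log2))
      }, numeric(n_genes))
      rownames(m) <- ids
      m
    }
    ref <- reference_set(draw(base_log2), draw(base_log2 + shift))
    list(ref = ref, de_genes = ids[de_idx],
         truth = data.frame(gene_id = ids, planted = shift != 0,
                            shift = shift, stringsAsFactors = FALSE))
  })
}

#' Simulate a differentiating trajectory between two reference populations
#'
#' Experimental samples whose mean interpolates linearly from the start
#' population mean to the end population mean as time runs over the grid,
#' with multiplicative log-normal noise — the situation the CCA staging is
#' designed to resolve.
#'
#' @param ref A [reference_set()].
#' @param grid A [time_grid()]; the interpolation weight is time / max
#'   time.
#' @param noise_cv Multiplicative noise CV (default 0.05).
#' @param seed Integer seed.
#' @return Gene x sample matrix (one column per grid time, named by time).
#' @export
simulate_trajectory <- function(ref, grid, noise_cv = 0.05, seed = 1L) {
  stopifnot(inherits(ref, "gwtm_refset"))
  withr_seed(derive_seed(seed, 303L), function() {
    t <- as.numeric(grid)
    w <- t / max(t)
    m_start <- rowMeans(ref$start)
    m_end <- rowMeans(ref$end)
    sig <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0
    out <- vapply(w, function(wi) {
      mu <- (1 - wi) * m_start + wi * m_end
      if (sig > 0) {
        mu * exp(stats::rnorm(length(mu), -sig^2 / 2, sig))
      } else mu
    }, numeric(nrow(ref$start)))
    rownames(out) <- rownames(ref$start)
    colnames(out) <- format_grid_times(grid)
    out
  })
}
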