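# gwtm

Kinetic modelling of time-course transcriptomes: who is driven by the same
regulator, once you account for how fast each mRNA decays?

## The problem

After a differentiation stimulus, transcript profiles are shaped by two
things at once: the activity of the regulators producing them and the decay
rate removing them. A slow-decaying transcript turns a sharp regulator
pulse into a delayed, smoothed rise; a fast-decaying one tracks the pulse
faithfully. Clustering expression profiles alone therefore both splits
genuinely co-regulated genes and merges unrelated ones. `gwtm` is for
experiments that measure, besides the expression time course, a
transcription-shutoff ("chase") time course — expression after
transcription is arrested pharmacologically — which isolates decay and
makes the deconvolution possible.

The model per transcript is

```
dx/dt = B + S f(t) - D x
```

with basal production `B`, sensitivity `S` to a hidden, time-varying
regulator activity `f`, and first-order degradation `D`. On the sampling
grid the derivative is a fixed rational-valued stencil matrix `A`, giving
the discrete solution `x = (A + D I)^-1 (B 1 + S f)`; after shutoff,
`x_d(t) = x_d0 exp(-D t)`. For every gene pair, the model is fitted
jointly to both genes' expression and chase series under one **shared**
`f` (bounded Levenberg–Marquardt, variance-weighted residuals); the
minimized residual sum of squares (RSS) is small only if one activity can
drive both genes. Ward clustering on `sqrt(RSS)` then yields the principal
transcriptional activities, visualized per cluster by the mean normalized
compound production `G = A x + D x = B + S f`.

Around this core the package provides: iterative normalization of chase
arrays against a stable gene set, empirical decay-rate estimation,
fold-change censuses and modelling-set filters, correlation clustering of
down-regulated genes into waves, a moderated t (empirical-Bayes variance
shrinkage) for two reference populations, canonical correspondence
analysis to stage samples along the resulting differentiation gradient,
and a synthetic-data generator with known ground truth that emulates the
full experimental design (7 expression points over 0–21 h, shutoff at
10 h, chase at 0/1/2/5.5 h, five activity shapes, three down-regulation
waves).

## Worked example

```r
library(gwtm)

# simulate the design with known truth: 18 up-regulated genes driven by
# three shared activities, 9 down-regulated in waves, 6 unchanged
cfg <- synth_config(n_up = 18, n_down = 9, n_flat = 6,
                    activities = c("early_maintained", "early_short",
                                   "late_continuous"))
sim <- simulate_dataset(cfg, seed = 1)
op  <- build_derivative_operator(expression_grid())

# which genes enter the kinetic modelling set?
up <- select_upregulated(sim$expression)
up
#> <gwtm_filter: 18 selected, 15 excluded>

# joint fit of a co-regulated pair (both driven by the early-maintained
# activity)
pd  <- pair_data(sim$expression, sim$degradation, "gene001", "gene004")
fit <- fit_pair(pd, op)
fit
#> <gwtm_pairfit gene001 ~ gene004: rss = 10.4, converged = TRUE>
round(c(D1 = fit$params[[1]]$D, D2 = fit$params[[2]]$D), 3)
#>    D1    D2
#> 0.455 0.325    # planted decay rates were 0.433 and 0.324 /h

# a cross-regulated pair (early-maintained vs early-short) fits far worse
fit_pair(pair_data(sim$expression, sim$degradation,
                   "gene001", "gene002"), op)
#> <gwtm_pairfit gene001 ~ gene002: rss = 80.26, converged = TRUE>

# all-pairs RSS and Ward clustering into principal activities
rss <- rss_matrix(sim$expression, sim$degradation,
                  genes = up$selected, op = op)
cl  <- ward_cluster(rss, k = 3)
cl
#> <gwtm_clust: 18 genes in 3 clusters (8/6/4)>
```

The pair RSS is a variance-weighted sum over 22 data points (7 expression
+ 4 chase per gene); values near the residual degrees of freedom (~9)
mean "compatible with one shared activity", values far above mean the
pair needs two different regulators. Here the co-regulated pair scores
10.4 — with both decay rates recovered to a few percent — while the
cross-regulated pair scores 80.3. The 3-cluster cut assigns 16 of the 18
genes to their planted activity (two slowly-decaying late-activity genes
are absorbed into the early-maintained cluster, the method's
characteristic hard case).

A shell front-end for the whole pipeline (simulate or analyse TSV
matrices, with checkpointed pair fitting) is installed at
`inst/scripts/run_gwtm.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/run_gwtm.R", package="gwtm"))')" \
    --outdir out --seed 1
```

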