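# Least-squares estimation, confidence intervals and block pruning.

test_that("noiseless recovery of a published parameter set", {
  sp <- inhibitor_spec("egcg_2")
  d <- recovery_dataset(sp, recovery_design("egcg_2"))
  truth <- true_par(sp)
  f <- fit_bivariate(d, sp,
                     fit_options(start = perturb20(truth, 1), multistart = 1))
  expect_true(f$converged)
  expect_lt(max(abs(coef(f) - truth) / abs(truth)), 1e-3)
  expect_lt(f$sse, 1e-12)
})

test_that("starting at the truth converges immediately on noiseless data", {
  sp <- scenario_spec("C")
  d <- generate_dataset(sp)
  f <- fit_bivariate(d, sp, fit_options(start = true_par(sp),
                                        multistart = 1))
  expect_true(f$converged)
  expect_lt(f$sse, 1e-20)
  expect_lte(f$niter, 10)
})

test_that("least-squares solution matches an exhaustive grid search", {
  ctl <- kinetic_params(1, 0.25, 3)
  sp <- bivariate_spec(ctl)
  d <- generate_dataset(sp, t_grid = seq(0, 10, length.out = 8), C_grid = 0,
                        noise = noise_model("gaussian_additive", 0.03,
                                            seed = 17),
                        clip_negative = FALSE)
  f <- fit_bivariate(d, sp, fit_options(multistart = 3))
  grid_sse <- function(Xg, vg, lg) {
    grid <- expand.grid(Xm = Xg, vm = vg, lam = lg, KEEP.OUT.ATTRS = FALSE)
    sse <- numeric(nrow(grid))
    for (tt in d$time) {
      z <- 2 + (4 * grid$vm / grid$Xm) * (grid$lam - tt)
      pred <- grid$Xm / (1 + exp(z))
      obs <- d$response[d$time == tt][1]
      sse <- sse + (obs - pred)^2
    }
    list(grid = grid, sse = sse)
  }
  # coarse global scan: no basin beats the optimizer's solution
  co <- grid_sse(seq(0.8, 1.2, by = 5e-3), seq(0.1, 0.4, by = 5e-3),
                 seq(2.5, 3.5, by = 5e-3))
  expect_lte(f$sse, min(co$sse))
  # fine 1e-3-step scan around the solution: it is the grid argmin
  step <- 1e-3
  est <- coef(f)
  fi <- grid_sse(seq(est[["Xm"]] - 0.02, est[["Xm"]] + 0.02, by = step),
                 seq(est[["vm"]] - 0.02, est[["vm"]] + 0.02, by = step),
                 seq(est[["lam"]] - 0.02, est[["lam"]] + 0.02, by = step))
  best <- fi$grid[which.min(fi$sse), ]
  expect_lt(abs(est[["Xm"]] - best$Xm), step + 1e-9)
  expect_lt(abs(est[["vm"]] - best$vm), step + 1e-9)
  expect_lt(abs(est[["lam"]] - best$lam), step + 1e-9)
})

test_that("row order of the dataset does not change the estimates", {
  sp <- scenario_spec("D")
  d <- generate_dataset(sp, noise = noise_model("gaussian_additive", 0.01,
                                                seed = 3))
  shuffled <- withr::with_seed(4, d[sample(nrow(d)), ])
  f1 <- fit_bivariate(d, sp, fit_options(multistart = 2))
  f2 <- fit_bivariate(kinetic_dataset(shuffled), sp,
                      fit_options(multistart = 2))
  expect_identical(coef(f1), coef(f2))
})

test_that("covariance machinery is coherent", {
  sp <- inhibitor_spec("egcg_2")
  d <- generate_dataset(sp, recovery_design("egcg_2")$t,
                        recovery_design("egcg_2")$C,
                        noise = noise_model("gaussian_additive", 0.03,
                                            seed = 5),
                        clip_negative = FALSE)
  f <- fit_bivariate(d, sp, fit_options(start = true_par(sp),
                                        multistart = 1))
  expect_equal(f$covariance, t(f$covariance))
  expect_true(all(eigen(f$covariance, only.values = TRUE)$values > -1e-12))
  expect_equal(unname(diag(f$correlation)), rep(1, f$p))
  expect_equal(unname(f$se), unname(sqrt(diag(f$covariance))))
  ci <- confidence_intervals(f)
  expect_equal(ci$halfwidth, qt(0.975, f$df) * ci$se)
  expect_equal(ci$upper - ci$lower, 2 * ci$halfwidth)
  # widening alpha tightens the interval
  ci90 <- confidence_intervals(f, alpha = 0.10)
  expect_true(all(ci90$halfwidth < ci$halfwidth))
})

test_that("insufficient data and degenerate designs are handled", {
  sp <- scenario_spec("C")
  tiny <- generate_dataset(sp, t_grid = c(0, 2, 4, 6), C_grid = c(0, 2))
  expect_error(fit_bivariate(tiny, sp), "insufficient data")
  expect_error(
    fit_bivariate(generate_dataset(sp, t_grid = c(0, 3, 6), C_grid = c(0, 2)),
                  sp),
    "4 distinct times")
  # single-concentration dataset: falls back to the control-only fit
  ctl_only <- generate_dataset(sp, t_grid = seq(0, 12, 0.5), C_grid = 0)
  expect_warning(f <- fit_bivariate(ctl_only, sp), "control-only")
  expect_named(coef(f), c("Xm", "vm", "lam"))
  expect_lt(f$sse, 1e-18)
})

test_that("unidentifiable blocks are flagged as rank deficient", {
  # scenario G has no Xm effect: fitting one leaves (mx, ax) unidentified
  spG <- scenario_spec("G")
  d <- generate_dataset(spG)
  tmpl <- bivariate_spec(spG$control,
                         effect_on_Xm = effect_block(0.5, 10, 1, "attenuate"),
                         effect_on_lag = spG$effect_on_lag)
  expect_warning(f <- fit_bivariate(d, tmpl, fit_options(multistart = 3)),
                 "rank-deficient")
  expect_true(f$rank_deficient)
  expect_true(any(is.na(f$se)))
})

test_that("pruning recovers the generating structure and records why", {
  sp <- scenario_spec("D")  # Xm and lag blocks only
  d <- generate_dataset(sp, noise = noise_model("gaussian_additive", 0.01,
                                                seed = 8),
                        clip_negative = FALSE)
  f <- suppressWarnings(
    prune_nonsignificant(d, full_template(sp), fit_options(multistart = 5)))
  kept <- names(Filter(Negate(is.null),
                       f$template[c("effect_on_Xm", "effect_on_vm",
                                    "effect_on_lag")]))
  expect_setequal(kept, c("effect_on_Xm", "effect_on_lag"))
  expect_length(f$pruned, 1)
  pr <- f$pruned[[1]]
  expect_equal(pr$block, "vm")
  expect_true(is.finite(pr$t) && is.finite(pr$t_critical))
  expect_match(pr$reason, "includes 0|does not worsen")
  # retained blocks recover the generating parameters
  truth <- true_par(sp)
  expect_lt(max(abs(coef(f)[names(truth)] - truth) / truth), 0.05)
})

test_that("pruning everything returns the control-only fit", {
  ctl <- kinetic_params(1, 0.25, 3)
  sp0 <- bivariate_spec(ctl)  # no dose effect at all
  d <- generate_dataset(sp0, t_grid = seq(0, 12, 0.4),
                        C_grid = c(0, 1, 2, 4),
                        noise = noise_model("gaussian_additive", 0.01,
                                            seed = 12),
                        clip_negative = FALSE)
  f <- suppressWarnings(
    prune_nonsignificant(d, full_template(bivariate_spec(ctl), m0 = 2),
                         fit_options(multistart = 3)))
  expect_named(coef(f), c("Xm", "vm", "lam"))
  expect_length(f$pruned, 3)
})

test_that("fit options are validated", {
  expect_error(fit_options(alpha = 0), "alpha")
  expect_error(fit_options(ftol = -1), "tolerances")
  sp <- scenario_spec("C")
  d <- generate_dataset(sp)
  expect_error(fit_bivariate(d, sp, fit_options(start = c(bogus = 1))),
               "unknown start")
})
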