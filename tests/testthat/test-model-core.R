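# Core model: reparameterized logistic, Weibull effects, bivariate surface.

test_that("logistic curve hits its anchor points exactly", {
  kp <- kinetic_params(Xm = 1, vm = 0.25, lam = 3)
  # at t = lambda the exponent is exactly 2; at tau the curve is at half-max
  expect_equal(logistic_response(kp, 3), 1 / (1 + exp(2)))
  expect_equal(logistic_response(kp, 5), 0.5)  # tau = 3 + 1/(2*0.25) = 5
  # property over random parameter sets
  withr::with_seed(11, {
    for (i in 1:25) {
      p <- kinetic_params(runif(1, 0.1, 500), runif(1, 0.01, 200),
                          runif(1, 0, 100))
      expect_equal(logistic_response(p, p$lam), p$Xm / (1 + exp(2)))
      expect_equal(logistic_response(p, tau_from(p)), p$Xm / 2)
    }
  })
})

test_that("published-parameter curve reaches its plateau", {
  kp <- kinetic_params(Xm = 1.12, vm = 0.18, lam = 4.78)
  expect_equal(logistic_response(kp, 30), 1.12, tolerance = 1e-6 / 1.12)
  expect_true(logistic_response(kp, 30) < 1.12)
})

test_that("curve is strictly increasing, bounded, and overflow-guarded", {
  kp <- kinetic_params(Xm = 2, vm = 0.5, lam = 10)
  t <- seq(-50, 200, length.out = 400)
  x <- logistic_response(kp, t)
  expect_true(all(diff(x) > 0 | x[-1] == x[-length(x)]))
  expect_true(all(x > 0 & x <= 2))
  # huge negative/positive exponents stay finite (guarded evaluation)
  steep <- kinetic_params(Xm = 1, vm = 1e6, lam = 50)
  expect_equal(logistic_response(steep, 0), 0)
  expect_equal(logistic_response(steep, 1e6), 1)
})

test_that("slope at the inflection point equals vm", {
  withr::with_seed(21, {
    for (i in 1:10) {
      p <- kinetic_params(runif(1, 0.5, 50), runif(1, 0.05, 20),
                          runif(1, 0, 20))
      tau <- tau_from(p)
      h <- 1e-5 * max(tau, 1)
      slope <- (logistic_response(p, tau + h) -
                logistic_response(p, tau - h)) / (2 * h)
      expect_equal(slope, p$vm, tolerance = 1e-6)
    }
  })
})

test_that("kapp and tau derivations are consistent", {
  expect_equal(kapp_from(kinetic_params(1, 0.25, 3)), 1)
  expect_equal(kapp_from(kinetic_params(1.12, 0.18, 4.78)), 4 * 0.18 / 1.12)
  expect_equal(tau_from(kinetic_params(1, 0.25, 3)), 5)
  expect_equal(tau_from(kinetic_params(1.12, 0.18, 4.78)),
               4.78 + 1.12 / 0.36)
  expect_equal(tau_from(kinetic_params(17.43, 16.10, 0.25)),
               0.25 + 17.43 / 32.2)
  # lag = tau - 2/kapp
  p <- kinetic_params(1, 0.25, 3)
  expect_equal(tau_from(p) - 2 / kapp_from(p), p$lam)
})

test_that("original and reparameterized logistic are the same curve", {
  withr::with_seed(31, {
    for (i in 1:10) {
      Xm <- runif(1, 0.5, 100); vm <- runif(1, 0.05, 30)
      # keep the lag exponent representable in the original form
      p <- kinetic_params(Xm, vm, runif(1, 0, min(30, 100 * Xm / (4 * vm))))
      kapp <- kapp_from(p)
      X0 <- p$Xm / (1 + exp(2 + 4 * p$vm * p$lam / p$Xm))
      orig <- original_logistic_params(p$Xm, X0, kapp)
      tg <- seq(0, 2 * tau_from(p), length.out = 1000)
      expect_equal(original_logistic_response(orig, tg),
                   logistic_response(p, tg), tolerance = 1e-12)
    }
  })
  o <- original_logistic_params(Xm = 2, X0 = 0.1, kapp = 0.8)
  expect_equal(original_logistic_response(o, 0), 0.1)
  expect_equal(original_logistic_response(o, 1e5), 2)
})

test_that("Weibull effect: zero at zero dose, half-effect exactly at m", {
  b <- effect_block(K = 0.86, m = 0.47, a = 2.51, direction = "attenuate")
  expect_equal(weibull_effect(b, 0), 0)
  expect_equal(weibull_effect(b, 0.47), 0.43)
  # arithmetic oracle at C = 2m
  expect_equal(weibull_effect(b, 0.94), 0.86 * (1 - exp(-log(2) * 2^2.51)))
  # half-effect at m for any shape; saturation at K
  withr::with_seed(41, {
    for (i in 1:25) {
      bb <- effect_block(runif(1, 0, 3), runif(1, 0.01, 50),
                         runif(1, 0.05, 8), "amplify")
      expect_equal(weibull_effect(bb, bb$m), bb$K / 2)
      Cg <- seq(0, 20 * bb$m, length.out = 200)
      eff <- weibull_effect(bb, Cg)
      expect_true(all(diff(eff) >= 0))
      expect_lt(abs(weibull_effect(bb, bb$m * 2^(30 / bb$a)) - bb$K), 1e-9)
    }
  })
  expect_error(weibull_effect(b, -1), "C must be")
})

test_that("modulation applies each block to its own parameter", {
  egcg1 <- inhibitor_spec("egcg_1")
  # half lag effect at C = m_lambda
  mod <- modulate(egcg1, 0.50)
  expect_equal(mod$lam, 4.78 * (1 + 0.81 / 2))
  # zero dose leaves the control untouched
  expect_equal(unclass(modulate(egcg1, 0)), unclass(egcg1$control))
  # absent vm block leaves vm constant in dose
  expect_equal(mod$vm, 0.18)
  # full suppression: Xm* -> 0 as dose grows
  supp <- bivariate_spec(kinetic_params(1, 0.25, 3),
                         effect_on_Xm = effect_block(1, 5, 2, "attenuate"))
  xs <- vapply(c(5, 10, 20), function(C) modulate(supp, C)$Xm, numeric(1))
  expect_true(all(diff(xs) < 0) && xs[3] < 1e-4)
})

test_that("out-of-validity modulation raises an explicit error", {
  taiw <- inhibitor_spec("taiwaniaflavone")  # K_v = 1.14 > 1
  expect_error(modulate(taiw, 1e4), "validity range")
  expect_error(bivariate_response(taiw, 1, 1e4), "validity range")
  # but the restricted range stays valid
  expect_true(modulate(taiw, 10)$vm > 0)
})

test_that("bivariate surface reduces to the control at zero dose", {
  spA <- scenario_spec("A")
  tg <- seq(0, 20, length.out = 50)
  expect_identical(bivariate_response(spA, tg, 0),
                   logistic_response(spA$control, tg))
  expect_equal(bivariate_response(spA, 5, 0), 0.5)  # control tau = 5
})

test_that("Xm-only suppression halves the plateau at C = m", {
  sp <- bivariate_spec(kinetic_params(1, 0.25, 3),
                       effect_on_Xm = effect_block(1, 5, 2, "attenuate"))
  expect_equal(bivariate_response(sp, 50, 5), 0.5, tolerance = 1e-6)
})

test_that("inhibitory surface is monotone in dose and time", {
  # plateau-only modulation (scenario C) is dose-monotone at every time
  spC <- scenario_spec("C")
  tgC <- seq(0, 30, length.out = 40)
  Cs <- c(0, 0.5, 1, 2, 4, 8)
  surfC <- vapply(Cs, function(C) bivariate_response(spC, tgC, C),
                  numeric(length(tgC)))
  expect_true(all(apply(surfC, 2, function(x) all(diff(x) >= -1e-12))))
  expect_true(all(apply(surfC, 1, function(x) all(diff(x) <= 1e-12))))
  # rate/lag modulation is dose-monotone past the longest modulated lag
  # (a slower rate raises the curve slightly before the lag, by design of
  # the logistic form)
  for (lab in c("A", "E")) {
    sp <- scenario_spec(lab)
    lam_max <- sp$control$lam * (1 + sp$effect_on_lag$K)
    tg <- seq(lam_max, lam_max + 30, length.out = 40)
    surf <- vapply(Cs, function(C) bivariate_response(sp, tg, C),
                   numeric(length(tg)))
    expect_true(all(apply(surf, 2, function(x) all(diff(x) >= -1e-12))))
    expect_true(all(apply(surf, 1, function(x) all(diff(x) <= 1e-12))))
  }
})

test_that("midpoint parameterization modulates the half-max time", {
  ctl <- kinetic_params(1, 0.25, 3)  # tau = 5
  spm <- bivariate_spec(ctl,
                        effect_on_tau = effect_block(1, 2, 2, "amplify"),
                        parameterization = "midpoint")
  # at C = m the tau effect is K/2: tau* = 5 * 1.5 = 7.5
  mod <- modulate(spm, 2)
  expect_equal(mod$lam + mod$Xm / (2 * mod$vm), 7.5)
  # the response at tau* is the (unchanged) half-maximum
  expect_equal(bivariate_response(spm, 7.5, 2), 0.5)
})

test_that("constructors reject invalid parameters", {
  expect_error(kinetic_params(0, 1, 1), "Xm")
  expect_error(kinetic_params(1, -1, 1), "vm")
  expect_error(kinetic_params(1, 1, -0.1), "lam")
  expect_error(kinetic_params(Inf, 1, 1), "finite")
  expect_silent(kinetic_params(1, 1, 0))  # zero lag is legal
  expect_error(effect_block(-0.1, 1, 1), "K")
  expect_error(effect_block(0.5, 0, 1), "m")
  expect_error(effect_block(0.5, 1, 0), "a")
  expect_error(original_logistic_params(1, 1.5, 1), "X0")
  ctl <- kinetic_params(1, 1, 1)
  expect_error(
    bivariate_spec(ctl, effect_on_Xm = effect_block(1.2, 1, 1, "attenuate")),
    "allow_superunity_K")
  expect_silent(
    bivariate_spec(ctl, effect_on_Xm = effect_block(1.2, 1, 1, "attenuate"),
                   allow_superunity_K = TRUE))
  expect_error(
    bivariate_spec(ctl, effect_on_lag = effect_block(1, 1, 1, "attenuate")),
    "amplify")
  expect_error(
    bivariate_spec(ctl,
                   effect_on_lag = effect_block(1, 1, 1, "amplify"),
                   effect_on_tau = effect_block(1, 1, 1, "amplify")),
    "mutually exclusive")
})
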