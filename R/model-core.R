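# Core kinetic model: reparameterized logistic aggregation curve, Weibull
# dose-response effect functions, and their combination into a bivariate
# response surface X(t, C).

#' Kinetic parameters of a single aggregation curve
#'
#' The control logistic triple describing one sigmoid aggregation kinetic:
#' maximum growth, maximum rate (slope at the inflection point) and lag
#' phase (abscissa intercept of the tangent at the inflection point).
#'
#' @param Xm Maximum aggregation growth (signal units, e.g. AU or %). Must
#'   be positive.
#' @param vm Maximum aggregation rate (signal units per time). Must be
#'   positive.
#' @param lam Lag phase (time units, e.g. h or d). Must be non-negative;
#'   curves with no lag are allowed (`lam = 0`), negative lags are not.
#' @return An object of class `kinetic_params`.
#' @examples
#' kp <- kinetic_params(Xm = 1, vm = 0.25, lam = 3)
#' logistic_response(kp, t = c(0, 3, 5, 20))
#' @export
kinetic_params <- function(Xm, vm, lam) {
  stopifnot(is.numeric(Xm), is.numeric(vm), is.numeric(lam),
            length(Xm) == 1L, length(vm) == 1L, length(lam) == 1L)
  if (!all(is.finite(c(Xm, vm, lam))))
    stop("kinetic parameters must be finite", call. = FALSE)
  if (Xm <= 0) stop("Xm must be > 0", call. = FALSE)
  if (vm <= 0) stop("vm must be > 0", call. = FALSE)
  if (lam < 0) stop("lam must be >= 0 (no negative lag phases)", call. = FALSE)
  structure(list(Xm = Xm, vm = vm, lam = lam), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("Kinetic parameters: Xm = %g, vm = %g, lambda = %g\n",
              x$Xm, x$vm, x$lam))
  invisible(x)
}

#' Parameters of the original (autocatalytic) logistic
#'
#' The classical integrated logistic in terms of the initial value `X0` and
#' the apparent rate `kapp`.  Kept as an algebraically equivalent form of
#' the reparameterized curve; see [original_logistic_response()].
#'
#' @param Xm Maximum growth (signal units).
#' @param X0 Initial aggregation value; must satisfy `0 < X0 < Xm`.
#' @param kapp Apparent (specific) rate, 1/time; must be positive.
#' @return An object of class `original_logistic_params`.
#' @export
original_logistic_params <- function(Xm, X0, kapp) {
  stopifnot(length(Xm) == 1L, length(X0) == 1L, length(kapp) == 1L)
  if (!all(is.finite(c(Xm, X0, kapp))))
    stop("parameters must be finite", call. = FALSE)
  if (X0 <= 0 || X0 >= Xm) stop("must have 0 < X0 < Xm", call. = FALSE)
  if (kapp <= 0) stop("kapp must be > 0", call. = FALSE)
  structure(list(Xm = Xm, X0 = X0, kapp = kapp),
            class = "original_logistic_params")
}

#' Weibull dose-response effect block
#'
#' One saturating dose-response function `K * (1 - exp(-ln2 * (C/m)^a))`
#' modulating a single kinetic parameter.  The effect is 0 at zero dose,
#' exactly `K/2` at `C = m` for any shape `a`, and tends to `K` at high
#' dose.  Direction `"attenuate"` multiplies the target parameter by
#' `(1 - effect)` (used for `Xm` and `vm`); `"amplify"` multiplies by
#' `(1 + effect)` (used for the lag phase and for the half-max time in the
#' midpoint parameterization).
#'
#' @param K Maximum fractional response (dimensionless, `>= 0`).
#' @param m Concentration at semi-maximum response (concentration units,
#'   `> 0`).
#' @param a Shape parameter (dimensionless, `> 0`).
#' @param direction `"attenuate"` or `"amplify"`.
#' @return An object of class `effect_block`.
#' @examples
#' eb <- effect_block(K = 0.86, m = 0.47, a = 2.51, direction = "attenuate")
#' weibull_effect(eb, C = c(0, 0.47, 0.94))
#' @export
effect_block <- function(K, m, a, direction = c("attenuate", "amplify")) {
  direction <- match.arg(direction)
  stopifnot(length(K) == 1L, length(m) == 1L, length(a) == 1L)
  if (!all(is.finite(c(K, m, a))))
    stop("effect-block parameters must be finite", call. = FALSE)
  if (K < 0) stop("K must be >= 0", call. = FALSE)
  if (m <= 0) stop("m must be > 0", call. = FALSE)
  if (a <= 0) stop("a must be > 0", call. = FALSE)
  structure(list(K = K, m = m, a = a, direction = direction),
            class = "effect_block")
}

#' Bivariate model specification
#'
#' The control kinetic triple plus optional Weibull effect blocks on each
#' kinetic parameter, defining the full response surface X(t, C).  In the
#' default `"lag"` parameterization the third kinetic coordinate is the lag
#' phase and an amplifying block acts on it directly.  In the `"midpoint"`
#' parameterization the amplifying block instead acts on the half-maximum
#' time `tau = lam + Xm/(2 vm)`; the modulated lag is then recovered as
#' `tau* - Xm*/(2 vm*)`.
#'
#' Attenuating blocks with `K > 1` would drive the modulated `Xm` or `vm`
#' negative at high dose; they are rejected by default and permitted (with
#' validity-range checking at evaluation time) via `allow_superunity_K`,
#' since fitted attenuation maxima slightly above 1 do occur in practice on
#' restricted concentration ranges.
#'
#' @param control A [kinetic_params()] object.
#' @param effect_on_Xm,effect_on_vm Optional attenuating [effect_block()]s.
#' @param effect_on_lag Optional amplifying [effect_block()] on the lag
#'   phase (only with `parameterization = "lag"`).
#' @param effect_on_tau Optional amplifying [effect_block()] on the
#'   half-maximum time (only with `parameterization = "midpoint"`).
#' @param parameterization `"lag"` (default) or `"midpoint"`.
#' @param allow_superunity_K Permit `K > 1` on attenuating blocks.
#' @return An object of class `bivariate_spec`.
#' @examples
#' sp <- bivariate_spec(
#'   control = kinetic_params(1, 0.25, 3),
#'   effect_on_Xm = effect_block(1, 5, 2, "attenuate"))
#' bivariate_response(sp, t = 50, C = 5)
#' @export
bivariate_spec <- function(control,
                           effect_on_Xm = NULL,
                           effect_on_vm = NULL,
                           effect_on_lag = NULL,
                           effect_on_tau = NULL,
                           parameterization = c("lag", "midpoint"),
                           allow_superunity_K = FALSE) {
  parameterization <- match.arg(parameterization)
  if (!inherits(control, "kinetic_params"))
    stop("control must be a kinetic_params object", call. = FALSE)
  for (nm in c("effect_on_Xm", "effect_on_vm", "effect_on_lag",
               "effect_on_tau")) {
    b <- get(nm)
    if (!is.null(b) && !inherits(b, "effect_block"))
      stop(nm, " must be NULL or an effect_block", call. = FALSE)
  }
  if (!is.null(effect_on_lag) && !is.null(effect_on_tau))
    stop("effect_on_lag and effect_on_tau are mutually exclusive",
         call. = FALSE)
  if (parameterization == "midpoint" && !is.null(effect_on_lag))
    stop("midpoint parameterization uses effect_on_tau, not effect_on_lag",
         call. = FALSE)
  if (parameterization == "lag" && !is.null(effect_on_tau))
    stop("lag parameterization uses effect_on_lag, not effect_on_tau",
         call. = FALSE)
  for (b in list(effect_on_Xm, effect_on_vm)) {
    if (!is.null(b)) {
      if (b$direction != "attenuate")
        stop("blocks on Xm and vm must attenuate", call. = FALSE)
      if (!allow_superunity_K && b$K > 1)
        stop("attenuating block with K > 1 requires allow_superunity_K = TRUE",
             call. = FALSE)
    }
  }
  for (b in list(effect_on_lag, effect_on_tau)) {
    if (!is.null(b) && b$direction != "amplify")
      stop("blocks on the lag phase / half-max time must amplify",
           call. = FALSE)
  }
  structure(list(control = control,
                 effect_on_Xm = effect_on_Xm,
                 effect_on_vm = effect_on_vm,
                 effect_on_lag = effect_on_lag,
                 effect_on_tau = effect_on_tau,
                 parameterization = parameterization,
                 allow_superunity_K = allow_superunity_K),
            class = "bivariate_spec")
}

#' @export
print.bivariate_spec <- function(x, ...) {
  cat("Bivariate aggregation-inhibition model\n")
  cat(sprintf("  control: Xm = %g, vm = %g, lambda = %g\n",
              x$control$Xm, x$control$vm, x$control$lam))
  blk <- function(b, lab) {
    if (!is.null(b))
      cat(sprintf("  %s block (%s): K = %g, m = %g, a = %g\n",
                  lab, b$direction, b$K, b$m, b$a))
  }
  blk(x$effect_on_Xm, "Xm")
  blk(x$effect_on_vm, "vm")
  blk(x$effect_on_lag, "lag")
  blk(x$effect_on_tau, "tau")
  cat(sprintf("  parameterization: %s\n", x$parameterization))
  invisible(x)
}

# exponent guard: beyond this the logistic is indistinguishable from its
# asymptote and exp() would overflow
.EXP_GUARD <- 700

#' Reparameterized logistic aggregation curve
#'
#' Evaluates `Xm / (1 + exp(2 + (4 vm / Xm) (lam - t)))`, the logistic
#' growth curve expressed directly in terms of the maximum growth `Xm`, the
#' maximum rate `vm` and the lag phase `lam`.  Exact identities:
#' `X(lam) = Xm / (1 + e^2)` and `X(tau) = Xm / 2` at the half-maximum time
#' `tau = lam + Xm / (2 vm)`.
#'
#' @param params A [kinetic_params()] object.
#' @param t Numeric vector of times (any finite value; `t < lam` is valid).
#' @return Numeric vector of responses, strictly increasing in `t` and
#'   bounded in `(0, Xm)`.
#' @export
logistic_response <- function(params, t) {
  stopifnot(inherits(params, "kinetic_params"))
  if (!all(is.finite(t))) stop("t must be finite", call. = FALSE)
  .logistic(params$Xm, params$vm, params$lam, t)
}

# vectorized workhorse; accepts equal-length parameter vectors
.logistic <- function(Xm, vm, lam, t) {
  z <- 2 + (4 * vm / Xm) * (lam - t)
  z <- pmin(pmax(z, -.EXP_GUARD), .EXP_GUARD)
  Xm / (1 + exp(z))
}

#' Apparent rate from the reparameterized triple
#'
#' The classical apparent (specific) rate `kapp = 4 vm / Xm`, inverting the
#' inflection-slope relation `vm = Xm kapp / 4`.
#'
#' @inheritParams logistic_response
#' @return The apparent rate (1/time).
#' @export
kapp_from <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  4 * params$vm / params$Xm
}

#' Half-maximum time
#'
#' The time at which the curve reaches half its maximum growth,
#' `tau = lam + Xm / (2 vm)`; equivalently `tau = lam + 2 / kapp`.
#'
#' @inheritParams logistic_response
#' @return The half-maximum time.
#' @export
tau_from <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  params$lam + params$Xm / (2 * params$vm)
}

#' Original (autocatalytic) logistic curve
#'
#' Evaluates `Xm / (1 + ((Xm - X0)/X0) exp(-kapp t))`, the integrated form
#' of the autocatalytic rate equation `dX/dt = kapp X (1 - X/Xm)`.  With
#' `kapp = 4 vm / Xm` and `X0 = Xm / (1 + exp(2 + 4 vm lam / Xm))` this is
#' algebraically identical to [logistic_response()]; the package keeps it
#' as an equivalence oracle.
#'
#' @param orig An [original_logistic_params()] object.
#' @param t Numeric vector of times.
#' @return Numeric vector of responses; equals `X0` at `t = 0`.
#' @export
original_logistic_response <- function(orig, t) {
  stopifnot(inherits(orig, "original_logistic_params"))
  if (!all(is.finite(t))) stop("t must be finite", call. = FALSE)
  z <- log((orig$Xm - orig$X0) / orig$X0) - orig$kapp * t
  z <- pmin(pmax(z, -.EXP_GUARD), .EXP_GUARD)
  orig$Xm / (1 + exp(z))
}

#' Weibull dose-response effect
#'
#' Evaluates `K * (1 - exp(-ln2 * (C/m)^a))`: zero at `C = 0`,
#' non-decreasing in `C`, exactly `K/2` at `C = m` for any shape `a`, and
#' tending to `K` as `C` grows.
#'
#' @param block An [effect_block()] object.
#' @param C Numeric vector of concentrations, `>= 0`.
#' @return Numeric vector of effect fractions (dimensionless).
#' @export
weibull_effect <- function(block, C) {
  stopifnot(inherits(block, "effect_block"))
  if (any(!is.finite(C)) || any(C < 0))
    stop("C must be finite and >= 0", call. = FALSE)
  .weibull(block$K, block$m, block$a, C)
}

.weibull <- function(K, m, a, C) {
  K * (1 - exp(-log(2) * (C / m)^a))
}

# Modulated (Xm*, vm*, lam*) at each concentration, vectorized over C.
# No validity checks: used by the fitting residual where out-of-range
# iterates must still evaluate.  Returns a list of vectors.
.modulated <- function(spec, C) {
  ctl <- spec$control
  n <- length(C)
  Xm <- rep.int(ctl$Xm, n)
  vm <- rep.int(ctl$vm, n)
  if (!is.null(spec$effect_on_Xm)) {
    b <- spec$effect_on_Xm
    Xm <- Xm * (1 - .weibull(b$K, b$m, b$a, C))
  }
  if (!is.null(spec$effect_on_vm)) {
    b <- spec$effect_on_vm
    vm <- vm * (1 - .weibull(b$K, b$m, b$a, C))
  }
  if (spec$parameterization == "midpoint") {
    tau <- ctl$lam + ctl$Xm / (2 * ctl$vm)
    if (!is.null(spec$effect_on_tau)) {
      b <- spec$effect_on_tau
      tau <- tau * (1 + .weibull(b$K, b$m, b$a, C))
    } else tau <- rep.int(tau, n)
    lam <- tau - Xm / (2 * vm)
  } else {
    lam <- rep.int(ctl$lam, n)
    if (!is.null(spec$effect_on_lag)) {
      b <- spec$effect_on_lag
      lam <- lam * (1 + .weibull(b$K, b$m, b$a, C))
    }
  }
  list(Xm = Xm, vm = vm, lam = lam)
}

#' Kinetic parameters modulated by an inhibitor concentration
#'
#' Applies the spec's Weibull effect blocks at concentration `C`:
#' `Xm* = Xm (1 - effect_x(C))`, `vm* = vm (1 - effect_v(C))`,
#' `lam* = lam (1 + effect_lam(C))` (or the tau-based rule in the midpoint
#' parameterization).  Absent blocks leave their parameter unchanged.
#'
#' @param spec A [bivariate_spec()] object (the control triple is taken
#'   from it).
#' @param C A single concentration, `>= 0`.
#' @return A [kinetic_params()] object with the modulated triple.
#'   Errors if the modulated `Xm*` or `vm*` is not positive at `C`
#'   (outside the model's validity range, possible only with
#'   super-unity `K`).
#' @export
modulate <- function(spec, C) {
  stopifnot(inherits(spec, "bivariate_spec"), length(C) == 1L)
  if (!is.finite(C) || C < 0) stop("C must be finite and >= 0", call. = FALSE)
  mod <- .modulated(spec, C)
  if (mod$Xm <= 0 || mod$vm <= 0)
    stop(sprintf(paste0("modulated parameters out of validity range at ",
                        "C = %g (Xm* = %g, vm* = %g); restrict the ",
                        "concentration range"), C, mod$Xm, mod$vm),
         call. = FALSE)
  p <- structure(list(Xm = mod$Xm, vm = mod$vm, lam = mod$lam),
                 class = "kinetic_params")
  if (mod$lam < 0)
    attr(p, "range_warning") <-
      sprintf("modulated lag is negative (%g) at C = %g", mod$lam, C)
  p
}

#' Bivariate aggregation-inhibition response surface
#'
#' Evaluates the full model `X(t, C)`: the logistic curve with kinetic
#' parameters modulated by the Weibull dose-response blocks at each
#' concentration.  At `C = 0` it reduces exactly to the control curve.
#'
#' @param spec A [bivariate_spec()] object.
#' @param t,C Numeric vectors of times and concentrations, recycled to a
#'   common length.
#' @return Numeric vector of responses.
#' @export
bivariate_response <- function(spec, t, C) {
  stopifnot(inherits(spec, "bivariate_spec"))
  if (!all(is.finite(t))) stop("t must be finite", call. = FALSE)
  if (any(!is.finite(C)) || any(C < 0))
    stop("C must be finite and >= 0", call. = FALSE)
  n <- max(length(t), length(C))
  t <- rep_len(t, n)
  C <- rep_len(C, n)
  mod <- .modulated(spec, C)
  bad <- mod$Xm <= 0 | mod$vm <= 0
  if (any(bad))
    stop(sprintf(paste0("modulated parameters out of validity range at ",
                        "C = %g; restrict the concentration range"),
                 C[which(bad)[1L]]), call. = FALSE)
  .logistic(mod$Xm, mod$vm, mod$lam, t)
}

# Prediction used inside the fitting residual: clamps non-positive
# modulated Xm*/vm* at a tiny floor so that out-of-range trial iterates
# still yield finite residuals.
.predict_clamped <- function(spec, t, C, floor = 1e-12) {
  mod <- .modulated(spec, C)
  .logistic(pmax(mod$Xm, floor), pmax(mod$vm, floor), mod$lam, t)
}
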