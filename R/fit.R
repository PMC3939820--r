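# Nonlinear least-squares estimation of the bivariate model, linearized
# confidence intervals, and significance-based pruning of effect blocks.

# block slots and the parameter-name prefix used for each
.BLOCK_SLOTS <- c(effect_on_Xm = "x", effect_on_vm = "v",
                  effect_on_lag = "l", effect_on_tau = "t")

.block_par_names <- function(slot) {
  sfx <- .BLOCK_SLOTS[[slot]]
  paste0(c("K", "m", "a"), sfx)
}

# flatten the free parameters of a spec into a named vector
.spec_to_par <- function(spec) {
  par <- c(Xm = spec$control$Xm, vm = spec$control$vm, lam = spec$control$lam)
  for (slot in names(.BLOCK_SLOTS)) {
    b <- spec[[slot]]
    if (!is.null(b)) {
      v <- c(b$K, b$m, b$a)
      names(v) <- .block_par_names(slot)
      par <- c(par, v)
    }
  }
  par
}

# rebuild a spec from a parameter vector, using `template` for structure;
# skips constructor validation (optimizer iterates may sit on bounds)
.par_to_spec <- function(par, template) {
  spec <- template
  spec$control <- structure(
    list(Xm = par[["Xm"]], vm = par[["vm"]], lam = par[["lam"]]),
    class = "kinetic_params")
  for (slot in names(.BLOCK_SLOTS)) {
    if (!is.null(template[[slot]])) {
      nm <- .block_par_names(slot)
      spec[[slot]]$K <- par[[nm[1]]]
      spec[[slot]]$m <- par[[nm[2]]]
      spec[[slot]]$a <- par[[nm[3]]]
    }
  }
  spec
}

# default box constraints for a model structure
.default_bounds <- function(template, K_max) {
  par <- .spec_to_par(template)
  lower <- upper <- par
  lower[] <- -Inf; upper[] <- Inf
  lower[c("Xm", "vm")] <- 1e-10
  lower["lam"] <- 0
  for (slot in names(.BLOCK_SLOTS)) {
    b <- template[[slot]]
    if (is.null(b)) next
    nm <- .block_par_names(slot)
    lower[nm] <- c(0, 1e-10, 1e-3)
    att <- b$direction == "attenuate"
    upper[nm[1]] <- if (!att) Inf else if (template$allow_superunity_K)
      K_max else 1
    upper[nm[3]] <- 100
  }
  list(lower = lower, upper = upper)
}

#' Fitting options
#'
#' @param alpha Significance level for confidence intervals and pruning
#'   (default 0.05).
#' @param max_iter Iteration cap for the Levenberg-Marquardt optimizer.
#' @param ftol,ptol Relative tolerances on the sum of squares and on the
#'   parameters for convergence.
#' @param multistart Number of starts: the heuristic initial guess plus
#'   `multistart - 1` multiplicatively jittered copies.  Ignored when
#'   `start` is supplied (that start is used alone).
#' @param jitter Relative amplitude of the multistart jitter (default 0.2).
#' @param start Optional named vector of initial values overriding the
#'   heuristic (partial override allowed).
#' @param seed Integer seed for the multistart jitter.
#' @param lower,upper Optional named vectors overriding default parameter
#'   bounds.
#' @param K_max Upper bound on attenuating-block `K` when the spec allows
#'   super-unity `K`.
#' @param verbose Print per-start convergence diagnostics.
#' @return An object of class `fit_options`.
#' @export
fit_options <- function(alpha = 0.05, max_iter = 1000,
                        ftol = 1e-12, ptol = 1e-12,
                        multistart = 5, jitter = 0.2,
                        start = NULL, seed = 1,
                        lower = NULL, upper = NULL,
                        K_max = 5, verbose = FALSE) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (ftol <= 0 || ptol <= 0) stop("tolerances must be > 0", call. = FALSE)
  structure(list(alpha = alpha, max_iter = max_iter, ftol = ftol,
                 ptol = ptol, multistart = multistart, jitter = jitter,
                 start = start, seed = as.integer(seed),
                 lower = lower, upper = upper, K_max = K_max,
                 verbose = verbose),
            class = "fit_options")
}

# crude single-series kinetic estimates: plateau, max slope, lag
.series_stats <- function(tt, yy) {
  o <- order(tt)
  tt <- tt[o]; yy <- yy[o]
  Xs <- max(yy)
  dr <- diff(yy) / diff(tt)
  vs <- max(dr[is.finite(dr)], 0)
  idx <- which(yy > 0.1 * Xs)
  t10 <- if (length(idx)) tt[idx[1]] else max(tt)
  ls <- if (vs > 0) max(t10 - 0.2 * Xs / (2 * vs), 0) else 0
  c(Xs = Xs, vs = vs, ls = ls)
}

# read K and m off an empirical effect-fraction profile eff(C):
# K from the largest dose, m from interpolating the half-K crossing
.block_guess <- function(Cs, eff, fallback_m) {
  eff[!is.finite(eff)] <- 0
  K0 <- max(eff[length(eff)], 0.2)
  half <- K0 / 2
  above <- which(eff >= half)
  m0 <- if (length(above) && above[1] > 1) {
    i <- above[1]
    exp(stats::approx(eff[c(i - 1, i)], log(Cs[c(i - 1, i)]),
                      xout = half, ties = "ordered")$y)
  } else if (length(above)) Cs[1] else fallback_m
  if (!is.finite(m0) || m0 <= 0) m0 <- fallback_m
  c(K0, m0, 1)
}

# initial-guess heuristic: control triple from the control series; block
# (K, m) read off the per-series kinetic estimates relative to the control
.heuristic_start <- function(data, template) {
  ctl <- data[data$concentration == 0, , drop = FALSE]
  s0 <- .series_stats(ctl$time, ctl$response)
  Xm0 <- s0[["Xs"]]
  if (Xm0 <= 0) Xm0 <- max(data$response, 1e-3)
  vm0 <- s0[["vs"]]
  if (vm0 <= 0) vm0 <- Xm0 / max(diff(range(ctl$time)), 1)
  lam0 <- s0[["ls"]]
  par <- c(Xm = Xm0, vm = vm0, lam = lam0)

  Cs <- sort(unique(data$concentration[data$concentration > 0]))
  m_fb <- if (length(Cs)) stats::median(Cs) else 1
  stats_by_C <- vapply(Cs, function(C) {
    sub <- data[data$concentration == C, , drop = FALSE]
    .series_stats(sub$time, sub$response)
  }, numeric(3))
  for (slot in names(.BLOCK_SLOTS)) {
    if (is.null(template[[slot]])) next
    guess <- if (length(Cs) == 0L) c(0.5, m_fb, 1) else switch(slot,
      effect_on_Xm = .block_guess(
        Cs, pmin(pmax(1 - stats_by_C["Xs", ] / Xm0, 0), 0.99), m_fb),
      effect_on_vm = .block_guess(
        Cs, pmin(pmax(1 - stats_by_C["vs", ] / vm0, 0), 0.99), m_fb),
      effect_on_lag = .block_guess(
        Cs, if (lam0 > 0) pmax(stats_by_C["ls", ] / lam0 - 1, 0)
            else rep(0, length(Cs)), m_fb),
      effect_on_tau = {
        tau_C <- stats_by_C["ls", ] +
          stats_by_C["Xs", ] / (2 * pmax(stats_by_C["vs", ], 1e-12))
        tau0 <- lam0 + Xm0 / (2 * vm0)
        .block_guess(Cs, pmax(tau_C / tau0 - 1, 0), m_fb)
      })
    names(guess) <- .block_par_names(slot)
    par <- c(par, guess)
  }
  par
}

# central-difference Jacobian of the model surface wrt the parameters
.model_jacobian <- function(par, template, t, C, rel = 1e-6) {
  p <- length(par)
  J <- matrix(0, nrow = length(t), ncol = p,
              dimnames = list(NULL, names(par)))
  for (j in seq_len(p)) {
    h <- rel * max(abs(par[j]), 1e-6)
    pp <- pm <- par
    pp[j] <- par[j] + h
    pm[j] <- par[j] - h
    J[, j] <- (.predict_clamped(.par_to_spec(pp, template), t, C) -
               .predict_clamped(.par_to_spec(pm, template), t, C)) / (2 * h)
  }
  J
}

# Moore-Penrose inverse via SVD; returns list(inv, rank)
.pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d, 0)
  inv <- s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
  list(inv = inv, rank = sum(keep))
}

#' Fit the bivariate aggregation-inhibition model
#'
#' Estimates all free parameters of a model structure (control triple plus
#' whichever effect blocks the `config` spec declares) by unweighted
#' nonlinear least squares (Levenberg-Marquardt, with optional multistart).
#' Standard errors come from the linearized covariance
#' `s^2 (J'J)^{-1}` with `s^2 = SSE/(n - p)` and `J` the model Jacobian at
#' the solution; confidence intervals use the Student t quantile with
#' `n - p` degrees of freedom.
#'
#' @param data A [kinetic_dataset()] (or a data frame with `time`,
#'   `concentration`, `response` columns).  Must contain a
#'   zero-concentration control series; row order is irrelevant.
#' @param config A [bivariate_spec()] declaring the model structure; its
#'   parameter values serve only as a structural template (starts come from
#'   the heuristic or `options$start`).
#' @param options A [fit_options()] object.
#' @return An object of class `agg_fit` with components `estimates`, `se`,
#'   `ci_halfwidth`, `covariance`, `correlation`, `residuals`, `fitted`,
#'   `sse`, `n`, `p`, `converged`, `rank_deficient`, `pruned`, `gof`,
#'   `spec` (the fitted model as a `bivariate_spec`) and bookkeeping
#'   fields.
#' @examples
#' sp <- scenario_spec("C")
#' d <- generate_dataset(sp)
#' f <- fit_bivariate(d, sp, fit_options(multistart = 1))
#' coef(f)
#' @export
fit_bivariate <- function(data, config, options = fit_options()) {
  stopifnot(inherits(config, "bivariate_spec"))
  if (!inherits(options, "fit_options"))
    stop("options must be a fit_options object", call. = FALSE)
  if (!inherits(data, "kinetic_dataset")) data <- kinetic_dataset(data)
  .check_series_depth(data)

  template <- config
  # degenerate design: control series only -> control-only logistic fit
  if (length(unique(data$concentration)) == 1L &&
      .n_blocks(template) > 0L) {
    warning("single concentration series: falling back to control-only fit",
            call. = FALSE)
    template <- bivariate_spec(control = template$control,
                               parameterization = template$parameterization)
  }

  par0 <- .heuristic_start(data, template)
  p <- length(par0)
  n <- nrow(data)
  if (n < p + 3)
    stop(sprintf("insufficient data: n = %d records for p = %d parameters",
                 n, p), call. = FALSE)

  bounds <- .default_bounds(template, options$K_max)
  lower <- bounds$lower; upper <- bounds$upper
  if (!is.null(options$lower)) lower[names(options$lower)] <- options$lower
  if (!is.null(options$upper)) upper[names(options$upper)] <- options$upper

  if (!is.null(options$start)) {
    bad <- setdiff(names(options$start), names(par0))
    if (length(bad))
      stop("unknown start parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    par0[names(options$start)] <- options$start
  }
  starts <- list(par0)
  if (options$multistart > 1) {
    jit <- withr::with_seed(options$seed, {
      lapply(seq_len(options$multistart - 1), function(i)
        par0 * (1 + stats::runif(p, -options$jitter, options$jitter)))
    })
    starts <- c(starts, jit)
  }
  # clamp starts to the strict interior of the box: the LM implementation
  # stalls when a start sits exactly on an active bound
  margin <- pmax(1e-8, 1e-3 * pmax(1, abs(par0)))
  lo_in <- ifelse(is.finite(lower), lower + margin, lower)
  hi_in <- ifelse(is.finite(upper), upper - margin, upper)
  starts <- lapply(starts, function(s) pmin(pmax(s, lo_in), hi_in))

  tt <- data$time; cc <- data$concentration; obs <- data$response
  resid_fun <- function(par) {
    obs - .predict_clamped(.par_to_spec(par, template), tt, cc)
  }

  best <- NULL
  ctrl <- minpack.lm::nls.lm.control(maxiter = options$max_iter,
                                     ftol = options$ftol,
                                     ptol = options$ptol)
  for (i in seq_along(starts)) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = starts[[i]], lower = lower, upper = upper,
                         fn = resid_fun, control = ctrl),
      error = function(e) NULL)
    if (is.null(res)) next
    sse_i <- res$deviance
    if (options$verbose)
      message(sprintf("start %d: SSE = %.6g, info = %d (%d iter)",
                      i, sse_i, res$info, res$niter))
    if (is.null(best) || sse_i < best$deviance) best <- res
  }
  if (is.null(best))
    stop("all optimizer starts failed", call. = FALSE)

  est <- best$par
  converged <- best$info %in% 1:4
  fitted <- .predict_clamped(.par_to_spec(est, template), tt, cc)
  resid <- obs - fitted
  sse <- sum(resid^2)
  dfree <- n - p
  s2 <- sse / dfree

  J <- .model_jacobian(est, template, tt, cc)
  JtJ <- crossprod(J)
  pv <- .pinv(JtJ)
  rank_deficient <- pv$rank < p
  if (rank_deficient)
    warning("rank-deficient Jacobian: some parameters are unidentifiable; ",
            "their standard errors are unreliable", call. = FALSE)
  covariance <- s2 * pv$inv
  dimnames(covariance) <- list(names(est), names(est))
  se <- sqrt(pmax(diag(covariance), 0))
  if (rank_deficient) {
    # flag unidentifiable directions with undefined SEs
    null_dir <- abs(diag(pv$inv %*% JtJ) - 1) > 1e-6
    se[null_dir] <- NA_real_
  }
  denom <- outer(se, se)
  correlation <- ifelse(denom > 0, covariance / denom, NA_real_)
  ci_half <- stats::qt(1 - options$alpha / 2, dfree) * se

  gof <- gof_stats(obs, fitted, p = p)

  structure(list(
    estimates = est, se = se, ci_halfwidth = ci_half,
    alpha = options$alpha,
    covariance = covariance, correlation = correlation,
    residuals = resid, fitted = fitted,
    sse = sse, n = n, p = p, df = dfree,
    converged = converged, niter = best$niter,
    rank_deficient = rank_deficient,
    pruned = list(),
    gof = gof,
    spec = .par_to_spec(est, template),
    template = template,
    options = options,
    data = data,
    trace = best$rsstrace), class = "agg_fit")
}

.n_blocks <- function(spec) {
  sum(!vapply(spec[names(.BLOCK_SLOTS)], is.null, logical(1)))
}

#' @export
coef.agg_fit <- function(object, ...) object$estimates

#' @export
residuals.agg_fit <- function(object, ...) object$residuals

#' @export
fitted.agg_fit <- function(object, ...) object$fitted

#' @export
vcov.agg_fit <- function(object, ...) object$covariance

#' @export
print.agg_fit <- function(x, ...) {
  cat(sprintf("Bivariate aggregation model fit: %d records, %d parameters\n",
              x$n, x$p))
  ci <- confidence_intervals(x)
  print(format(ci, digits = 4), row.names = FALSE)
  cat(sprintf("SSE = %.4g | R2_adj = %.4f | DW = %.3f | Bf = %.3f | Af = %.3f\n",
              x$sse, x$gof$r2_adj, x$gof$dw, x$gof$bf, x$gof$af))
  if (!x$converged) cat("WARNING: optimizer did not converge\n")
  if (length(x$pruned))
    cat("Pruned blocks:",
        paste(vapply(x$pruned, `[[`, character(1), "block"),
              collapse = ", "), "\n")
  invisible(x)
}

#' Per-parameter confidence intervals of a fit
#'
#' Symmetric Student-t intervals: half-width `qt(1 - alpha/2, n - p) * SE`.
#' Parameters with undefined standard errors (rank-deficient fits) get `NA`
#' bounds and are marked unavailable.
#'
#' @param fit An `agg_fit` object.
#' @param alpha Significance level (defaults to the level used in the fit).
#' @return A data frame with columns `parameter`, `estimate`, `se`,
#'   `halfwidth`, `lower`, `upper`, `ns` (CI includes zero or SE
#'   undefined).
#' @export
confidence_intervals <- function(fit, alpha = fit$alpha) {
  stopifnot(inherits(fit, "agg_fit"))
  hw <- stats::qt(1 - alpha / 2, fit$df) * fit$se
  data.frame(parameter = names(fit$estimates),
             estimate = unname(fit$estimates),
             se = unname(fit$se),
             halfwidth = unname(hw),
             lower = unname(fit$estimates - hw),
             upper = unname(fit$estimates + hw),
             ns = unname(is.na(fit$se) |
                           abs(fit$estimates) <= hw | !is.finite(hw)),
             stringsAsFactors = FALSE)
}

#' Fit with significance-based pruning of effect blocks
#'
#' Fits the full declared model, then iteratively removes non-significant
#' effect blocks.  A block counts as significant only if both checks pass:
#'
#' * the confidence interval of its maximum-response parameter `K`
#'   excludes zero (Student t, level `alpha`) -- with `K = 0` the block's
#'   `m` and `a` are unidentifiable, so `K` is the well-posed parameter to
#'   test; and
#' * dropping the whole block significantly worsens the fit (nested-model
#'   F test on the three block parameters at the same level).  This guards
#'   the Wald test on `K` against its degenerate failure mode: a spurious
#'   block can park `m` beyond the observed dose range with `K` pinned at
#'   a bound, producing a tiny (meaningless) linearized SE for `K` while
#'   contributing nothing to the fit.
#'
#' The least-significant non-significant block (largest drop-test p-value)
#' is removed first and the reduced model refit, until every remaining
#' block is significant.  If all blocks fall, the control-only logistic
#' fit is returned (a valid outcome, not an error).
#'
#' @inheritParams fit_bivariate
#' @return An `agg_fit` whose `pruned` component lists each removed block
#'   with its triggering statistics.
#' @export
prune_nonsignificant <- function(data, config, options = fit_options()) {
  stopifnot(inherits(config, "bivariate_spec"))
  template <- config
  pruned <- list()
  repeat {
    fit <- fit_bivariate(data, template, options)
    template <- fit$template
    slots <- names(.BLOCK_SLOTS)[!vapply(fit$template[names(.BLOCK_SLOTS)],
                                         is.null, logical(1))]
    if (!length(slots)) break
    crit <- stats::qt(1 - options$alpha / 2, fit$df)
    stat <- lapply(slots, function(slot) {
      kname <- .block_par_names(slot)[1]
      k <- fit$estimates[[kname]]
      s <- fit$se[[kname]]
      tstat <- if (!is.finite(s) || s == 0) 0 else abs(k) / s
      wald_sig <- tstat >= crit
      f_p <- NA_real_
      if (wald_sig) {
        # confirm by the drop-one-block nested comparison
        red <- template
        red[[slot]] <- NULL
        red <- structure(red, class = "bivariate_spec")
        red_opts <- options
        red_opts$start <- fit$estimates[setdiff(names(fit$estimates),
                                                .block_par_names(slot))]
        red_fit <- tryCatch(
          suppressWarnings(fit_bivariate(data, red, red_opts)),
          error = function(e) NULL)
        if (!is.null(red_fit)) {
          dsse <- max(red_fit$sse - fit$sse, 0)
          s2 <- fit$sse / fit$df
          f <- if (s2 > 0) (dsse / 3) / s2 else Inf
          f_p <- stats::pf(f, 3, fit$df, lower.tail = FALSE)
        } else f_p <- 0  # reduced model unfittable: keep the block
      }
      list(t = tstat, wald_sig = wald_sig, f_p = f_p)
    })
    names(stat) <- slots
    ns <- vapply(stat, function(s)
      !s$wald_sig || (is.finite(s$f_p) && s$f_p > options$alpha),
      logical(1))
    if (!any(ns)) break
    # least significant first: failed Wald ranks by t, then by drop p
    ord_key <- vapply(stat, function(s)
      if (!s$wald_sig) -1 / (1 + s$t) else -s$f_p, numeric(1))
    drop_slot <- slots[ns][which.min(ord_key[ns])]
    s <- stat[[drop_slot]]
    kname <- .block_par_names(drop_slot)[1]
    pruned[[length(pruned) + 1L]] <- list(
      block = sub("effect_on_", "", drop_slot),
      K = unname(fit$estimates[[kname]]),
      se = unname(fit$se[[kname]]),
      t = s$t, t_critical = crit, df = fit$df,
      drop_f_pvalue = s$f_p,
      reason = if (!s$wald_sig) "K confidence interval includes 0"
               else "dropping the block does not worsen the fit")
    template[[drop_slot]] <- NULL
    template <- structure(template, class = "bivariate_spec")
  }
  fit$pruned <- pruned
  fit
}
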