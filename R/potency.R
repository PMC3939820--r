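# Global potency index EC50 at the control half-maximum time tau.

#' Half-inhibitory concentration at the control half-max time
#'
#' The global potency index: the inhibitor concentration that halves the
#' aggregation response relative to the untreated control at the reference
#' time `tau` at which the control itself reaches half its maximum growth
#' (`tau = lam + Xm/(2 vm)` of the control triple).  The root of
#' `X(tau, C)/X(tau, 0) = 1/2` is located by bracketing bisection on
#' `(0, C_max]` to a relative tolerance of `1e-6`.
#'
#' With `method = "closed_form_a12"` the returned reference time is instead
#' the closed-form expression `tau* - Xm* ln(3) / (4 vm*)` evaluated with
#' the modulated parameters at the solution concentration (the time at
#' which the inhibited curve reaches a quarter of its modulated maximum);
#' the EC50 itself is still located numerically.
#'
#' @param spec A [bivariate_spec()].  A spec without effect blocks yields
#'   an unattained result (the dose-response ratio is identically 1).
#' @param method `"numerical"` (canonical) or `"closed_form_a12"`.
#' @param C_max Upper end of the concentration search interval; defaults to
#'   100 times the largest semi-maximum concentration `m` among the
#'   spec's effect blocks.
#' @return An object of class `potency_result` with fields `ec50`, `tau`,
#'   `method`, `bracket`, `achieved_ratio` and `attained`.  If the
#'   inhibition never halves the response on `(0, C_max]` the result has
#'   `attained = FALSE` and `ec50 = NA` (not an error).
#' @examples
#' sp <- bivariate_spec(kinetic_params(1, 0.25, 3),
#'                      effect_on_Xm = effect_block(1, 5, 2, "attenuate"))
#' ec50_tau(sp)
#' @export
ec50_tau <- function(spec, method = c("numerical", "closed_form_a12"),
                     C_max = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "bivariate_spec"))
  if (.n_blocks(spec) < 1L) {
    # no dose effect at all: the ratio is identically 1, never halved
    tau <- tau_from(spec$control)
    return(structure(list(ec50 = NA_real_, tau = tau, method = method,
                          bracket = c(0, if (is.null(C_max)) Inf else C_max),
                          achieved_ratio = 1, attained = FALSE),
                     class = "potency_result"))
  }
  if (is.null(C_max)) {
    ms <- vapply(Filter(Negate(is.null),
                        spec[names(.BLOCK_SLOTS)]), `[[`, numeric(1), "m")
    C_max <- 100 * max(ms)
  }
  if (C_max <= 0) stop("C_max must be > 0", call. = FALSE)

  tau <- tau_from(spec$control)
  x0 <- bivariate_response(spec, tau, 0)
  ratio <- function(C) {
    # out-of-validity concentrations (super-unity K) count as full
    # suppression for the purpose of bracketing
    tryCatch(bivariate_response(spec, tau, C) / x0, error = function(e) 0)
  }
  f <- function(C) ratio(C) - 0.5

  f_hi <- f(C_max)
  if (f_hi > 0) {
    return(structure(list(ec50 = NA_real_, tau = tau, method = method,
                          bracket = c(0, C_max),
                          achieved_ratio = f_hi + 0.5,
                          attained = FALSE), class = "potency_result"))
  }
  lo <- 0; hi <- C_max  # f(0+) = 0.5 > 0, f(hi) <= 0
  repeat {
    mid <- (lo + hi) / 2
    if (mid <= lo || mid >= hi) break  # no representable midpoint left
    if (f(mid) > 0) lo <- mid else hi <- mid
    if ((hi - lo) <= 1e-6 * hi) break
  }
  ec50 <- (lo + hi) / 2

  tau_report <- tau
  if (method == "closed_form_a12") {
    mod <- modulate(spec, ec50)
    tau_star <- mod$lam + mod$Xm / (2 * mod$vm)  # modulated half-max time
    tau_report <- tau_star - mod$Xm * log(3) / (4 * mod$vm)
  }

  structure(list(ec50 = ec50, tau = tau_report, method = method,
                 bracket = c(0, C_max),
                 achieved_ratio = ratio(ec50),
                 attained = TRUE), class = "potency_result")
}

#' @export
print.potency_result <- function(x, ...) {
  if (x$attained) {
    cat(sprintf("EC50,tau = %.6g at tau = %.6g (method: %s, ratio = %.6f)\n",
                x$ec50, x$tau, x$method, x$achieved_ratio))
  } else {
    cat(sprintf(paste0("EC50 not attained on (0, %g]: inhibition never ",
                       "halves the response (ratio at C_max = %.4f)\n"),
                x$bracket[2], x$achieved_ratio))
  }
  invisible(x)
}
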