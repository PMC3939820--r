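# Goodness-of-fit battery: adjusted R2, Fisher F consistency test,
# Durbin-Watson statistic, and the bias/accuracy factors of Ross.

#' Adjusted coefficient of determination
#'
#' `R2_adj = 1 - (1 - R2) (n - 1)/(n - p)` with `R2 = 1 - SSE/SST`, SST
#' about the observed mean.  The denominator uses `n - p` (not
#' `n - p - 1`): the nonlinear model has no separate intercept term, so all
#' `p` parameters are counted alike.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @param p Number of fitted parameters; requires `n > p + 1`.
#' @return The adjusted R-squared (`<= 1`; can be negative).  `NA` with a
#'   warning when the observations have zero variance.
#' @export
r2_adjusted <- function(observed, predicted, p) {
  .check_pair(observed, predicted)
  n <- length(observed)
  if (n <= p + 1) stop("need n > p + 1", call. = FALSE)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) {
    warning("zero total variance: adjusted R2 undefined", call. = FALSE)
    return(NA_real_)
  }
  sse <- sum((observed - predicted)^2)
  r2 <- 1 - sse / sst
  1 - (1 - r2) * (n - 1) / (n - p)
}

#' Fisher F consistency test
#'
#' The spreadsheet-era consistency heuristic: `F = (regression mean
#' square)/(residual mean square)` with regression SS taken about the
#' observed mean, `F = (sum((pred - mean(obs))^2)/p) / (SSE/(n - p))`, and
#' the p-value from the upper tail of the F distribution with `(p, n - p)`
#' degrees of freedom.  This is a heuristic check that the model captures
#' the signal, not a nested-model test.
#'
#' @inheritParams r2_adjusted
#' @return The upper-tail p-value.  A perfect fit (SSE = 0) reports 0.
#' @export
fisher_f_pvalue <- function(observed, predicted, p) {
  .check_pair(observed, predicted)
  n <- length(observed)
  if (n <= p) stop("need n > p", call. = FALSE)
  sse <- sum((observed - predicted)^2)
  if (sse == 0) return(0)
  ssr <- sum((predicted - mean(observed))^2)
  f <- (ssr / p) / (sse / (n - p))
  stats::pf(f, p, n - p, lower.tail = FALSE)
}

#' Durbin-Watson statistic
#'
#' `DW = sum(diff(e)^2) / sum(e^2)` on an ordered residual sequence; ranges
#' from 0 (perfect positive first-order autocorrelation) to 4 (perfect
#' negative), with white noise near 2.  For pooled multi-series fits the
#' package orders residuals concentration series by concentration series
#' (ascending dose), each series by time, since autocorrelation is
#' meaningful within a kinetic trace.
#'
#' @param residuals Ordered numeric vector, length `>= 2`.
#' @return The DW statistic; `NA` with a warning if all residuals are zero.
#' @export
durbin_watson <- function(residuals) {
  if (length(residuals) < 2) stop("need >= 2 residuals", call. = FALSE)
  if (any(!is.finite(residuals)))
    stop("residuals must be finite", call. = FALSE)
  denom <- sum(residuals^2)
  if (denom == 0) {
    warning("all residuals zero: Durbin-Watson undefined", call. = FALSE)
    return(NA_real_)
  }
  sum(diff(residuals)^2) / denom
}

#' Bias and accuracy factors
#'
#' Log-ratio summaries of systematic and absolute prediction error:
#' `Bf = 10^mean(log10(pred/obs))` and `Af = 10^mean(|log10(pred/obs)|)`.
#' Both equal 1 for a perfect fit; `Af >= 1` always and `Af >= max(Bf,
#' 1/Bf)`.  Pairs with a non-positive observed or predicted value are
#' excluded (the log-ratio is undefined there); if more than 10% of pairs
#' would be excluded the computation aborts instead.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return A list with components `bf`, `af` and `n_excluded`.
#' @export
bias_accuracy_factors <- function(observed, predicted) {
  .check_pair(observed, predicted)
  ok <- observed > 0 & predicted > 0
  n_excl <- sum(!ok)
  if (n_excl > 0.1 * length(observed))
    stop(sprintf(paste0("%d of %d pairs have non-positive values; ",
                        "bias/accuracy factors are log-ratio based and ",
                        "need positive responses"),
                 n_excl, length(observed)), call. = FALSE)
  lr <- log10(predicted[ok] / observed[ok])
  list(bf = 10^mean(lr), af = 10^mean(abs(lr)), n_excluded = n_excl)
}

#' Full goodness-of-fit battery
#'
#' Bundles [r2_adjusted()], [fisher_f_pvalue()], [durbin_watson()] (on
#' `observed - predicted` in the order supplied), [bias_accuracy_factors()]
#' and the root-mean-square error.
#'
#' @inheritParams r2_adjusted
#' @return An object of class `gof_stats`: a list with `r2_adj`,
#'   `f_pvalue`, `dw`, `bf`, `af`, `rmse`, `n_excluded`.
#' @export
gof_stats <- function(observed, predicted, p) {
  resid <- observed - predicted
  ba <- tryCatch(bias_accuracy_factors(observed, predicted),
                 error = function(e) list(bf = NA_real_, af = NA_real_,
                                          n_excluded = NA_integer_))
  structure(list(
    r2_adj = r2_adjusted(observed, predicted, p),
    f_pvalue = fisher_f_pvalue(observed, predicted, p),
    dw = suppressWarnings(durbin_watson(resid)),
    bf = ba$bf, af = ba$af, n_excluded = ba$n_excluded,
    rmse = sqrt(mean(resid^2))), class = "gof_stats")
}

#' @export
print.gof_stats <- function(x, ...) {
  cat(sprintf(
    "GOF: R2_adj = %.4f | F p-value = %.3g | DW = %.3f | Bf = %.3f | Af = %.3f | RMSE = %.4g\n",
    x$r2_adj, x$f_pvalue, x$dw, x$bf, x$af, x$rmse))
  invisible(x)
}

.check_pair <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length", call. = FALSE)
  if (any(!is.finite(observed)) || any(!is.finite(predicted)))
    stop("observed and predicted must be finite", call. = FALSE)
  invisible(TRUE)
}
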