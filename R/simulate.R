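# Synthetic-data generation: noise models, default experiment designs and
# dataset construction/validation.

#' Noise model for synthetic datasets
#'
#' @param kind `"none"`, `"gaussian_additive"` (constant standard
#'   deviation `sigma` in signal units) or `"gaussian_proportional"`
#'   (standard deviation `sigma * signal`, `sigma` a fraction).
#' @param sigma Noise scale, `>= 0`. Ignored for `kind = "none"`.
#' @param seed Integer random seed; mandatory for stochastic kinds (no
#'   hidden global state).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("none", "gaussian_additive",
                                 "gaussian_proportional"),
                        sigma = 0, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(sigma) == 1L, is.finite(sigma))
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (kind != "none" && is.null(seed))
    stop("a seed is required for stochastic noise models", call. = FALSE)
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(kind = kind, sigma = sigma, seed = seed),
            class = "noise_model")
}

#' Default experiment design for a model spec
#'
#' Times: 31 evenly spaced points from 0 to twice the latest plausible
#' half-maximum time of the modulated curves (so every series shows lag,
#' growth and plateau).  Concentrations: the zero-dose control plus 5
#' log-spaced doses spanning a quarter of the smallest to four times the
#' largest semi-maximum concentration `m` among the effect blocks, which
#' straddles every block's half-effect dose and keeps all blocks
#' identifiable.
#'
#' @param spec A [bivariate_spec()].
#' @param n_times Number of time points (default 31).
#' @param n_doses Number of positive concentrations (default 5).
#' @return A list with components `t_grid` and `C_grid`.
#' @export
default_design <- function(spec, n_times = 31, n_doses = 5) {
  stopifnot(inherits(spec, "bivariate_spec"))
  ctl <- spec$control
  blocks <- Filter(Negate(is.null),
                   list(spec$effect_on_Xm, spec$effect_on_vm,
                        spec$effect_on_lag, spec$effect_on_tau))
  # latest half-max time over the dose range (vm attenuation capped so the
  # horizon stays finite even at full suppression)
  Kl <- if (!is.null(spec$effect_on_lag)) spec$effect_on_lag$K else 0
  Kv <- if (!is.null(spec$effect_on_vm)) min(spec$effect_on_vm$K, 0.95) else 0
  if (spec$parameterization == "midpoint") {
    Kt <- if (!is.null(spec$effect_on_tau)) spec$effect_on_tau$K else 0
    tau_max <- tau_from(ctl) * (1 + Kt)
  } else {
    tau_max <- ctl$lam * (1 + Kl) + ctl$Xm / (2 * ctl$vm * (1 - Kv))
  }
  t_grid <- seq(0, 2 * tau_max, length.out = n_times)
  if (length(blocks) == 0L) {
    C_grid <- 0
  } else {
    ms <- vapply(blocks, `[[`, numeric(1), "m")
    C_grid <- c(0, exp(seq(log(min(ms) / 4), log(max(ms) * 4),
                           length.out = n_doses)))
  }
  list(t_grid = t_grid, C_grid = C_grid)
}

#' Assemble and validate a kinetic dataset
#'
#' @param df A data frame with numeric columns `time`, `concentration`,
#'   `response`.
#' @param units Named list of unit labels (`time`, `concentration`,
#'   `response`); opaque labels, no conversion is attempted.
#' @param provenance Free-text note on where the records came from.
#' @return The data frame with class `kinetic_dataset` and unit/provenance
#'   attributes, ordered by concentration then time.
#' @export
kinetic_dataset <- function(df,
                            units = list(time = "h", concentration = "mM",
                                         response = "AU"),
                            provenance = "unspecified") {
  need <- c("time", "concentration", "response")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("dataset lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(df)[need]
  for (nm in need) {
    if (!is.numeric(df[[nm]]) || any(!is.finite(df[[nm]])))
      stop("column '", nm, "' must be finite numeric", call. = FALSE)
  }
  if (any(df$time < 0)) stop("times must be >= 0", call. = FALSE)
  if (any(df$concentration < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  if (!any(df$concentration == 0))
    stop("dataset must contain a zero-concentration control series",
         call. = FALSE)
  df <- df[order(df$concentration, df$time), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, units = units, provenance = provenance,
            class = c("kinetic_dataset", "data.frame"))
}

# series sizes; fitting needs >= 4 distinct times per concentration
.check_series_depth <- function(df) {
  depth <- tapply(df$time, df$concentration,
                  function(tt) length(unique(tt)))
  if (any(depth < 4))
    stop("each concentration series needs >= 4 distinct times for fitting",
         call. = FALSE)
  invisible(TRUE)
}

#' Generate a synthetic kinetic dataset from a model spec
#'
#' Evaluates the bivariate response surface on the Cartesian product of the
#' grids and adds noise.  Negative noisy responses are clipped at zero (an
#' instrument floor); the number of clipped points is recorded in the
#' `clipped` attribute.  Generation is deterministic given the noise seed.
#'
#' @param spec A [bivariate_spec()].
#' @param t_grid,C_grid Time and concentration grids; `C_grid` must contain
#'   0 (control series).  Defaults come from [default_design()].
#' @param noise A [noise_model()].
#' @param clip_negative Clip negative noisy responses at zero (default
#'   `TRUE`, an instrument floor).  Set `FALSE` for calibration studies
#'   that require exactly Gaussian errors: clipping truncates the error
#'   distribution wherever the surface is near zero.
#' @param units,provenance Passed to [kinetic_dataset()].
#' @return A `kinetic_dataset` with attributes `units`, `provenance`,
#'   `clipped` and `noise`.
#' @examples
#' sp <- scenario_spec("C")
#' d <- generate_dataset(sp, noise = noise_model("gaussian_additive",
#'                                               sigma = 0.02, seed = 1))
#' head(d)
#' @export
generate_dataset <- function(spec, t_grid = NULL, C_grid = NULL,
                             noise = noise_model("none"),
                             clip_negative = TRUE,
                             units = list(time = "h", concentration = "mM",
                                          response = "AU"),
                             provenance = NULL) {
  stopifnot(inherits(spec, "bivariate_spec"), inherits(noise, "noise_model"))
  des <- if (is.null(t_grid) || is.null(C_grid)) default_design(spec) else NULL
  if (is.null(t_grid)) t_grid <- des$t_grid
  if (is.null(C_grid)) C_grid <- des$C_grid
  if (!all(is.finite(t_grid)) || !all(is.finite(C_grid)))
    stop("grids must be finite", call. = FALSE)
  if (!any(C_grid == 0))
    stop("C_grid must contain 0: fits require a control series",
         call. = FALSE)
  g <- expand.grid(time = sort(t_grid), concentration = sort(unique(C_grid)),
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[order(g$concentration, g$time), , drop = FALSE]
  mu <- bivariate_response(spec, g$time, g$concentration)
  resp <- switch(noise$kind,
    none = mu,
    gaussian_additive = mu + withr::with_seed(
      noise$seed, stats::rnorm(length(mu), sd = noise$sigma)),
    gaussian_proportional = mu + withr::with_seed(
      noise$seed, stats::rnorm(length(mu), sd = 1)) * noise$sigma * mu)
  clipped <- if (clip_negative) sum(resp < 0) else 0L
  if (clip_negative) resp[resp < 0] <- 0
  g$response <- resp
  if (is.null(provenance))
    provenance <- sprintf("synthetic (%s noise, sigma = %g)",
                          noise$kind, noise$sigma)
  out <- kinetic_dataset(g, units = units, provenance = provenance)
  attr(out, "clipped") <- clipped
  attr(out, "noise") <- noise
  attr(out, "spec") <- spec
  out
}
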