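# Dataset and report I/O: long-format CSV datasets (with JSON sidecar
# metadata), JSON model configurations, and fit reports in JSON, CSV or
# plain-text form.

#' Read a long-format kinetic dataset from CSV
#'
#' The only accepted dialect is tidy/long CSV with one record per row and
#' header columns for time, concentration and response (names
#' configurable).  Wide time-by-concentration matrices are rejected with a
#' conversion hint.  Decimal separator is the dot; no locale handling.
#'
#' @param path Path to a CSV file.
#' @param time_col,concentration_col,response_col Column names (defaults
#'   `time`, `concentration`, `response`).
#' @param units,provenance Passed to [kinetic_dataset()]; `provenance`
#'   defaults to the file path.
#' @return A [kinetic_dataset()].  Rows with missing or non-numeric fields
#'   raise an error citing the offending file line numbers.
#' @export
read_dataset <- function(path, time_col = "time",
                         concentration_col = "concentration",
                         response_col = "response",
                         units = list(time = "h", concentration = "mM",
                                      response = "AU"),
                         provenance = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0L) stop("empty dataset file: ", path, call. = FALSE)
  need <- c(time_col, concentration_col, response_col)
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    hint <- if (ncol(raw) > 3)
      paste0(" (looks like a wide matrix; reshape to long format with one",
             " time,concentration,response record per row)") else ""
    stop("missing column(s) ", paste(miss, collapse = ", "),
         " in ", path, hint, call. = FALSE)
  }
  df <- data.frame(time = suppressWarnings(as.numeric(raw[[time_col]])),
                   concentration =
                     suppressWarnings(as.numeric(raw[[concentration_col]])),
                   response = suppressWarnings(as.numeric(raw[[response_col]])))
  bad <- which(!stats::complete.cases(df))
  if (length(bad))
    stop("non-numeric or missing fields on line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path,  # +1 for header
         call. = FALSE)
  if (is.null(provenance)) provenance <- paste0("read from ", path)
  kinetic_dataset(df, units = units, provenance = provenance)
}

#' Write a kinetic dataset as CSV with a JSON metadata sidecar
#'
#' The CSV has the header `time,concentration,response`.  The sidecar
#' (`<path>.meta.json`) records units, provenance, the noise model, the
#' clipped-point count and, for generated datasets, the generating model
#' spec.
#'
#' @param dataset A [kinetic_dataset()].
#' @param path Output CSV path.
#' @param sidecar Write the metadata sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, sidecar = TRUE) {
  stopifnot(inherits(dataset, "kinetic_dataset"))
  df <- as.data.frame(dataset)
  # %.17g guarantees the doubles survive the text round trip exactly
  txt <- vapply(df, function(x) sprintf("%.17g", x), character(nrow(df)))
  utils::write.csv(as.data.frame(txt), path, row.names = FALSE,
                   quote = FALSE)
  if (sidecar) {
    noise <- attr(dataset, "noise")
    meta <- list(
      units = attr(dataset, "units"),
      provenance = attr(dataset, "provenance"),
      n_records = nrow(df),
      clipped = attr(dataset, "clipped"),
      noise = if (!is.null(noise)) unclass(noise),
      spec = {
        sp <- attr(dataset, "spec")
        if (!is.null(sp)) spec_to_list(sp)
      })
    jsonlite::write_json(Filter(Negate(is.null), meta),
                         paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  }
  invisible(path)
}

#' Serialize a model spec to a plain list
#'
#' @param spec A [bivariate_spec()].
#' @return A nested list mirroring the spec structure (suitable for JSON).
#' @export
spec_to_list <- function(spec) {
  stopifnot(inherits(spec, "bivariate_spec"))
  out <- list(control = unclass(spec$control))
  for (slot in c("effect_on_Xm", "effect_on_vm", "effect_on_lag",
                 "effect_on_tau")) {
    if (!is.null(spec[[slot]])) out[[slot]] <- unclass(spec[[slot]])
  }
  out$parameterization <- spec$parameterization
  out$allow_superunity_K <- spec$allow_superunity_K
  out
}

#' Rebuild a model spec from its list form
#'
#' @param x A list as produced by [spec_to_list()].
#' @return A [bivariate_spec()].
#' @export
spec_from_list <- function(x) {
  blk <- function(b) {
    if (is.null(b)) NULL else effect_block(b$K, b$m, b$a, b$direction)
  }
  bivariate_spec(
    control = kinetic_params(x$control$Xm, x$control$vm, x$control$lam),
    effect_on_Xm = blk(x$effect_on_Xm),
    effect_on_vm = blk(x$effect_on_vm),
    effect_on_lag = blk(x$effect_on_lag),
    effect_on_tau = blk(x$effect_on_tau),
    parameterization = if (is.null(x$parameterization)) "lag"
                       else x$parameterization,
    allow_superunity_K = isTRUE(x$allow_superunity_K))
}

#' Write / read a model configuration (JSON)
#'
#' The configuration file declares the model structure (which effect
#' blocks are present, the parameterization flag, whether super-unity
#' attenuation maxima are allowed) plus the template parameter values.
#'
#' @param spec A [bivariate_spec()].
#' @param path JSON file path.
#' @return `write_model_config` returns `path` invisibly;
#'   `read_model_config` returns a [bivariate_spec()].
#' @export
write_model_config <- function(spec, path) {
  jsonlite::write_json(spec_to_list(spec), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  spec_from_list(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Assemble a structured report from a fit
#'
#' Mirrors the layout of a published parameter table: one row per free
#' parameter with estimate, confidence half-width and NS flag; a
#' goodness-of-fit block; a potency block (numerical EC50 at the control
#' half-max time, plus the closed-form reference time, when the fitted
#' model has at least one effect block); pruned blocks with their
#' triggering statistics; and provenance.
#'
#' @param fit An `agg_fit` object.
#' @param input_checksum Optional MD5 checksum of the input dataset file.
#' @param timestamp Report timestamp string; `NULL` (default) stamps the
#'   current UTC time.  Pass a fixed string for byte-reproducible output.
#' @return An object of class `fit_report` (a nested list).
#' @export
fit_report <- function(fit, input_checksum = NULL, timestamp = NULL) {
  stopifnot(inherits(fit, "agg_fit"))
  ci <- confidence_intervals(fit)
  pot <- NULL
  if (.n_blocks(fit$spec) > 0L) {
    pnum <- ec50_tau(fit$spec)
    pot <- list(ec50 = pnum$ec50, tau = pnum$tau,
                attained = pnum$attained, method = pnum$method)
    if (pnum$attained) {
      pa12 <- ec50_tau(fit$spec, method = "closed_form_a12")
      pot$tau_closed_form_a12 <- pa12$tau
    }
  }
  if (is.null(timestamp))
    timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  structure(list(
    parameters = ci,
    sse = fit$sse, n = fit$n, p = fit$p,
    converged = fit$converged,
    rank_deficient = fit$rank_deficient,
    gof = unclass(fit$gof),
    potency = pot,
    pruned = fit$pruned,
    provenance = list(
      input_checksum = input_checksum,
      alpha = fit$alpha,
      multistart = fit$options$multistart,
      seed = fit$options$seed,
      package_version = as.character(utils::packageVersion("amylokin")),
      timestamp = timestamp)), class = "fit_report")
}

#' Write a fit report
#'
#' @param report A [fit_report()].
#' @param path Output path.
#' @param format `"json"` (round-trippable), `"csv"` (parameter table with
#'   GOF rows appended) or `"text"` (human-readable table).
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(report, path,
                             format = c("json", "csv", "text")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "fit_report"))
  if (format == "json") {
    # digits = I(17): estimates survive the text round trip exactly
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = I(17), pretty = TRUE, null = "null",
                         na = "null")
  } else if (format == "csv") {
    tab <- report$parameters
    gof <- report$gof
    extra <- data.frame(parameter = names(gof),
                        estimate = unlist(gof, use.names = FALSE),
                        se = NA, halfwidth = NA, lower = NA, upper = NA,
                        ns = NA)
    utils::write.csv(rbind(tab, extra), path, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(utils::capture.output(print(report)), con)
  }
  invisible(path)
}

#' Read back a JSON fit report
#'
#' @param path Path to a JSON file written by [write_fit_report()].
#' @return A `fit_report` object.
#' @export
read_fit_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$parameters <- as.data.frame(x$parameters)
  # JSON nulls (undefined statistics, e.g. DW of a perfect fit) -> NA
  for (nm in c("r2_adj", "f_pvalue", "dw", "bf", "af", "rmse")) {
    if (is.null(x$gof[[nm]])) x$gof[nm] <- list(NA_real_)
  }
  if (!is.null(x$pruned) && is.data.frame(x$pruned))
    x$pruned <- lapply(seq_len(nrow(x$pruned)),
                       function(i) as.list(x$pruned[i, ]))
  structure(x, class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat("Fit report\n==========\n")
  tab <- x$parameters
  tab$ci <- sprintf("%.4g ± %.3g", tab$estimate, tab$halfwidth)
  tab$flag <- ifelse(tab$ns, "NS", "")
  print(tab[, c("parameter", "ci", "flag")], row.names = FALSE)
  cat(sprintf("\nn = %d, p = %d, SSE = %.4g, converged = %s\n",
              x$n, x$p, x$sse, x$converged))
  g <- x$gof
  cat(sprintf("R2_adj = %.4f | F p-value = %.3g | DW = %.3f | Bf = %.3f | Af = %.3f\n",
              g$r2_adj, g$f_pvalue, g$dw, g$bf, g$af))
  if (!is.null(x$potency)) {
    if (isTRUE(x$potency$attained)) {
      cat(sprintf("EC50,tau = %.4g at tau = %.4g (closed-form tau: %.4g)\n",
                  x$potency$ec50, x$potency$tau,
                  x$potency$tau_closed_form_a12))
    } else cat("EC50 not attained within the search bracket\n")
  }
  if (length(x$pruned)) {
    cat("Pruned blocks:\n")
    for (pr in x$pruned)
      cat(sprintf("  %s: K = %.4g (|t| = %.3g < %.3g), %s\n",
                  pr$block, pr$K, pr$t, pr$t_critical, pr$reason))
  }
  invisible(x)
}
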