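# Scenario atlas: seven frozen parameter sets covering every qualitative
# combination of dose effects on the logistic parameters (A: all three;
# B: Xm+vm; C: Xm only; D: Xm+lag; E: vm+lag; F: vm only; G: lag only).

.scenario_cache <- new.env(parent = emptyenv())

.scenario_table <- function() {
  if (is.null(.scenario_cache$tab)) {
    path <- system.file("extdata", "scenario_params.csv",
                        package = "amylokin", mustWork = TRUE)
    .scenario_cache$tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .scenario_cache$tab
}

#' Frozen simulation-scenario parameter sets
#'
#' Returns the registry of the seven scenario parameter sets (labels A-G)
#' as a data frame, one row per scenario, with `NA` marking an absent
#' effect block.
#'
#' @return A data frame with columns `scenario`, the control triple
#'   (`Xm`, `vm`, `lam`) and the Weibull triples (`Kx`, `mx`, `ax`, `Kv`,
#'   `mv`, `av`, `Kl`, `ml`, `al`).
#' @export
scenario_registry <- function() .scenario_table()

#' Build the model spec of a named scenario
#'
#' @param label One of `"A"` to `"G"`.
#' @return A [bivariate_spec()] with that scenario's parameter set.
#' @examples
#' scenario_spec("D")
#' @export
scenario_spec <- function(label) {
  tab <- .scenario_table()
  row <- tab[tab$scenario == label, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("unknown scenario '", label, "'; valid labels: ",
         paste(tab$scenario, collapse = ", "), call. = FALSE)
  blk <- function(K, m, a, direction) {
    if (is.na(K)) NULL else effect_block(K, m, a, direction)
  }
  bivariate_spec(
    control = kinetic_params(row$Xm, row$vm, row$lam),
    effect_on_Xm = blk(row$Kx, row$mx, row$ax, "attenuate"),
    effect_on_vm = blk(row$Kv, row$mv, row$av, "attenuate"),
    effect_on_lag = blk(row$Kl, row$ml, row$al, "amplify"))
}

#' Evaluate a scenario surface on a grid
#'
#' Computes the noiseless bivariate response of a scenario parameter set on
#' the Cartesian product of the supplied grids.
#'
#' @param label Scenario label, `"A"` to `"G"`.
#' @param t_grid Non-empty vector of times, `>= 0`.
#' @param C_grid Non-empty vector of concentrations, `>= 0`.
#' @return A data frame with columns `time`, `concentration`, `response`,
#'   ordered by concentration then time.
#' @examples
#' head(simulate_scenario("G", t_grid = 0:20, C_grid = c(0, 5, 10)))
#' @export
simulate_scenario <- function(label, t_grid = NULL, C_grid = NULL) {
  sp <- scenario_spec(label)
  if (is.null(t_grid) || is.null(C_grid)) {
    des <- default_design(sp)
    if (is.null(t_grid)) t_grid <- des$t_grid
    if (is.null(C_grid)) C_grid <- des$C_grid
  }
  if (length(t_grid) == 0L || length(C_grid) == 0L)
    stop("grids must be non-empty", call. = FALSE)
  if (any(t_grid < 0) || any(C_grid < 0))
    stop("grids must be non-negative", call. = FALSE)
  g <- expand.grid(time = sort(t_grid), concentration = sort(C_grid),
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[order(g$concentration, g$time), , drop = FALSE]
  rownames(g) <- NULL
  g$response <- bivariate_response(sp, g$time, g$concentration)
  g
}
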