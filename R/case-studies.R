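# Worked inhibitor case studies: fitted parameter sets for nine published
# inhibitor/protein systems (EGCG, di-C7-PC and methylglyoxal on insulin;
# apigenin, taiwaniaflavone and the ectoines on Abeta42; trehalose on
# apomyoglobin).  Used as ground truth for simulation and
# parameter-recovery studies.

.case_cache <- new.env(parent = emptyenv())

.case_table <- function() {
  if (is.null(.case_cache$tab)) {
    path <- system.file("extdata", "inhibitor_params.csv",
                        package = "amylokin", mustWork = TRUE)
    .case_cache$tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .case_cache$tab
}

#' Registry of worked inhibitor case studies
#'
#' @return A data frame, one row per case, with the control triple, the
#'   Weibull effect triples (`NA` marks a block found non-significant and
#'   absent from that case's model) and unit labels.
#' @export
inhibitor_registry <- function() .case_table()

#' Build the model spec of a named inhibitor case study
#'
#' Super-unity attenuation maxima (`K > 1`, present in the taiwaniaflavone
#' rate block) are permitted automatically; the resulting spec is valid
#' only on a restricted concentration range.
#'
#' @param case Case name; see `inhibitor_registry()$case`.
#' @return A [bivariate_spec()].
#' @examples
#' inhibitor_spec("egcg_1")
#' @export
inhibitor_spec <- function(case) {
  tab <- .case_table()
  row <- tab[tab$case == case, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("unknown case '", case, "'; valid cases: ",
         paste(tab$case, collapse = ", "), call. = FALSE)
  blk <- function(K, m, a, direction) {
    if (is.na(K)) NULL else effect_block(K, m, a, direction)
  }
  super <- !is.na(row$Kv) && row$Kv > 1 || !is.na(row$Kx) && row$Kx > 1
  bivariate_spec(
    control = kinetic_params(row$Xm, row$vm, row$lam),
    effect_on_Xm = blk(row$Kx, row$mx, row$ax, "attenuate"),
    effect_on_vm = blk(row$Kv, row$mv, row$av, "attenuate"),
    effect_on_lag = blk(row$Kl, row$ml, row$al, "amplify"),
    allow_superunity_K = super)
}
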