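# Shared test helpers: perturbed starts and the recovery study designs.

# multiplicative +/-20% perturbation of a parameter vector, deterministic
perturb20 <- function(par, seed) {
  withr::with_seed(seed, par * (1 + stats::runif(length(par), -0.2, 0.2)))
}

true_par <- function(spec) amylokin:::.spec_to_par(spec)

# dose/time designs used for the published-parameter recovery studies;
# cases not listed use the package's default design
recovery_design <- function(case) {
  switch(case,
    egcg_1 = list(t = seq(0, 30, length.out = 31),
                  C = c(0, 0.1, 0.2, 0.4, 0.8, 1.6)),
    egcg_2 = list(t = seq(0, 120, length.out = 41),
                  C = c(0, 0.0025, 0.005, 0.01, 0.02, 0.05, 0.1, 0.2)),
    dic7pc = list(t = seq(0, 400, length.out = 41),
                  C = c(0, 0.1, 0.2, 0.3, 0.47, 0.65, 0.8, 1.0)),
    methylglyoxal = list(t = seq(0, 12, length.out = 31),
                         C = c(0, 0.1, 0.25, 0.42, 0.8, 1.8, 3.6)),
    taiwaniaflavone = list(t = seq(0, 3, length.out = 31),
                           C = c(0, 0.5, 1, 2, 4, 8, 10)),
    apigenin = list(t = seq(0, 3, length.out = 31),
                    C = c(0, 0.5, 1, 2.16, 4, 8, 16)),
    NULL)
}

# noiseless dataset from a generating spec on its recovery design
recovery_dataset <- function(spec, design = NULL) {
  if (is.null(design)) generate_dataset(spec)
  else generate_dataset(spec, design$t, design$C)
}

# a full three-block model structure sharing a spec's control triple
full_template <- function(spec, m0 = 2) {
  bivariate_spec(spec$control,
                 effect_on_Xm = effect_block(0.5, m0, 1, "attenuate"),
                 effect_on_vm = effect_block(0.5, m0, 1, "attenuate"),
                 effect_on_lag = effect_block(0.5, m0, 1, "amplify"))
}
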