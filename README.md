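# amylokin

Modelling chemical inhibition of amyloid protein aggregation kinetics.

Amyloid-forming proteins (insulin, Aβ42, apomyoglobin, ...) aggregate with a
characteristic sigmoid kinetic signal — a lag (pre-nucleation) phase, a fast
growth (elongation) phase and a plateau — typically monitored by ThT
fluorescence or absorbance. Candidate inhibitors are screened by recording
these curves at several inhibitor concentrations. `amylokin` fits the whole
time × concentration surface at once with a bivariate model, quantifies which
kinetic parameters the chemical actually modifies, and summarizes potency in
a single dose index. It is aimed at anyone analysing in-vitro fibrillation
inhibition data: kinetics labs, formulation groups, and method developers who
need a transparent, statistically annotated alternative to curve-by-curve
fitting.

## The model

A single aggregation curve is a logistic reparameterized in the three
quantities practitioners care about — maximum growth *X<sub>m</sub>* (signal
units), maximum aggregation rate *v<sub>m</sub>* (signal/time, the slope at
the inflection point) and lag phase *λ* (time):

```
X(t) = Xm / (1 + exp(2 + (4 vm / Xm) (λ − t)))
```

Useful identities: *X(λ) = X<sub>m</sub>/(1+e²)*, and the half-maximum time
is *τ = λ + X<sub>m</sub>/(2 v<sub>m</sub>)* with *X(τ) = X<sub>m</sub>/2*.
The classical autocatalytic form with apparent rate
*k<sub>app</sub> = 4 v<sub>m</sub>/X<sub>m</sub>* is algebraically identical
and kept as an internal cross-check.

Each kinetic parameter can be modulated by the inhibitor concentration *C*
through a Weibull dose–response term
*w(C) = K (1 − exp(−ln2 (C/m)<sup>a</sup>))*, which is 0 at zero dose and
exactly *K/2* at *C = m*:

```
Xm*(C) = Xm (1 − wx(C))      vm*(C) = vm (1 − wv(C))      λ*(C) = λ (1 + wλ(C))
```

Inserting the modulated triple into the logistic gives the full response
surface *X(t, C)*. A chemical that attenuates only *X<sub>m</sub>* is an
*apparent* inhibitor (it changes the thermodynamic plateau); one that slows
*v<sub>m</sub>* or stretches *λ* is a *true* inhibitor of the kinetics.
Potency is summarized by EC<sub>50,τ</sub>: the concentration that halves the
response relative to the untreated control at the control's half-maximum
time τ.

The package provides:

* `logistic_response()`, `weibull_effect()`, `modulate()`,
  `bivariate_response()` — the model core;
* `generate_dataset()`, `simulate_scenario()` — a seeded synthetic-data
  generator plus a frozen atlas of seven scenario parameter sets covering
  every qualitative effect combination;
* `fit_bivariate()`, `prune_nonsignificant()`, `confidence_intervals()` —
  Levenberg–Marquardt least squares with multistart, linearized covariance,
  Student-t intervals, and significance-based removal of unsupported
  dose-effect blocks;
* `gof_stats()` — adjusted R², Fisher F consistency p-value, Durbin–Watson
  statistic, bias/accuracy factors;
* `ec50_tau()` — the potency index by bracketing bisection;
* `read_dataset()`, `write_fit_report()`, `run_cli()` — long-CSV / JSON I/O
  and a `fit` / `simulate` / `generate` / `potency` command line;
* `inhibitor_registry()` — nine bundled parameter sets for published
  inhibitor/protein systems (EGCG, di-C7-PC and methylglyoxal on insulin;
  apigenin, taiwaniaflavone, ectoine and hydroxyectoine on Aβ42; trehalose
  on apomyoglobin), used as ground truth in recovery studies.

## Worked example

Simulate a noisy screen of EGCG against insulin at acidic pH (the bundled
`egcg_1` parameter set: plateau and lag affected, rate untouched), then fit
the full three-block model with pruning:

```r
library(amylokin)

truth <- inhibitor_spec("egcg_1")
data <- generate_dataset(truth,
                         t_grid = seq(0, 30, length.out = 31),
                         C_grid = c(0, 0.1, 0.2, 0.4, 0.8, 1.6),  # mM
                         noise = noise_model("gaussian_additive",
                                             sigma = 0.02, seed = 42),
                         clip_negative = FALSE)

template <- bivariate_spec(kinetic_params(1, 1, 1),
  effect_on_Xm  = effect_block(0.5, 0.5, 1, "attenuate"),
  effect_on_vm  = effect_block(0.5, 0.5, 1, "attenuate"),
  effect_on_lag = effect_block(0.5, 0.5, 1, "amplify"))

fit <- prune_nonsignificant(data, template)
fit
ec50_tau(fit$spec)
```

```
Bivariate aggregation model fit: 186 records, 9 parameters
 parameter estimate       se halfwidth  lower  upper    ns
        Xm   1.1173 0.003833  0.007565 1.1098 1.1249 FALSE
        vm   0.1803 0.002701  0.005330 0.1749 0.1856 FALSE
       lam   4.6698 0.069963  0.138069 4.5317 4.8078 FALSE
        Kx   0.4217 0.009413  0.018577 0.4031 0.4403 FALSE
        mx   0.6611 0.016609  0.032777 0.6283 0.6939 FALSE
        ax   1.7006 0.085424  0.168580 1.5320 1.8692 FALSE
        Kl   0.9788 0.132740  0.261957 0.7169 1.2408 FALSE
        ml   0.6356 0.160861  0.317453 0.3181 0.9530 FALSE
        al   0.8025 0.071530  0.141161 0.6613 0.9436 FALSE
SSE = 0.06697 | R2_adj = 0.9979 | DW = 2.122 | Bf = 0.934 | Af = 1.153
Pruned blocks: vm
EC50,tau = 0.367041 at tau = 7.76876 (method: numerical, ratio = 0.500000)
```

Reading the output: the rate block was removed as non-significant — the fit
correctly recognizes that EGCG under these conditions does not change the
elongation rate — while the recovered control triple
(*X<sub>m</sub>* ≈ 1.12 AU, *v<sub>m</sub>* ≈ 0.18 AU/h, *λ* ≈ 4.7 h) and the
plateau/lag dose blocks sit close to the generating values (the generating
lag block was *K* = 0.81, *m* = 0.50, *a* = 0.98). DW ≈ 2 indicates
uncorrelated residuals; B<sub>f</sub>/A<sub>f</sub> near 1 indicate unbiased,
accurate predictions. An EC<sub>50,τ</sub> of ≈ 0.37 mM at τ ≈ 7.8 h
summarizes the inhibition strength.

The same workflow is available from a shell:

```sh
amylokin generate --scenario D --noise gaussian_additive --sigma 0.01 --seed 7 --out screen.csv
amylokin fit --data screen.csv --prune --out report.json
amylokin potency --config model.json
```

(The `amylokin` script is installed under `inst/exec/`; call it via
`Rscript $(Rscript -e 'cat(system.file("exec","amylokin",package="amylokin"))') ...`
or symlink it onto your PATH.)

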