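---
title: "Modelling chemical inhibition of amyloid aggregation kinetics with amylokin"
author: "amylokin authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling chemical inhibition of amyloid aggregation kinetics with amylokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amylokin)
```

# The model and its assumptions

Aggregation of amyloidogenic proteins monitored by ThT fluorescence or
absorbance produces sigmoid kinetics: a lag phase while nuclei form, a fast
elongation phase, and a plateau once soluble protein is exhausted. `amylokin`
describes one curve by a logistic reparameterized in the three geometric
descriptors of that shape,

$$X(t) = \frac{X_m}{1 + \exp\!\big(2 + \tfrac{4 v_m}{X_m}(\lambda - t)\big)},$$

where $X_m$ is the maximum aggregation growth (AU or %), $v_m$ the maximum
aggregation rate (signal per time; the slope at the inflection point) and
$\lambda$ the lag phase (time; the abscissa intercept of the tangent at the
inflection point). Exact consequences of this form, used throughout the test
suite: $X(\lambda) = X_m/(1+e^2)$, and at the half-maximum time
$\tau = \lambda + X_m/(2v_m)$ the curve passes exactly through $X_m/2$. The
classical autocatalytic logistic with initial value $X_0$ and apparent rate
$k_\mathrm{app} = 4v_m/X_m$ is the same curve under a parameter mapping; the
package keeps both forms and tests their pointwise equality, which guards
the reparameterization against algebraic drift.

An inhibitor at concentration $C$ acts by modulating the kinetic parameters
through saturating Weibull dose–response functions
$w(C) = K\,(1 - e^{-\ln 2\,(C/m)^a})$ — zero at $C=0$, exactly $K/2$ at
$C = m$, tending to $K$. Plateau and rate are attenuated,
$X_m^\ast = X_m(1 - w_x)$ and $v_m^\ast = v_m(1 - w_v)$, the lag is
amplified, $\lambda^\ast = \lambda(1 + w_\lambda)$. The bivariate surface
$X(t, C)$ is the logistic evaluated with the modulated triple. This is an
empirical, geometric description: it does not resolve nucleation/elongation
mechanism, temperature dependence, or non-monotone (biphasic) dose effects,
all of which are out of scope.

Two parameterizations of the third kinetic coordinate are supported. The
default (`"lag"`) modulates $\lambda$ directly. The alternative
(`"midpoint"`) amplifies the half-maximum time,
$\tau^\ast = \tau(1 + w_\tau)$, and recovers
$\lambda^\ast = \tau^\ast - X_m^\ast/(2 v_m^\ast)$; it is useful when the
half-max time is the better-determined landmark. The two cannot be mixed in
one model.

## Tunable parameters

| Parameter | Meaning | Units | Constraint |
|---|---|---|---|
| $X_m$ | maximum growth | AU or % | $> 0$ |
| $v_m$ | maximum rate | AU/h, AU/d, %/h | $> 0$ |
| $\lambda$ | lag phase | h or d | $\ge 0$ (lag-free curves allowed) |
| $K$ | maximum fractional effect | – | $\ge 0$; $\le 1$ for attenuation |
| $m$ | semi-maximum dose | mM or µM | $> 0$ |
| $a$ | dose-response shape | – | $> 0$ |

Units are opaque labels; no conversion is attempted (the bundled case
studies deliberately mix mM/µM and h/d, as their sources do). Attenuating
blocks with $K > 1$ would drive $X_m^\ast$ or $v_m^\ast$ negative at high
dose; they are rejected unless `allow_superunity_K = TRUE`, because fitted
attenuation maxima slightly above 1 do occur on restricted dose ranges (the
bundled taiwaniaflavone rate block has $K_v = 1.14$ and is valid only up to
roughly 10 µM). Evaluation outside the validity range raises an explicit
error rather than returning a negative-parameter curve.

# Synthetic data: what the generator emulates

`generate_dataset()` evaluates the surface on a time × dose grid and adds
either additive Gaussian noise (constant $\sigma$ in signal units) or
proportional Gaussian noise ($\sigma \times$ signal). Negative draws are
clipped at zero by default — an instrument floor — with the clipped count
reported; `clip_negative = FALSE` disables the floor. Seeds are mandatory
for stochastic generation and scoped locally (no global RNG state is
touched). Real plate-reader data additionally show drift, well-to-well
gain differences, and occasional non-sigmoid artifacts; none of these are
emulated, so passing recovery tests demonstrate correctness of the
estimator under its assumed error model, not robustness to every
instrumental pathology.

The default experiment design uses 31 evenly spaced times from 0 to twice
the latest plausible modulated half-max time, and the zero-dose control
plus five log-spaced doses spanning $[\min(m)/4,\ 4\max(m)]$ — every
block's half-effect dose is straddled, which keeps all Weibull triples
identifiable. A frozen atlas of seven scenario parameter sets (labels A–G,
`scenario_registry()`), covering every qualitative combination of affected
parameters, is bundled with a checksum test, alongside nine published
inhibitor/protein parameter sets (`inhibitor_registry()`) used as ground
truth for recovery studies.

# Fitting

`fit_bivariate()` minimizes the unweighted sum of squared residuals with
Levenberg–Marquardt under box constraints, by default from five starts (a
data-driven heuristic plus four ±20% jittered copies), keeping the best.
Standard errors come from the linearized covariance
$s^2 (J^\top J)^{-1}$, $s^2 = \mathrm{SSE}/(n-p)$, with $J$ the model
Jacobian at the solution (central differences); confidence intervals are
symmetric Student-$t$ intervals with $n - p$ degrees of freedom. A
rank-deficient $J^\top J$ (an unidentifiable block) is inverted by SVD
pseudo-inverse, flagged, and the affected standard errors reported as
unavailable.

Design choices worth knowing:

* **Initial guesses.** The control triple comes from the control series
  (plateau = max response; rate = steepest successive slope; lag from the
  10%-crossing time). Block guesses are read off *per-series* kinetic
  estimates: each dose series yields its own crude $(X_m, v_m, \lambda)$,
  these are converted to empirical effect fractions relative to the
  control, $K_0$ is the effect at the top dose and $m_0$ the interpolated
  half-$K_0$ crossing. A cruder constant guess ($K_0 = 0.5$, $m_0$ =
  median dose) was tried first and left the optimizer in local minima on
  scenarios where lag and rate effects partially mimic one another; the
  per-series heuristic lands inside the global basin on all bundled
  parameter sets.
* **Interior starts.** The LM implementation stalls when a start sits
  exactly on an active box bound, so starts are clamped to the strict
  interior (relative margin $10^{-3}$).
* **Numerical guards.** The logistic exponent is clamped at ±700 (beyond
  which the curve is its asymptote to double precision); during
  optimization, trial iterates that push a modulated parameter
  non-positive are evaluated with a tiny positive floor so residuals stay
  finite, while user-facing evaluation errors instead.
* **Weighting.** Plain unweighted SSE. Consequence: under proportional
  (heteroscedastic) noise the linearized confidence intervals are
  miscalibrated (measured plateau-parameter coverage near 50% at 5%
  proportional noise); they are calibrated under additive noise (measured
  93–97% across parameters at $\sigma = 0.05$ AU on the EGCG/insulin
  design, 200 replicates). Zero-clipping likewise truncates the error
  distribution wherever the surface is near zero and visibly biases lag
  estimates; calibration studies therefore use unclipped additive noise.
* **Degenerate input.** A dataset with only the control series falls back
  to the control-only logistic fit with a warning; each series must have
  at least four distinct times.

## Significance-based model reduction

`prune_nonsignificant()` mirrors how practitioners report "NS" entries:
fit the full declared model, drop unsupported dose-effect blocks, refit.
A block counts as significant only if **both** (i) the $t$-based
confidence interval of its $K$ excludes zero — $K$ is the well-posed
parameter to test, since with $K = 0$ the block's $m$ and $a$ are
unidentifiable — and (ii) removing the whole block significantly worsens
the fit (nested-model $F$ test on 3 degrees of freedom at the same
$\alpha$, default 0.05). The second check exists because the Wald test
alone has a degenerate failure mode we observed directly: a spurious
block can park $m$ at or beyond the edge of the dose range with $K$
pinned at a bound, producing a tiny linearized SE for $K$ and
$|t| \approx 3$ while contributing nothing real; the drop test exposes
it. The least-significant block (largest drop-test p-value) goes first;
pruning everything is a valid outcome (control-only fit). At
$\alpha = 0.05$ an irreducible share of runs will still keep one spurious
block — replication across seeds is the honest guard, and the structure
recovery test judges by majority across three replicates.

# Goodness of fit

The battery reported with every fit, with the conventions made explicit
since several have no single standard definition:

* **Adjusted $R^2$** $= 1 - (1 - R^2)(n-1)/(n-p)$ — denominator $n - p$,
  not $n - p - 1$, because the nonlinear model has no separate intercept.
* **Fisher $F$ consistency p-value** — regression mean square (about the
  observed mean) over residual mean square with $(p, n-p)$ degrees of
  freedom. This mirrors spreadsheet-era practice and is flagged as a
  consistency heuristic, not a nested-model test; its p-value is *not*
  uniform under an "uncorrelated predictions" null and should not be used
  as one.
* **Durbin–Watson** $= \sum(\Delta e)^2 / \sum e^2 \in [0, 4]$, computed
  on residuals ordered concentration series by concentration series
  (ascending dose), each by time — autocorrelation is meaningful within a
  kinetic trace, and the pooled-ordered convention is a documented choice,
  not an assertion about any external convention. No significance tables
  are provided.
* **Bias and accuracy factors**
  $B_f = 10^{\overline{\log_{10}(P/O)}}$,
  $A_f = 10^{\overline{|\log_{10}(P/O)|}}$ — log-ratio summaries of
  systematic and absolute error; pairs with non-positive values are
  excluded (hard error if more than 10% would be).

# The potency index

$\mathrm{EC}_{50,\tau}$ is defined here as the dose halving the response
relative to the untreated control at the control's half-maximum time
$\tau$: the root of $X(\tau, C)/X(\tau, 0) = 1/2$, found by bracketing
bisection on $(0, C_{\max}]$ (default $C_{\max} = 100\max(m)$) to relative
tolerance $10^{-6}$, cross-checked in the tests against a dense grid scan.
This is the only reading of "halving at the half-max time" that is well
defined for every scenario shape, including pure-lag inhibitors. Weak
inhibition that never halves the response returns an explicit
"not attained" result rather than an error. A closed-form alternative
reference time, $\tau^\ast - X_m^\ast \ln 3/(4 v_m^\ast)$ evaluated with
the modulated parameters at the solution dose (the time at which the
inhibited curve reaches a quarter of its own modulated maximum), is
reported under `method = "closed_form_a12"`; both times appear in fit
reports, clearly labelled. Potency values quoted in the source tables of
the bundled case studies were produced by an algebra not fully specified
in those sources and are not reproduction targets; the package computes
its own documented definition.

An exact limit used in testing: if plateau and rate are attenuated by
*matched* blocks (equal $K = 1$, $m$, $a$), $k_\mathrm{app}$ is preserved,
the inhibited curve at $\tau$ sits exactly at $X_m^\ast/2$, and
$\mathrm{EC}_{50,\tau} = m$ exactly. With a plateau-only block the ratio
at $\tau$ is $2x/(1+e^{2-2/x})$ with $x = X_m^\ast/X_m$, so the root sits
at $w_x = 3/4$, i.e. $C = m\,2^{1/a}$ — a useful reminder that plateau
suppression alone does not halve the *curve* at $\tau$ when it halves the
*plateau*.

# Problem sizes and runtime choices

The packaged studies use desk-scale designs chosen for identifiability:
31–41 time points, 6–8 concentrations (186–328 records), 6–12 free
parameters. Closed-loop recovery on noiseless surfaces from ±20%-perturbed
starts reproduces every bundled parameter set to well below $10^{-3}$
relative error; the confidence-interval calibration study uses 200 noisy
replicates; structure recovery uses three replicates per scenario at
$\sigma = 0.01$. All studies run in seconds to a few minutes on one CPU.

# Known limitations

* Heteroscedastic data (proportional error) will yield miscalibrated
  intervals under the unweighted objective; weighting schemes are out of
  scope by design.
* The surface is monotone non-increasing in dose only past the lag
  region: before $\lambda^\ast$, a slower $v_m^\ast$ slightly *raises*
  the curve (a property of the logistic form, covered by tests).
* Biphasic dose responses (e.g. re-entrant aggregation at high dose)
  cannot be represented; fits to such data will fail the GOF battery.
* Dose ranges far beyond the fitted range can underflow a modulated
  parameter to zero with super-unity $K$; evaluation errors explicitly
  rather than extrapolating.
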