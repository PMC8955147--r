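---
title: "Release kinetics, IVIVC convolution and permeation analysis with filmkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Release kinetics, IVIVC convolution and permeation analysis with filmkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filmkin)
library(dplyr)
```

filmkin characterises fast-dissolving mucoadhesive films through three
linked analyses: empirical release-model fitting with information-criterion
model selection, convolution-based prediction of the in-vivo plasma
concentration–time profile from in-vitro dissolution data, and Franz-cell
permeation flux estimation. This vignette explains the models, the
statistical conventions, the numerical choices, and what the synthetic-data
generators do and do not emulate.

## The empirical release models

A dissolution profile records cumulative percent of the loaded dose
released, $F(t)$, at sampling times $t$ (minutes). filmkin fits the nine
standard single-phase release laws:

| model | $F(t)$ | mechanism it represents |
|---|---|---|
| zero order | $k_0 t$ | constant-rate release |
| first order | $100(1 - e^{-k_1 t})$ | release proportional to remaining drug |
| Higuchi | $k_H \sqrt{t}$ | planar matrix diffusion |
| Korsmeyer–Peppas | $k_{KP}\, t^{n}$ | power law; $n$ classifies transport |
| Hixson–Crowell | $100[1 - (1 - k_{HC} t)^3]$ | dissolving particles of shrinking radius |
| Hopfenberg | $100[1 - (1 - k_{HB} t)^n]$ | surface erosion; $n$ encodes geometry |
| Baker–Lonsdale | $\tfrac{3}{2}[1 - (1 - F/100)^{2/3}] - F/100 = k_{BL} t$ | diffusion from a sphere (implicit) |
| Peppas–Sahlin | $k_1 t^m + k_2 t^{2m}$ | additive Fickian + relaxational terms |
| Weibull | $100\{1 - \exp[-(t - T_i)^\beta / \alpha]\}$ | flexible sigmoid/exponential shape |

Conventions adopted (`evaluate_release()`):

* All values are clamped to $[0, 100]$ percent.
* The erosion forms (Hixson–Crowell, Hopfenberg) are undefined once
  $k t > 1$; we return exactly 100 there — the matrix has fully eroded —
  rather than raising an error. This matters for fast-dissolving films,
  whose late sampling points sit at complete release.
* The Weibull lag $T_i$ is constrained $\ge 0$ with default 0; times
  $t \le T_i$ return 0.
* The Hopfenberg exponent $n$ is a continuous free parameter $\ge 1$.
  The slab/cylinder/sphere derivation gives $n \in \{1,2,3\}$, but release
  data rarely identify the geometry, so fixing $n$ to an integer would
  impose structure the data cannot check.
* Baker–Lonsdale is implicit in $F$; we solve it by bracketed root finding
  (`uniroot`, tolerance $10^{-12}$) on $F \in [0,100]$. The left-hand side
  attains its maximum $1/2$ at $F = 100$, so $k_{BL} t \ge 0.5$ means
  complete release.

Useful identities (unit-tested): Weibull$(\beta = 1, T_i = 0)$ equals first
order with $k_1 = 1/\alpha$; Korsmeyer–Peppas with $n = 0.5$ is Higuchi and
with $n = 1$ is zero order; Peppas–Sahlin with $k_2 = 0$ is Korsmeyer–Peppas;
Hopfenberg with $n = 3$ is Hixson–Crowell.

## Fitting and model comparison

`fit_release()` minimises $\mathrm{SSE} = \sum_i (F_{obs,i} - F_{model,i})^2$
by bounded Levenberg–Marquardt least squares (`minpack.lm::nls.lm`) with a
deterministic multi-start strategy: a data-driven head start per model
(endpoint slope, log–log regression, double-log Weibull linearisation; for
Peppas–Sahlin, separable least squares — the model is linear in $k_1, k_2$
given $m$, so $m$ is profiled over a fixed grid) followed by a fixed grid of
bound-scaled fallbacks. No random jitter is used, so the same profile always
gives the same fit. The $t=0, F=0$ point is retained in the objective, and
replicate profiles are averaged per time point before fitting (mean-profile
fitting, the common practice for triplicate dissolution runs).

Goodness of fit (`release_gof()`) uses frozen conventions:

$$R^2_{adj} = 1 - (1 - R^2)\frac{n-1}{n-p-1}, \qquad
\mathrm{RMSE} = \sqrt{\mathrm{SSE}/(n-p)}, \qquad
\mathrm{AIC} = n \ln(\mathrm{SSE}/n) + 2p,$$

with $n$ observations and $p$ parameters. The AIC is the least-squares form
used by common dissolution-fitting software; RMSE is the
degrees-of-freedom–corrected variant. Both choices are conventions, not
universals — published AIC magnitudes are only interpretable relative to a
stated convention, which is why `write_report()` records these strings in
its run metadata. A perfect fit makes the least-squares AIC diverge; it is
reported as $-\infty$ with a warning rather than silently.

`rank_release_models()` fits all requested models once and sorts by AIC
(default), RMSE, or adjusted $R^2$; `rerank()` re-sorts without refitting.
For models with equal $p$, AIC ordering provably equals SSE ordering.

### A note on model selection near nested submodels

The nano-emulsion-like preset (below) uses Hopfenberg with $n = 1.05$.
At $n = 1$ Hopfenberg degenerates to a clamped straight line — exactly the
zero-order model with $k_0 = 100\,k_{HB}$. Within one percent-point of
noise, data generated at $n = 1.05$ are therefore nearly indistinguishable
from their one-parameter submodel, and AIC (correctly) often prefers the
more parsimonious zero-order fit. Selection consistency is a property of
identifiable parameter points, so the packaged selection study
(`scripts/acceptance.R`, and the corresponding test) generates from the
interior point $k_{HB} = 0.06\ \mathrm{min}^{-1}, n = 2$, where the
generating model wins the AIC ranking in 100/100 seeded replicates at
$\sigma = 1$ percent point.

## In-vitro → in-vivo convolution

The predicted plasma profile is the convolution of the systemic input rate
$I(t)$ (mass/min) with the unit impulse response $u(t)$, the plasma
concentration–time curve per unit intravenous dose:

$$C(t) = \int_0^t I(x)\, u(t-x)\, dx .$$

filmkin parameterises $u(t) = \sum_i A_i e^{-\lambda_i t}$
(polyexponential, `uir_model()`), the standard form for intravenous
disposition. Its parameters must come from literature or fitted IV data and
are supplied via `uir_model()` or a JSON/YAML config
(`read_uir_json()`). `placeholder_uir()` ships a clearly flagged synthetic
two-exponential stand-in ($A = (600, 150)$ ng/mL per mg,
$\lambda = (0.15, 0.015)$ min$^{-1}$; distribution and elimination
half-lives of about 5 and 46 min, a plausible shape for a rapidly
distributed lipophilic steroid) so the machinery is fully testable; its
`non_paper = TRUE` flag travels with every output. Concentration units pass
through from the UIR verbatim — the package never rescales them.

Numerical pipeline (`predict_plasma()`):

1. **Input rate** (`input_rate_from_release()`). Cumulative absorbed mass
   $M(t) = f_{bio} \cdot D \cdot F(t)/100$ is interpolated onto a uniform
   grid with the monotone shape-preserving Fritsch–Carlson cubic
   (`splinefun(method = "monoH.FC")`) — an ordinary cubic spline can
   overshoot 100% and create negative rates — then differentiated by
   forward differences. Differencing telescopes, so the mass balance
   $\sum_k I_k \, \Delta t = M(t_{last})$ holds to machine precision.
   Dips in the observed cumulative curve up to 2 percent points are
   treated as analytical noise and flattened; larger dips are an error.
2. **Convolution** (`convolve_profiles()`). Left-rectangle discretisation
   $C_k = \sum_{j \le k} I_j\, u((k-j)\Delta t)\, \Delta t$, i.e. a
   discrete convolution scaled by $\Delta t$, evaluated via FFT. The
   output grid extends past the last input time until $C$ falls below
   0.1% of its maximum, capturing the disposition tail. Default
   $\Delta t = 0.01$ min; at this step the bolus and constant-rate
   closed-form oracles agree to well under 1%, and halving $\Delta t$
   moves $C_{max}$ by under 0.5%.
3. **Metrics** (`pk_metrics()`). $C_{max}$, earliest $T_{max}$ (ties break
   to the earlier time), and trapezoidal $AUC_{0-last}$.

Because convolution is linear, $C(t)$ is proportional to dose and to the
UIR coefficients, and the conservation law
$AUC_C = f_{bio} \cdot D \cdot F_{last}/100 \cdot \sum_i A_i/\lambda_i$
holds up to discretisation error; the test suite asserts it within 1%.
Bioavailability defaults to $f_{bio} = 1$, the usual assumption for buccal
delivery of highly lipophilic drugs, and the default dose is 1.46 mg (a
typical per-film estradiol load).

## Franz-cell permeation

Receptor-chamber sampling with replacement dilutes the receptor, so
cumulative permeated amount per area must add back the withdrawn mass:

$$Q_n = \frac{V_r C_n + V_s \sum_{i<n} C_i}{A},$$

with receptor volume $V_r$, sample volume $V_s$ and diffusion area $A$
(`cumulative_permeated()`; the default `franz_cell()` is the common
2.54 cm² / 5.2 mL / 1 mL configuration). With $V_s = 0$ this reduces to the
naive $V_r C_n / A$. Steady-state flux $J_{ss}$ is the OLS slope of $Q$
versus time over a stated window — closed interval, default 360–480 min,
the late linear phase — converted to µg cm⁻² h⁻¹
(`steady_state_flux()`), and apparent permeability is
$P_{app} = J_{ss}/C_d$ (`apparent_permeability()`). The initial donor
concentration $C_d$ must be given explicitly: whether it is loaded dose
over wetting volume or some other definition is a study-level choice the
package refuses to guess.

## Film mechanics

`tensile_strength()` computes $TS = F_{max}/A$ (N/mm² = MPa) and
`percent_elongation()` computes $PE = 100 \cdot \Delta L / L_0$, the
standard definitions; `film_summary()` gives per-arm mean ± SD tables for
any numeric film metrics. Group-comparison inference is deliberately out of
scope — these are routine ANOVA/t-tests best run directly.

## What the synthetic generators emulate

`simulate_release()` evaluates a model on the 8-point grid
(0, 1.5, …, 13.5 min) and adds independent Gaussian noise (default
$\sigma = 1$ percent point, clamped to $[0, 105]$; the $t=0$ blank stays
exactly 0). Two presets pin the two study arms:

* `nano_emulsion_like` — Hopfenberg $k_{HB} = 0.132, n = 1.05$: 80.8%
  released at 6 min, 99.2% at 7.5 min, complete by 9 min.
* `cosolvency_like` — Weibull $\alpha = 1965, \beta = 3.5$: ~80% at
  10 min, ~98% at 13 min.

`simulate_permeation()` inverts a lag-plus-linear target
$Q(t) = \max(0, J_{ss}(t - t_{lag})/60)$ through the sampling-replacement
correction, so the noise-free series round-trips to the generating flux
exactly (the suite asserts $10^{-9}$); defaults are
$J_{ss} = 0.121$ µg cm⁻² h⁻¹ scale with a 120 min lag, sampled every
30 min to 480 min.

The generators are deliberately simple: additive i.i.d. Gaussian noise, no
between-replicate correlation, no heteroscedasticity (real dissolution
error grows near the analytical limits), no receptor-depletion curvature,
and a placeholder UIR rather than fitted human disposition. Passing tests
therefore demonstrate correctness of the estimators under their stated
assumptions — not that any particular laboratory dataset will meet those
assumptions.

## Problem sizes and determinism

The packaged studies use the sizes a desk check warrants: 100 seeded
replicates for the selection and flux Monte-Carlo studies, $\Delta t =
0.01$ min for convolution oracles (coarser steps for plots and smoke
tests). Every stochastic path takes an explicit seed through
`withr::with_seed`, so identical configs give byte-identical outputs
(`write_report()` round-trips are asserted in the suite).

## Known limitations

* Single-phase models only; biphasic or mechanistic PDE release models are
  out of scope.
* No deconvolution (Wagner–Nelson, numerical deconvolution) — the package
  predicts plasma from release, not the reverse.
* No dissolution similarity factors (f1/f2), no multi-dose superposition,
  no nonlinear pharmacokinetics.
* Near nested submodel boundaries, AIC selection between release models is
  intrinsically ambiguous (see above); report the full ranking table, not
  just the winner.
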