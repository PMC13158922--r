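---
title: "Kinetic modeling of FeTPPS-catalyzed biomimetic drug oxidation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modeling of FeTPPS-catalyzed biomimetic drug oxidation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimoxkin)
```

## The reaction system

Water-soluble iron porphyrins such as FeTPPS mimic the heme center of
cytochrome P450: a peroxide oxidant (tert-butyl hydroperoxide, tBuOOH)
activates the resting catalyst to a high-valent iron-oxo species
(FeTPPS\*), which oxidizes a drug substrate and returns the catalyst to
its resting state; in parallel, the oxidant slowly destroys the catalyst.
`mimoxkin` models this cycle with mass-action rate laws:

$$
\begin{aligned}
\frac{d[\mathrm{FeTPPS}]}{dt} &= -(k_1+k_3)[\mathrm{FeTPPS}][\mathrm{tBuOOH}]
  + k_2[\mathrm{S}][\mathrm{FeTPPS}^*]\\
\frac{d[\mathrm{FeTPPS}^*]}{dt} &= k_1[\mathrm{FeTPPS}][\mathrm{tBuOOH}]
  - k_2[\mathrm{S}][\mathrm{FeTPPS}^*]\\
\frac{d[\mathrm{tBuOOH}]}{dt} &= -(k_1+k_3)[\mathrm{FeTPPS}][\mathrm{tBuOOH}]
  + \delta\\
\frac{d[\mathrm{S}]}{dt} &= -k_2[\mathrm{S}][\mathrm{FeTPPS}^*]
\end{aligned}
$$

with $k_1$ the activation, $k_2$ the substrate-oxidation and $k_3$ the
apparent catalyst-degradation constant (all bimolecular,
conc$^{-1}$ s$^{-1}$). $k_3$ is an overall descriptor: the real
deactivation chemistry involves several parallel channels and this single
second-order term is the coarsest faithful summary. The *extended*
variant adds a direct, non-catalytic channel $-k_4[\mathrm{S}][\mathrm{tBuOOH}]$
to the substrate and oxidant balances, needed for substrates whose decay
is visibly biphasic.

Dosing enters through the initial conditions and the feed term $\delta$.
One-shot dosing places `eqv` substrate-equivalents of oxidant in the
reactor at $t=0$ ($\delta = 0$); continuous dosing starts oxidant-free and
feeds $\delta = \mathrm{eqv}\cdot S_0/t_{\max}$ throughout. The catalyst
loading is tied to the design as $[\mathrm{FeTPPS}]_0 = S_0/\mathrm{eqv}$.
Three cumulative bookkeeping pools (catalytic product, non-catalytic
product, degraded catalyst) are integrated alongside so that catalyst and
substrate conservation are exact identities of the right-hand side; the
tests rely on this.

Volume changes from the syringe feed are ignored, temperature is not a
model input, and pH enters only as a dataset label: runs at different pH
are fitted independently and compared afterwards.

## Observation model and units

Chromatographic peak areas, not concentrations, are what the instrument
delivers, and metabolite response factors are generally unknown. The
package therefore fits the substrate channel only and works directly on
the response scale: the model is integrated with the initial response
(area units) in place of $S_0$, which simply rescales the bimolecular
constants by the response factor without changing any trajectory shape —
joint rescaling invariance is asserted in the test suite. Fitted
constants are consequently reported *per response unit per second* unless
true concentrations are supplied; with the default `response_scale = 1`
areas equal concentrations numerically. Time is seconds internally;
data files carry minutes and are converted on read.

## The synthetic-data generator

No raw peak-area data are published for this chemistry, so the package
generates its own study material. `default_design()` encodes the
laboratory protocol: $S_0 = 5\times10^{-4}$ mol L$^{-1}$, 10 oxidant
equivalents fed continuously over 60 min, sampling at 2, 4, 6, 8, 10, 15,
20, 25, 30, 40, 50 and 60 min, triplicates. `default_truth()`
($k_1 = 2$, $k_2 = 200$, $k_3 = 0.2$) yields roughly 76% conversion in
the hour — substantial but incomplete, the phenotype of the well-behaved
substrates. Noise is multiplicative lognormal with mean 1 and `cv = 0.05`
(plus an optional additive floor, default 0): replicate scatter grows
with the signal, reproducing the heteroscedasticity visible in real
residual plots. The published work states no noise magnitude; 5% relative
scatter is typical of integrated HPLC peak areas in triplicate work.

`biphasic_truth()` ($k_1 = 80$, $k_2 = 200$, $k_3 = 40$, $k_4 = 0.3$) is
a deliberate stress scenario for model selection: fast activation and
fast degradation produce an early catalytic phase that stalls when the
catalyst dies, after which accumulating oxidant drives a second decay
phase through the direct channel (about three quarters of the substrate
flux). The two-step shape is essential, not cosmetic: a *gently*
biphasic curve whose late acceleration merely tracks the oxidant level
can be reproduced exactly by the standard model, because the standard
activation flux $k_1[\mathrm{FeTPPS}][\mathrm{tBuOOH}]$ is itself
proportional to the oxidant level and the catalyst pool can be made to
decay in proportion to the substrate (set $(k_1+k_3)\approx k_4$ and the
two models coincide on the substrate channel). Only decay that *resumes
after catalyst death* is outside the standard model's reach. This
observational near-equivalence is a real feature of the chemistry under
continuous dosing, and it shapes everything said below about
identifiability.

What the generator does not emulate: chromatographic drift, carryover,
ionization suppression, replicate-level systematic offsets, or any
pH-dependent mechanism change. Passing recovery tests on this material
therefore demonstrates correctness of the estimation machinery under the
assumed noise model, not robustness to instrument pathology.

## Fitting protocol

`fit_kinetics()` minimizes the pooled sum of squared residuals between
observed substrate areas and model predictions over all replicates and
times (replicates are pooled, not modeled hierarchically), using
Levenberg–Marquardt (`minpack.lm::nls.lm`) on the *log* rate constants,
which enforces positivity and is the scale on which standard errors and
Wald intervals are formed. Multistart initialization replaces manual
guessing: the first start is a fixed data-scaled point, the rest are
log-uniform draws over $[10^{-3}, 10^{3}]$ times the dimensional scale
$1/(S_{0,\mathrm{area}}\, t_{\max})$; 16 starts by default, 4 in the large
repeated studies below. Optimization is two-stage: all starts are
explored with the integrator at relative tolerance $10^{-8}$, then the
best candidate is polished at $10^{-12}$. The polish matters: the SSR
surface has a long, curved, nearly flat valley (next section), and at
$10^{-8}$ the integration error is larger than the residual differences
along the valley, so the finite-difference Jacobian turns to noise and
the optimizer stalls mid-valley. With the polish, noiseless data are
recovered to better than $10^{-5}$ relative.

The initial response defaults to the descriptor's nominal
$S_0 \times$ `response_scale`. When that value is not trusted — the
situation with real areas — `refine_initial_value()` re-estimates it by
refitting over a grid of 20 evenly spaced candidates within $\pm 3$
"global" standard deviations of the experimental mean, keeping the
candidate with the smallest residual SD and never returning a worse fit
than it received. The global SD is read as the replicate SD of the
earliest sampled time (the published protocol does not say whether it
means the SD of the first samples or of all samples; the earliest-time
reading is the conservative one and is exposed as an argument).

Convergence uses `ftol = 1e-10` on the relative SSR change,
`gtol = 1e-8`, an internal `ptol = 1e-15` (the default parameter
tolerance stops the flat-valley descent prematurely), and at most 500
iterations. Parameter points where the ODE solver fails return large
finite penalty residuals so the optimizer can retreat; the count is
reported as a warning.

Standard errors come from the Gauss–Newton covariance
$\hat\sigma^2 (J^\top J)^{-1}$ in log space with
$\hat\sigma^2 = \mathrm{SSR}/(n-p)$ and $J$ the forward-difference
Jacobian at the optimum. A singular $J^\top J$ is inverted by SVD
pseudo-inverse and flagged (`identifiability_warning`); this reports the
minimum-norm answer rather than refusing, matching how practitioners
actually read such fits, but it means rank-deficient directions show
*small* rather than infinite uncertainty — one more reason the
correlation diagnostics below matter.

## Practical identifiability: what these data can and cannot pin down

Under the default continuous design the cycle runs close to quasi-steady
state in the activated catalyst: $k_2 S \gg k_1 X$ most of the time, so
the substrate decay rate is approximately the activation flux
$k_1[\mathrm{FeTPPS}][\mathrm{tBuOOH}]$ — nearly independent of $k_2$.
Substrate-only data then determine $k_1$ well, but $(k_2, k_3)$ only
through a weakly curved combination: the noiseless substrate curve at
$(2.17, 21, \sim 0)$ differs from the one at the generating truth
$(2, 200, 0.2)$ by under 3% of $S_0$, below the 5% replicate noise. At
`cv = 0.05` the maximum-likelihood estimate wanders to one or the other
end of this valley ($k_3 \to 0$, or $k_2$ arbitrarily large with $k_3$
recovered), and no optimizer can do better, because the data genuinely do
not contain the information: warm-starting *at the truth* descends to a
lower-SSR point elsewhere on the valley. In 20-seed pilot runs $k_1$ was
recovered within a factor of 2 in every run while $k_2$ essentially never
was. This is the package's reproduction, in controlled conditions, of
the identifiability warnings that accompany real fits of this chemistry
— standard errors comparable to the estimates and parameter correlations
above 0.9 — and it is why the diagnostics module treats the correlation
matrix and the high-correlation flags as first-class outputs rather than
afterthoughts. Full-information recovery of all three constants at this
truth should not be expected from substrate-only data on this design, and
the acceptance study reports honestly whatever rates it measures.
Designs that sample the first two minutes densely, observe a second
channel, or lower the oxidant excess would break the quasi-steady-state
degeneracy.

## Uncertainty propagation

`wald_ci()` back-transforms $\log\hat\theta \pm z\,SE_{\log}$, keeping
bounds positive. `monte_carlo_bands()` draws 100 parameter sets (the
published protocol's count) independently per parameter, re-integrates
each, and takes pointwise 2.5/97.5 percentiles. Sampling is normal in
log-parameters by default — consistent with positivity and with the log
scale of the standard errors — while `scale = "natural"` reproduces the
literal published procedure (normal on the original scale, truncated at
zero). Draws are independent because the source procedure was; a
covariance-correlated mode exists behind `correlated = TRUE` but is off
by default. Failed integrations are dropped and counted rather than
redrawn (the source does not say which; dropping is reported via
`n_failed`), and more than 50% failures aborts the band.

## Model selection

`select_model()` implements the parsimony rule for the nested pair: the
extended model is chosen only when it improves AIC
($n\ln(\mathrm{SSR}/n) + 2p$, Gaussian constants dropped) by at least 2
*and* its fitted non-catalytic pathway is non-negligible, quantified as
$k_4 \max(S\cdot X) > 5\%$ of $k_2 \max(S\cdot \mathrm{FeTPPS}^*)$ along
the fitted trajectory (the source states the negligibility condition only
qualitatively; the 5% peak-flux rule is this package's quantification).
Ties retain the standard model, and a $k_4 = 0$ fit can never select the
extended variant. Because the extended model contains the standard one at
$k_4 = 0$, `fit_both_variants()` alternates warm starts between the two
fits (extended seeded from the standard optimum plus a vanishing $k_4$,
standard re-polished from the extended optimum's $k_1$–$k_3$) until
neither improves — without this, random multistarts occasionally leave
one variant at a worse local optimum and the AIC comparison measures
optimizer luck instead of model adequacy. With the symmetric protocol the
false-extended rate on $k_4 = 0$ data sits near the $\chi^2_1$
noise-overfit expectation ($P[\Delta\mathrm{AIC} \ge 2] \approx 5\%$).
An unconverged variant defers selection; `run_pipeline()` and the
selection studies then retain the parsimonious standard model and record
the deferral.

## Clearance normalization

At low substrate concentration the pharmacokinetic definition of
clearance applied to the cycle gives
$CL(t) = v/[\mathrm{S}] = k_2[\mathrm{FeTPPS}^*]$, hence the exact
identity $k_2/CL(t) \cdot [\mathrm{FeTPPS}^*](t) = 1$: the activated
catalyst plays the role of the effective enzyme abundance
$[E]_\mathrm{Total}$ and $k_2$ that of the turnover number $k_{cat}$.
`steady_state_check()` verifies the identity numerically (it holds to
$10^{-10}$, being algebraic) and reports the relative variation of
$CL(t)$, which measures how defensible a *constant* $k_2/CL$ summary is
for that run. `exclusion_flag()` operationalizes the published exclusion
of runs with rapidly varying FeTPPS\*: coefficient of variation of
$[\mathrm{FeTPPS}^*]$ above 0.5 over the central-to-final window
$[0.2\,t_{\max}, t_{\max}]$ excludes the run; both the window and the
threshold are arguments because the source gives no numbers.

Literature intrinsic clearances arrive in two unit conventions;
`convert_clearance()` passes body-weight-normalized values through and
multiplies per-mg-microsomal-protein values by the single published
factor 0.07 exactly as stated (the factor is taken to subsume the
$\mu$L min$^{-1}\to$ L h$^{-1}$ conversion; this assumption is
documented rather than second-guessed). `k2_over_cl()` reports the
ratio under the table's display convention — one significant figure,
halves away from zero, guarded against binary-representation error so
quotients like $6\times10^{-6}/0.08$ land on the intended digit. The
built-in `clearance_table()` reproduces every internally consistent
published row exactly; one row (buspirone at pH 4.5) is flagged because
its printed ratio cannot be obtained from its own printed numerator and
denominator. `mean_charge()` is the Henderson–Hasselbalch bookkeeping
helper for relating $k_2$ shifts to ionization; pKa values are user
input, not package data.

## Numerical choices

* Integration: `deSolve::ode` (lsoda) with a compiled-C right-hand side;
  defaults rtol $10^{-8}$, atol $10^{-12}$ — the system stiffens when
  $k_2 \gg k_1$. Inside the fitting objective the tolerances are much
  tighter (see the two-stage protocol above).
* Negative undershoot: clipped to zero on output; an undershoot beyond
  $10^3 \times$ atol aborts as an integration failure.
* Dense output: 601 evenly spaced points over the reaction window for
  bands and plots, independent of the sampling grid.
* Degenerate inputs: zero replicate SD makes the $s_0$ refinement return
  the experimental mean with a notice; SSR $= 0$ makes AIC report
  $-\infty$ with a notice; an all-zero FeTPPS\* window reports the
  steady-state identity as undefined.
* Study sizes: the repeated studies in the test suite and the acceptance
  script use 100 seeded datasets per arm with 4 multistarts per fit;
  single analyses default to 16 starts. The Euler cross-check uses a
  fixed step of $10^{-3}$ s over the full hour.

## Limitations

Single-curve substrate-channel fitting on the standard design cannot
separate $k_2$ from $k_3$ at high $k_2/k_1$ (see the identifiability
section); metabolite channels are generated but never fitted, because
their response factors are unknowable in the real assay; replicates are
pooled rather than modeled; no profile-likelihood or bootstrap intervals
are provided; and the standard/extended pair is observationally
near-equivalent under continuous dosing except for two-step decays, so
model selection should be read as a statement about curve shape, not
mechanism.
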