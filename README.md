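# mimoxkin

Kinetic modeling of metalloporphyrin-catalyzed biomimetic drug oxidation.

Liver microsomes are the gold standard for measuring a drug's oxidative
metabolic lability, but chemical mimics of the cytochrome P450 active
site — here the water-soluble iron porphyrin FeTPPS activated by
tert-butyl hydroperoxide (tBuOOH) — offer a cheap, cell-free alternative
if their kinetics can be put on a quantitative footing. `mimoxkin` is an
R package plus analysis workflow for exactly that: mechanistic ODE
modeling of the catalytic cycle, nonlinear least-squares estimation of
the rate constants from chromatographic peak-area time series, honest
uncertainty and identifiability diagnostics, and normalization of the
fitted oxidation constant against literature intrinsic clearance.

## The model

Mass-action rate laws for catalyst activation, substrate oxidation and
oxidative catalyst degradation:

$$
\begin{aligned}
d[\mathrm{FeTPPS}]/dt &= -(k_1+k_3)\,[\mathrm{FeTPPS}][\mathrm{tBuOOH}] + k_2\,[\mathrm{S}][\mathrm{FeTPPS}^*] \\
d[\mathrm{FeTPPS}^*]/dt &= k_1\,[\mathrm{FeTPPS}][\mathrm{tBuOOH}] - k_2\,[\mathrm{S}][\mathrm{FeTPPS}^*] \\
d[\mathrm{tBuOOH}]/dt &= -(k_1+k_3)\,[\mathrm{FeTPPS}][\mathrm{tBuOOH}] + \delta \\
d[\mathrm{S}]/dt &= -k_2\,[\mathrm{S}][\mathrm{FeTPPS}^*]
\end{aligned}
$$

One-shot dosing puts the whole oxidant charge in at $t=0$
($\delta = 0$); continuous dosing feeds it at
$\delta = \mathrm{eqv}\cdot S_0 / t_{\max}$. An extended variant adds a
direct non-catalytic channel $-k_4[\mathrm{S}][\mathrm{tBuOOH}]$ for
substrates with two-step decay curves. Fits run on the log rate
constants via multistart Levenberg–Marquardt; uncertainty comes from
log-scale Wald intervals and 100-draw parametric Monte Carlo trajectory
bands; the parsimony rule (AIC improvement of at least 2 *and* a
non-negligible fitted $k_4$ flux) decides between the variants; and the
steady-state identity $CL = k_2[\mathrm{FeTPPS}^*]$ connects the fitted
chemistry to pharmacokinetic clearance, giving the normalized ratio
$k_2/CL = 1/[\mathrm{FeTPPS}^*]$.

## Worked example

```r
library(mimoxkin)

# triplicate peak-area series, 5% multiplicative noise, standard design:
# 500 umol/L substrate, 10 equivalents tBuOOH fed over 60 min
ds  <- generate_dataset(default_truth(), default_design(),
                        noise_model(cv = 0.05, seed = 101))
res <- run_pipeline(ds, out_dir = "results/demo", seed = 42,
                    n_draws = 100, n_starts = 8)
res$selection$variant
#> [1] "standard"
unlist(res$fit$estimates)
#>       k1       k2       k3
#> 1.90e+00 1.56e+13 2.01e-01
res$diagnostics$high_corr_pairs$r
#> k1-k2, k1-k3, k2-k3 all |r| > 0.9
```

The run (generating truth $k_1=2$, $k_2=200$, $k_3=0.2$ per response
unit per second) illustrates the central scientific caveat: $k_1$ and
$k_3$ come back within 5% of truth, while $k_2$ runs away to a huge
value with all pairwise parameter correlations flagged above 0.9. Under
continuous dosing the cycle sits in quasi-steady state, substrate decay
tracks the activation flux, and substrate-only data simply do not pin
$k_2$ down — the same practical-identifiability warning that accompanies
fits to the real chemistry, here reproduced under controlled conditions.
The predicted curves are nonetheless accurate: the 95% Monte Carlo band
for the substrate at 60 min, `[4.2e-05, 1.7e-04]`, comfortably covers
the true value `1.2e-04`.

On biphasic data (catalytic phase, catalyst-death stall, renewed
non-catalytic decay; truth $k_4 = 0.3$) the same pipeline selects the
extended model and recovers `k4 = 0.301`:

```r
ds2 <- generate_dataset(biphasic_truth(), default_design(),
                        noise_model(cv = 0.05, seed = 202))
fits <- fit_both_variants(ds2, fit_options(n_starts = 8, seed = 42))
select_model(fits$standard, fits$extended)$variant
#> [1] "extended"   (AIC -784.8 vs -741.9; k4 flux fraction 0.38)
```

The clearance module reproduces every internally consistent row of the
published $k_2/CL$ comparison exactly from its printed inputs
(12/12; one buspirone row is flagged because its printed ratio cannot
be derived from its own printed $k_2$ and $CL$):

```r
k2_over_cl(2.8e-6, 13.37)   # chlorpromazine, pH 4.5
#> [1] 2e-07
```

## Analysis workflow

Numbered drivers under `analysis/` rerun the full study and write tables
under `results/`:

| script | what it does |
| --- | --- |
| `01_simulate.R` | trajectories under both dosing modes; half-conversion contrast (13.9 vs 40.0 min) |
| `02_generate_data.R` | synthetic triplicate datasets (standard + biphasic truth) |
| `03_fit_and_select.R` | both model variants, parsimony selection, diagnostics |
| `04_uncertainty.R` | Wald intervals and 95% Monte Carlo bands |
| `05_clearance.R` | published k2/CL reproduction, steady-state identity, exclusion rule, charge helper |

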