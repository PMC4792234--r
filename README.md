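# micalkin

Steady-state kinetic analysis of non-essential activation in MICAL-family
monooxygenases, plus the solution mass-estimation calculations (SEC
calibration, SAXS Guinier / volume-of-correlation / forward-scattering
mass) used to characterise the constructs — with a synthetic assay
generator so the whole analysis is testable without any experimental data.

## The problem

MICAL enzymes oxidise NADPH at a basal rate that F-actin accelerates
without being required for turnover — a *non-essential activator*. The
question the kinetics answer is mechanistic: does the calponin-homology
(CH) domain merely sit next to the catalytic monooxygenase (MO) domain, or
does it couple actin binding to the active site? The rapid-equilibrium
activator model makes that question quantitative:

```
v = E·k_cat·(S/K_M)·(1 + β·A/(α·K_act)) / (1 + S/K_M + A/K_act + S·A/(α·K_M·K_act))
```

with S = [NADPH], A = [F-actin], E = total enzyme. `β` is the turnover
acceleration in the ternary complex; `α` is the binding coupling — `α = 1`
means actin binding leaves NADPH affinity untouched, `α < 1` means the two
ligands mutually enhance each other's binding. At fixed A the law collapses
to a Michaelis–Menten form whose apparent constants

```
k_cat_app(A) = k_cat·(1 + β·A/(α·K_act)) / (1 + A/(α·K_act))
K_M_app(A)  = K_M·(1 + A/K_act) / (1 + A/(α·K_act))
```

drift with activator unless `α = 1`. Whether `α` is needed at all is
decided by an extra-sum-of-squares F-test between the five-parameter global
fit and the fit with `α` pinned at 1. For the isolated MO domain `α = 1`
suffices; for the MO-CH construct the data demand `α ≈ 0.16` — the CH
domain couples actin binding to a ~6-fold NADPH affinity gain on top of a
β ≈ 7.4 rate acceleration, lifting catalytic power more than 20-fold
across the assayed actin range.

The package implements the rate law and its apparent-parameter
decomposition, a generator of replicate initial-rate campaigns and
absorbance progress traces with the published assay design, per-activator
and global least-squares fitting with Gauss–Newton standard errors, the
nested-model F-test, and the three solution-mass estimators.

## Worked example

Simulate the MO-CH campaign (NADPH 10–150 µM × F-actin 0–8 µM, 600 nM
enzyme, 3 replicates, 3% velocity CV) from the published global parameters,
then refit:

```r
library(micalkin)
truth  <- mical_params("MO-CH")          # k_cat 1.7, K_M 37.7, K_act 10.5, α 0.16, β 7.43
rates  <- generate_dataset(truth, mical_design("MO-CH", seed = 7))
fit    <- fit_global(rates)
print(fit)
#> Fit result [global_alpha_free]
#>   k_cat   = 1.72739  (SE 0.0969)
#>   K_M     = 39.2011  (SE 4.16)
#>   K_act   = 10.8357  (SE 2.19)
#>   alpha   = 0.147618  (SE 0.0369)
#>   beta    = 7.19251  (SE 0.471)
#>   rss = 0.624424, dof = 55, n = 60
extra_ss_f_test(fit_global(rates, fix_alpha = 1), fit)
#> Extra-sum-of-squares F-test: F(1, 55) = 76.91, p = 4.944e-12
```

All five parameters come back within ~1 SE of the generating truth, and the
F-test rejects the uncoupled (`α = 1`) model decisively — the inference the
real data support for MO-CH. From printed apparent constants, the
catalytic-power arithmetic reproduces the published summary row exactly:

```r
round_half_up(catalytic_power(c(1.7, 7.9, 10.0, 10.3),
                              c(37.7, 23.9, 17.5, 9.9)), 1)
#> [1]   45.1  330.5  571.4 1040.4
```

The `analysis/` directory holds the full narrative workflow — run from the
repository root after installing:

* `01_simulate_assays.R` — both campaign datasets plus example traces
  (including an activator-depletion trace) into `results/`
* `02_fit_kinetics.R` — apparent-constant tables, global fits, F-tests
* `03_mass_metrics.R` — SEC calibration on the packaged synthetic
  standards, toy-sphere Debye profile → Guinier → volume-of-correlation
  round trip, forward-scattering-ratio mass, and percent deviations from
  the 68 425 Da sequence+FAD mass

The methods vignette (`vignettes/activator-kinetics.Rmd`) documents the
model assumptions, noise model, optimizer contract and numerical choices.

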