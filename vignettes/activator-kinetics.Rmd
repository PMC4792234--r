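---
title: "Non-essential activator kinetics and solution mass metrics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-essential activator kinetics and solution mass metrics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micalkin)
```

# The kinetic model

MICAL-family monooxygenases oxidise NADPH at a basal rate that is
accelerated — but not gated — by filamentous actin. The appropriate
steady-state description is the rapid-equilibrium *non-essential activator*
scheme: the enzyme E binds substrate S (NADPH) with dissociation constant
$K_M$ and activator A (F-actin) with dissociation constant $K_{act}$; in
the ternary complex the substrate constant is rescaled by the coupling
factor $\alpha$ (thermodynamic linkage forces the same factor onto the
activator constant of the ES complex), and turnover is rescaled by the
acceleration factor $\beta$:

$$
v \;=\; \frac{E\,k_{cat}\,\dfrac{S}{K_M}\left(1 + \beta\dfrac{A}{\alpha K_{act}}\right)}
{1 + \dfrac{S}{K_M} + \dfrac{A}{K_{act}} + \dfrac{S\,A}{\alpha K_M K_{act}}}.
$$

Assumptions worth keeping in mind:

* **Rapid equilibrium** — all binding steps are fast relative to turnover,
  so species abundances are set by the equilibrium constants alone.
* **Non-limiting substrate and activator** — free concentrations equal
  totals; with 600 nM enzyme against micromolar ligands this is a mild
  approximation.
* **Initial-rate regime** — the model describes the velocity before either
  pool is meaningfully consumed.

Two identities anchor the implementation and are enforced by tests:
$\alpha = \beta = 1$ collapses the model to single-substrate
Michaelis–Menten for every activator concentration, and at any fixed $A$
the rate law factors exactly into an apparent Michaelis–Menten form with

$$
k_{cat}^{app}(A) = k_{cat}\frac{1 + \beta A/(\alpha K_{act})}{1 + A/(\alpha K_{act})},
\qquad
K_M^{app}(A) = K_M\frac{1 + A/K_{act}}{1 + A/(\alpha K_{act})}.
$$

`velocity()` implements the packed form; the test suite checks it to
$10^{-10}$ relative against an independently written four-species
enumeration (relative abundances $1, S/K_M, A/K_{act},
SA/(\alpha K_M K_{act})$, turnover $k_{cat}$ on ES and $\beta k_{cat}$ on
ESA) and against the apparent-form decomposition on random draws.

$K_M^{app}$ is constant in activator exactly when $\alpha = 1$; a falling
$K_M^{app}$ across activator levels is the fingerprint of positive coupling
($\alpha < 1$), which is what distinguishes the MO-CH construct
($\alpha \approx 0.16$) from the isolated MO domain ($\alpha = 1$).
Catalytic power is reported as $1000\,k_{cat}^{app}/K_M^{app}$ in
s$^{-1}$mM$^{-1}$, and printed tables use half-away-from-zero rounding,
which reproduces the published summary rows digit for digit.

## Parameters and defaults

| parameter | meaning | units | MO | MO-CH |
|---|---|---|---|---|
| $k_{cat}$ | turnover of ES | 1/s | 0.68 | 1.7 |
| $K_M$ | NADPH dissociation constant | µM | 28.8 | 37.7 |
| $K_{act}$ | F-actin dissociation constant | µM | 9.3 | 10.5 |
| $\alpha$ | binding coupling | — | 1 (restrained) | 0.16 |
| $\beta$ | turnover acceleration | — | 4.7 | 7.43 |

These are the published global estimates, exposed by `mical_params()`. The
narrative quoting of the two K constants swaps their labels relative to the
methods definition; this package follows the numerically consistent
assignment, in which the zero-actin apparent $K_M$ (28.8 / 37.7 µM) is the
NADPH constant. Where $\beta$ is quoted twice with different precision we
use 7.43 (MO-CH) and 4.7 (MO).

# The synthetic assay generator

`mical_design()` reproduces the two assay campaigns: 600 nM enzyme;
NADPH at 3–100 µM (six levels) against F-actin at
{0, 0.45, 0.9, 2.2, 7.5} µM for MO, and NADPH at 10–150 µM (five
levels) against {0, 2, 4, 8} µM for MO-CH; three replicates per
condition. The second MO actin level is stored as 0.45 µM, matching the
summary-table header rather than the methods text (0.4); the choice is
arbitrary and configurable.

Replicate velocities are drawn as `v_true * (1 + N(0, cv))`, truncated at
zero, with `cv = 0.03` by default: multiplicative noise reproduces the
roughly constant *relative* scatter of replicate initial rates seen in
published error bars, and 3% is a realistic bench value for a manual
cuvette assay. Each condition draws from its own deterministic substream of
the design seed, so a dataset is reproducible bit-for-bit and independent
of grid iteration order.

`simulate_trace()` produces full absorbance records: substrate depletion
`dS/dt = -v(S, A)` is integrated with a fixed-step classical 4th-order
Runge–Kutta scheme (`deSolve::ode(method = "rk4")`, default
`dt = 0.05` s, validated against `dt/10` re-integration to $10^{-4}$
relative), converted to absorbance with
$\varepsilon_{340} = 6220\,\mathrm{M^{-1}cm^{-1}}$ and a 1 cm path —
standard NADPH values, both configurable, since the source assay reports
neither. `extract_initial_rate()` is the measurement model: an ordinary
least-squares slope over a read window (default 5–10 s, the window used
once mixing has settled), divided by $\varepsilon\ell$. Negative slope
estimates within 3 SE of zero are clipped to zero with a warning.

With `deplete_activator = TRUE` the activator pool is consumed
stoichiometrically with NADPH (default 1:1, configurable sites per
filament), which produces the biphasic decay observed when reducing
equivalents consumed during the read window exceed the activator present.
This is a simulation knob for exploring that scenario, not a mechanistic
claim. Because the activated:basal velocity ratio at 0.4 µM activator is
only ~2.3 and velocity falls smoothly as the pool is consumed, the two
phases are best contrasted with well-separated windows (e.g. 0–3 s
versus 20–30 s at an enzyme concentration that stretches depletion to
~15 s); adjacent 5 s windows straddling the transition differ by far
less than the asymptotic contrast.

What the generator does *not* emulate: mixing dead time, photobleaching and
instrument drift, actin polymerisation dynamics, oxygen dependence, and any
systematic (non-Gaussian, condition-correlated) error. Passing recovery
tests on these synthetic campaigns therefore demonstrates that the
estimator is consistent and well-calibrated under the stated noise model —
not that real assays are free of systematic error.

# Fitting and inference

`fit_michaelis_menten()` and `fit_global()` minimise unweighted residual
sums of squares with Levenberg–Marquardt (`minpack.lm::nls.lm`, box
bounds, `ftol = ptol = 1e-12`). Unweighted least squares is the default
because the source analysis does not state weights; `weights = 1/SEM^2` is
available. Bounds are $k_{cat}, K_M, K_{act} > 0$,
$\alpha \in (10^{-3}, 10^3)$, $\beta \in [0, 10^3]$.

Initialisation is data-driven: the zero-activator slice seeds
$k_{cat}, K_M$; the top-activator slice seeds $\beta$ (ratio of apparent
$k_{cat}$) and $\alpha$ (ratio of apparent $K_M$); $K_{act}$ starts at the
median positive activator level. The default 8 multi-starts perturb this
seed log-uniformly by up to half a decade; starts use a private RNG stream
so fits are deterministic and leave the caller's RNG untouched. Standard
errors are Gauss–Newton: $(J^TJ)^{-1}\,\mathrm{rss}/\mathrm{dof}$ from a
central-difference Jacobian at the optimum, the convention of common
curve-fitting software. Degenerate inputs are flagged rather than fitted
silently: substrate-independent data drive $K_M$ into a bound and clear the
`converged` flag, and the global fit requires at least two activator levels
including zero, without which $\beta$ is unidentifiable.

Model selection uses the extra-sum-of-squares F-test between the
$\alpha$-free and $\alpha = 1$ fits:
$F = \frac{(RSS_r - RSS_f)/(df_r - df_f)}{RSS_f/df_f}$, with the p-value
from the F upper tail. A small RSS inversion (restricted below full, within
$10^{-8}$ relative) is clamped to zero — it can only arise from optimizer
tolerance; anything larger errors, since it means the fits are not nested
or one failed.

Validation at the published design (MO-CH grid, 3 replicates, 3% CV) uses
200 simulated campaigns for recovery (median relative bias of each
parameter < 5%, ±2 SE coverage ≥ 85%), 100 for the monotone-$K_M^{app}$
diagnostic, 2000 for the F-test's type-I error (0.05 ± 0.02) and 200 for
its power against $\alpha = 0.16$ (≥ 90%). These problem sizes give
Monte-Carlo standard errors comfortably below the margins being checked
while keeping the suite quick to run.

# Solution mass metrics

Three independent estimators of particle mass in solution are provided,
with a toy-structure generator so all of them are testable without any
experimental profile.

* **SEC**: `sec_calibration()` fits $\log_{10}(M)$ against $V_e/V_o$ on
  standards; `sec_predict_mass()` inverts it. The packaged
  `sec_standards_synthetic.tsv` is a synthetic five-standard set (classical
  gel-filtration markers on a log-linear curve with 0.4% jitter,
  Superose-12-scale volumes), *not* measured data.
* **Guinier**: `guinier_fit()` fits $\ln I$ vs $q^2$ with the cutoff
  $q R_g \le 1.3$ iterated to self-consistency (the community convention
  for globular particles; the cutoff is a parameter). Positive slope —
  no decay at small angle — is an error, not a number.
* **Volume of correlation**: $V_c = I(0) / \int_0^{q_u} q I(q)\,dq$ with
  trapezoidal integration and the unmeasured $0 \to q_{min}$ segment filled
  by the closed-form Guinier integral; mass is $(V_c^2/R_g)/1.231$. The
  1.231 denominator is treated as an opaque published empirical constant
  for protein at $q_u \approx 0.3\,\mathrm{Å^{-1}}$; no attempt is made to
  re-derive its q-range dependence.
* **Forward-scattering ratio**: mass from
  $M_{std}\,(I_0/c)_{sample}/(I_0/c)_{std}$ against a standard of known
  mass (the published analysis used dimeric BSA, 132 kDa).

`toy_profile()` evaluates the Debye sum
$I(q) = \sum_{ij} \sin(qd_{ij})/(qd_{ij})$ over a coordinate set. Above
2000 points the double sum is evaluated through a 512-bin pair-distance
histogram; at the bin widths and q ranges used this reproduces the exact
sum to well under 0.1%, and the suite asserts that agreement directly.
`coordinate_rg()` gives the real-space radius of gyration, closing the
round trip: for a uniform ball of radius 30 Å both routes must land within
2% of $\sqrt{3/5}\cdot 30 = 23.24$ Å.

# Known limitations

* The kinetic model is steady-state and rapid-equilibrium only: no
  pre-steady-state phases, substrate inhibition, oxygen dependence, or
  ordered ternary mechanisms.
* Standard errors are local (Gauss–Newton); strongly correlated parameters
  (notably $K_{act}$ with $\alpha$ and $\beta$) can make 2 SE intervals
  approximate at a single campaign's size. Bootstrap or profile intervals
  are out of scope.
* The noise model is uncorrelated and multiplicative; real replicate
  structure (day effects, shared actin preps) would widen true uncertainty.
* The mass estimators assume dilute, monodisperse, protein-typical
  scattering; the Vc constant is specific to that regime.
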