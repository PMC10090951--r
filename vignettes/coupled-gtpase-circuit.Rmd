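---
title: "Modeling a Golgi-localized coupled GTPase circuit"
author: "coupledGTPase package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling a Golgi-localized coupled GTPase circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coupledGTPase)
```

## The circuit

Secretion at the Golgi is controlled by two coupled molecular switches: a
monomeric GTPase of the Arf1 family (mG) and a trimeric GTPase of the Gi
family (tG). Growth-factor stimulus recruits the GEF for the mGTPase (mGEF),
which switches mG on; active mG recruits GIV/Girdin, the GEF for the
tGTPase (tGEF); active tG then releases effectors which, together with tGEF
itself, activate the GAP for the mGTPase (mGAP). mGAP both switches mG off
and drives vesicle formation, i.e. secretion. The forward arrow plus the two
feedback arrows form closed-loop control between the two switches. Secreted
growth factors feed back on cell number through an autocrine
secrete-and-sense loop.

The package models this circuit with logic-based ordinary differential
equations in seven variables: the fractional activations of mGEF, mGAP, mG*,
tGEF and tG*, the secreted growth-factor amount S, and the cell number X.
Each regulatory arrow is a *normalized Hill function*

$$f(x) = \frac{B\,x^n}{K^n + x^n} \;(0 \le x < 1),\qquad f(x) = 1 \;(x \ge 1),$$

with $B = (EC_{50}^n - 1)/(2EC_{50}^n - 1)$ and $K = (B-1)^{1/n}$, so that
$f(0)=0$, $f(EC_{50})=0.5$ and $f(1)=1$. These constants are real and
positive only when $EC_{50}^n < 0.5$; `hillConstants()` rejects degenerate
combinations. We extend $f$ to negative inputs by returning 0: stochastic
noise can transiently push an argument below zero, and the extension keeps
activations inside [0, 1] while preserving continuity at 0.

The five GTPase variables follow tau-scaled relaxation equations; for
example $\tau_{mGAP}\,d\,mGAP/dt = (f_2(tGEF)f_3(tG^*) + k_{mGAP})Y^{max}_{mGAP} - mGAP$
for the AND-gate feedback onto mGAP. The secretion and cell equations are

$$dS/dt = \big(\beta_S f_9(mGAP) + k_S - \alpha_S \tfrac{S}{S+K_2}\big)X - \gamma S,
\qquad
dX/dt = \lambda \tfrac{S}{S+K_1}\big(1 - \tfrac{X}{K}\big) - \mu X.$$

Three variants are provided: `coupled` (the full circuit), `uncoupled` (a
single mG switch: the mGAP equation loses its feedback drive and relaxes to
its basal level), and `giv_depleted` (the coupled circuit with
$Y^{max}_{tGEF} = 0.1$, i.e. 10% of the control GIV level). The feedback
gate is `AND` (product of the two arrows) or `OR` (weighted sum
$c_{tGEF} f_2 + c_{tG^*} f_3$ with constants 0.24 and 0.0017, placed as
multipliers of the two activation terms; the placement is configurable
through the parameter object because only the constants, not their exact
algebraic position, are conventionally reported).

## The parameter table

The kinetic constants used throughout are bundled as
`inst/extdata/params_synthetic.yaml` and loaded by
`defaultCircuitParameters()`. The original parameter table for this type of
circuit is distributed as supplementary material rather than printed, so the
bundled set is a synthetic reconstruction: it was calibrated with this
package's own machinery so that the model reproduces the canonical reported
behaviors of the circuit —

* active mG* rises ~3-fold by 5 min after a 0.23 stimulus step and declines
  again by 30 min (the transient created by the delayed negative feedback);
* under GIV depletion the same stimulus gives a sustained mG* response,
  and the mGEF/mGAP/mG* trajectories approach those of the uncoupled
  variant;
* the steady-state mGEF to mG* relation is nearly linear across doses
  (dose-response alignment, DoRA), while a single uncoupled switch is
  hyperresponsive;
* the stimulus to secretion and stimulus to tG* dose responses are mildly
  ultrasensitive (fitted Hill coefficients near 1.9 and 1.7), and the tGEF
  to tG* relation sits close to the saturated regime of a strongly
  ultrasensitive curve (fitted Hill coefficient near 3.8);
* with the OR-gate constants 0.24/0.0017 the basal steady state matches the
  AND gate to within 1%.

Calibrating parameters against observed trends is the same workflow the
fitting module automates (`fitParameters()`), and no claim of parameter
identifiability is attached: the set is *a* parameterization consistent with
those behaviors, not a unique estimate.

Stimulus units follow the EGF normalization convention: concentrations in
nM are divided by 217.4 nM (= 50 nM / 0.23), so 50 nM corresponds to the
standard simulation stimulus 0.23 (`egfToStimulus()`).

## Deterministic simulation

All deterministic solves use the stiff-capable adaptive integrator
`deSolve::lsoda` with rtol 1e-8 and atol 1e-10, the analogue of a stiff
MATLAB-style solver for this system. The standard protocol is: equilibrate
at stimulus 0 from an arbitrary state (all variables at 0.5) until the
right-hand side has infinity norm below 1e-8 — `preEquilibrate()` runs
doubling time spans up to 144,000 min, which covers the longest plausible
reading of the equilibration horizon — then switch the stimulus on and
integrate over [0, 1440] min. Uniqueness of the basal fixed point is
checked by tests from distinct starting states; the slowest mode is the
cell-number equation (relaxation rate of order $\mu$), which bounds the
accuracy of the equilibrium at roughly 1e-5.

On GIV depletion versus uncoupling: the two variants share the identical
mGEF equation, and their mGAP equations differ only by the residual drive
$f_2(tGEF)f_3(tG^*)$ evaluated at the depleted tGEF level. Because Hill
functions are smooth, this residual is small but not exactly zero, so the
trajectories agree to the size of that residual (about 1e-3 here) rather
than to machine precision; equality is exact only in the limit of a fully
silenced drive.

## Stochastic simulation

Noise is modeled by independent Ornstein-Uhlenbeck channels
$\tau^{noise} d\eta = -\eta\,dt + \sigma\,dW$, each with zero mean and
stationary variance $\sigma^2/(2\tau^{noise})$. Three configurations are
supported (`noiseConfig()`): noise in the stimulus only
($\sigma_{sti} = 0.02$, $\tau^{noise} = 1$ min); additionally in every
species equation ($\sigma = 0.02$, reduced to $2\times10^{-5}$ for S and
$2\times10^{-6}$ for X so that noise does not overwhelm their small reaction
rates) with tGAP perturbed inside fact8's argument; or additionally in every
connection — each activation function and the nonlinear secretion,
endocytosis and proliferation rates ($\sigma = 0.02$; 0.002 for the
cell-number channel).

The OU channels are advanced by the update
$\eta_{n+1} = \eta_n - \eta_n\,dt + \sigma\,\delta W + \tfrac12\sigma^2(\delta W^2 - dt)$
(the `"as_printed"` scheme). The quadratic term is the Milstein correction
written for a multiplicative-noise equation; for additive OU noise the
mathematically standard scheme is plain Euler-Maruyama (the correction has
zero mean and vanishing effect on the stationary law), so both schemes are
implemented and their stationary statistics are asserted equal in the test
suite. The default keeps the correction for fidelity to the published
update rule. Species are advanced by the Euler scheme at a fixed step
dt = 0.01 min; species noise enters inside the tau-scaled bracket for the
five GTPase equations and directly in dS/dt and dX/dt, mirroring where the
published update rules place the terms. S and X are floored at zero if a
step overshoots (logged as a warning; at the default amplitudes this is
rare). No state clipping is applied otherwise — the normalized Hill
function absorbs out-of-range arguments.

Each ensemble replicate r uses seed `seed + r - 1`, making every replicate
independently reproducible; Wiener increments are drawn channel-by-channel
in a fixed documented order from R's RNG. Ensemble statistics (mean and SD
with the N-1 denominator) are evaluated at 1,440 min by default.

## Dose-response and DoRA quantification

`doseSweep()` equilibrates at stimulus 0 and measures terminal states at
1,440 min for each dose, deterministically or as a stochastic ensemble. The
default grid combines the seven printed doses {0, 0.00046, 0.0046, 0.046,
0.115, 0.23, 0.46} with 20 log-spaced points for fit stability.
`fitHill()` fits $a x^n/(x^n + K) + d$ by Levenberg-Marquardt least squares
from a grid of starts ($n \in \{0.5, 1, 2, 4\}$ crossed with K built from
the x quartiles), keeping the best residual and breaking ties toward the
smaller n; the offset d is retained only when it improves the residual sum
of squares by more than 1%. The mGEF to mG* pair uses an ordinary linear
fit instead — DoRA manifests as linearity of exactly this pair.
$R^2 = 1 - \sum(y_i-f_i)^2/\sum(y_i-\bar y)^2$ throughout (squared
deviations; this convention is consistent with negative values for poor
fits). Steady-state means are used on both axes of every pair.

## Fitting and sensitivity

`fitParameters()` fits selected parameters to fold-change datasets (mean
± SEM over time). The objective is the sum over datasets of the
normalized RMSE — RMSE divided by the mean of the data values — with
control and GIV-depleted datasets weighted equally, and the acceptance
thresholds are strict: below 0.2 for the mG* readout and below 0.45 for
tG*. Fold changes are normalized to each condition's own pre-stimulus
baseline, for both data generation and model predictions, keeping the two
sides of the comparison on one convention. The optimizer is Nelder-Mead on
log-transformed parameters restarted from a small Latin hypercube, with a
hard evaluation budget — a reproducible, seeded surrogate for manual
tuning with the same acceptance criterion. Which parameters are free is
always caller-specified; the workflow captures trends and does not claim
identifiability.

`logSensitivity()` implements the ±10% central difference for
$d\ln X/d\ln\alpha$. The literal printed recipe divides the difference of
$\ln X$ by $0.2\alpha$, which carries units of $1/\alpha$; dividing by 0.2
instead yields the dimensionless logarithmic gain that the definition
$d\ln X/d\ln\alpha$ denotes. The default therefore divides by 0.2, and an
`"as_printed"` scheme dividing by $0.2\alpha$ is provided; the two differ
exactly by the factor $\alpha$, which the test suite asserts.

## Network perturbation

`loadInteractions()` filters a STRING-style scored edge list at a
combined-score cutoff (667 in the published analysis), collapses duplicate
edges keeping the maximum score, and treats the surviving edges as
unweighted — geodesics are hop-count shortest paths, matching the
published procedure. `deleteNodeDiff()` removes a node in silico and, for
every anchor-partner seed pair, compares the complete geodesic sets before
and after. The *alteration fraction* is the size of the symmetric
difference of the two sets over the size of their union; the published
workflow filters to pairs with fraction exactly 1 (only deleted or newly
created paths), and because only those pairs drive the downstream ranking,
results are insensitive to the denominator convention at that filter. The
exact formula of the original alteration-fraction definition lives in an
external reference, so the union-denominator form used here is a documented
package choice. `rankEndProteins()` ranks partners of fraction-1 pairs by
the number of turned-over geodesics, ties broken alphabetically.

## Synthetic data

`syntheticTimecourses()` emulates the statistical shape of densitometry and
FRET fold-change measurements: the ground-truth model is simulated for
control and GIV-depleted conditions, sampled at experiment-like grids
(0/5/15/30 min for the pulldown-style mG* readout; 5-min steps to 30 min
for the FRET-style tG* readout), converted to fold change, and given
replicate noise. Replicates are Gaussian with standard deviation equal to
`noiseScale` (default 10%, a choice standing in for error bars reported
only graphically) times the true value, truncated at zero because ratio
readouts are positive; each replicate's baseline is pinned at 1, as each
experimental replicate is normalized to its own baseline, and datasets
report mean ± SEM over 3 replicates by default. What passing tests on
these data show is self-consistency of the pipeline under a realistic noise
magnitude — they cannot certify the noise model, sampling, or unmodeled
biology (spatial organization, receptor dynamics) of real measurements.

`generatePPIFixture()` plants a linker node on all geodesics between an
anchor and a known partner subset, with longer backup routes keeping the
graph connected after deletion, so network tests have an exactly known
answer.

## Problem sizes and numerical choices

The package's own test and acceptance workloads use ensembles of 100-200
runs (rather than 1,000) over reduced dose grids; zero-mean stimulus noise
makes ensemble means converge to the deterministic curves, so fitted Hill
exponents are stable well below 1,000 runs, which the convergence tests
verify at increasing ensemble sizes. Deterministic reference tolerances are
rtol 1e-8 / atol 1e-10; the fixed-step stochastic engine uses dt = 0.01
min; a fixed-step RK4 oracle at dt = 0.005 min cross-checks the adaptive
solver in the test suite.

## Known limitations

* No spatial or compartmental resolution: the model is well-mixed by
  construction.
* The normalized-Hill abstraction does not resolve GEF/GAP biochemistry;
  parameters are phenomenological.
* The bundled parameter table is a calibrated reconstruction, not the
  original supplementary values; quantities that depend on fine parameter
  detail (e.g. exact sensitivity magnitudes) should be read as
  representative, not as reproductions.
* Fold-change data carry no absolute scale, so fits constrain shapes, not
  absolute copy numbers.
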