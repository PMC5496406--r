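---
title: "Population PK-PD modelling of mitiglinide glucose lowering: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population PK-PD modelling of mitiglinide glucose lowering: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitipkpd)
```

# The model

Mitiglinide is a rapid-acting insulin secretagogue: after a single oral
dose it is absorbed within minutes, suppresses plasma glucose transiently,
and is cleared within a few hours. `mitipkpd` implements the population
PK-PD analysis of this system as a reusable workflow: structural model,
trial simulation, sequential FOCE estimation, non-compartmental analysis
and residual diagnostics.

## Structural pharmacokinetics

A two-compartment disposition model with first-order oral absorption and an
absorption lag time. States are the depot amount $A_a$, central amount
$A_1$ and peripheral amount $A_2$ (mg):

$$
\begin{aligned}
dA_a/dt &= -K_a A_a \\
dA_1/dt &= K_a A_a - CL \cdot C - CL_2\,(C - C_2) \\
dA_2/dt &= CL_2\,(C - C_2)
\end{aligned}
$$

with $C = A_1/V$ and $C_2 = A_2/V_2$. The whole dose sits in the depot
until the lag time $T_{lag}$; before the lag the plasma concentration is
exactly zero. Clearances are parameterized directly ($CL$, $CL_2$ in L/h)
rather than as micro rate constants.

Units are fixed package-wide: dose mg, volumes L, clearances L/h, time h,
drug concentration mg/L (numerically identical to µg/mL, so the fitted
IC50 is directly comparable to simulated concentrations), glucose mmol/L.

Because the system is linear, the central concentration has the standard
tri-exponential closed form built from the micro constants
$k_{10} = CL/V$, $k_{12} = CL_2/V$, $k_{21} = CL_2/V_2$. The package
carries **two independent evaluation routes** — the closed form
(`analytic_central_conc()`, also compiled for the estimation hot path) and
an adaptive stiff-capable ODE integrator (`deSolve::lsoda`, `rtol = 1e-8`,
`atol = 1e-10` by default) — and the test suite pins them together to a
relative $10^{-6}$ across two decades of parameter space. The closed form
degenerates when $K_a$ collides with a disposition eigenvalue; the exported
function then raises an error and callers fall back to the numeric route
(inside the estimation loops the collision is instead sidestepped by a
relative $10^{-9}$ nudge, far below estimation noise).

The lag is handled by time-shifting the solution (analytic route) or by
starting the integration at $T_{lag}$ (numeric route) — not by a transit
compartment — so the lag contract is exact and the integrator never sees
the discontinuity.

## Effect compartment and glucose response

Plasma concentration drives a hypothetical effect site (biophase) with
first-order equilibration,

$$ dC_e/dt = K_{e0}\,(C - C_e), $$

and glucose follows a sigmoid inhibitory Emax function of the effect-site
concentration:

$$ E = E_0 \left( 1 - \frac{C_e^{\gamma}}{IC_{50}^{\gamma} + C_e^{\gamma}} \right). $$

The biophase introduces the hysteresis between concentration and response;
$K_{e0}$ controls how fast the effect tracks plasma. Maximal inhibition is
complete suppression of the baseline $E_0$ — no separate Imax parameter is
introduced. The Hill ratio is computed on the log scale so large
$C_e^\gamma$ cannot overflow. The effect compartment is driven by the
central concentration and carries negligible mass (the standard biophase
assumption), so it does not enter the mass balance.

## Population model

Inter-individual variability is log-normal, $\theta_i = tv_\theta\,
e^{\eta_i}$, with $\eta_i \sim N(0, \omega^2_\theta)$, on
$K_a, V, T_{lag}, CL_2$ (PK) and $K_{e0}, \gamma, E_0$ (PD). $V_2$, $CL$
and $IC_{50}$ are population constants — the final random-effect set of the
reference analysis, after its shrinkage-based pruning (random effects with
shrinkage above 0.5 were excluded there; the package reports shrinkage and
flags that threshold but never prunes silently). Published CV percentages
are converted to variances by the exact log-normal relation
$\omega^2 = \ln(1 + CV^2)$, the inverse of which the sampler reproduces in
Monte-Carlo checks.

## Residual error

The source analysis does not report its residual model, so the package must
choose one. Decision: **proportional** error for drug concentration (the
profile spans three orders of magnitude and LC-MS/MS assays have
concentration-proportional precision) and **additive** error for glucose
(narrow physiological range). Defaults: 10% proportional SD, 0.15 mmol/L
additive SD; both are arguments of `reference_population()`. All recovery
tests simulate with the package's own generator, so this choice defines the
study conditions rather than biasing any comparison.

Numerical guards: predicted concentrations below $10^{-6}$ mg/L use a
variance floor $\sigma^2 (10^{-6})^2$ so pre-lag zeros cannot produce
singular densities; zero pre-dose drug observations are excluded from the
PK likelihood (standard practice); glucose values driven negative by noise
are truncated at zero and flagged, and flagged observations are excluded
from the likelihoods.

# The synthetic study

`default_design()` encodes the emulated trial: 18 fasted subjects, one
10 mg oral dose, both analytes sampled at 0, 0.08, 0.17, 0.25, 0.33, 0.5,
0.75, 1, 1.5, 2, 3 h (the protocol describes a single blood-draw schedule,
so glucose shares the drug times). `reference_population()` carries the
published typical values and CVs verbatim. `generate_study()` composes the
two with the simulator.

Seeding: a master integer seed expands into per-subject substreams
(`substream = (seed mod 10^6) * 2039 + subject index`), so enlarging the
cohort never perturbs earlier subjects and every dataset is byte-identical
under a fixed seed.

What the generator deliberately does **not** emulate: assay drift and
between-run effects, dropout, food effects, covariate structure
(weight, age), between-occasion variability, correlated random effects, and
whatever the true residual structure of the original assay was. Passing
recovery tests therefore demonstrate that the estimator inverts the
package's own generative model at the published parameters and design —
not that it would reproduce the original study's estimates from its raw
data, which were never deposited.

## A deliberate inconsistency in the reference set

The published population clearance ($CL$ = 0.03 L/h) is three orders of
magnitude below the same study's non-compartmental apparent clearance
(CL/F = 7.80 L/h) and implies a terminal half-life of thousands of hours,
versus the observed 1.69 h. The package stores the printed value verbatim
and treats the set as a self-consistent simulation truth; no correction is
guessed. Two consequences:

* Over a 3 h window, elimination is practically invisible, so $tv_{CL}$
  and $tv_{V_2}$ are **not identifiable** from the emulated design. They
  are estimated (the optimizer tolerates the flat directions) but excluded
  from recovery assertions.
* Demonstrations that want a realistic terminal phase can use
  `nca_consistent_population()`, a clearly-labelled synthetic variant with
  $CL$ set to the NCA value.

# Estimation

## FOCE

The marginal likelihood of each subject's data is approximated by a
Laplace-type expansion at the conditional mode of the random effects
("first-order conditional estimation"). Per subject:

1. the **inner problem** maximizes the joint log-density
   $\log p(y_i \mid \eta) + \log p(\eta)$ over $\eta$;
2. the curvature at the mode is approximated first-order (Gauss-Newton):
   $H = F^{\mathsf T} R^{-1} F + \Omega^{-1}$, where $F = \partial f /
   \partial \eta$ by central differences and the residual variance $R$ is
   evaluated at the mode — which, for the proportional PK error, is the
   "with interaction" form;
3. the contribution is $-2\,l(\hat\eta) + \log\det H - p \log 2\pi$.

The first-order Hessian is the conventional FOCE choice: it is cheap,
always positive semi-definite (plus the $\Omega^{-1}$ ridge), and on toy
problems with one random effect the objective lands within 1% of exact
numeric quadrature (a standing test). A ridge is added in the rare case the
Cholesky factorization still fails.

The inner optimizer is a compact Nelder-Mead in dimension ≤ 4, warm-started
from the previous outer iteration's mode, polished from zero, and — for the
PK stage — additionally started with the individual lag pulled just below
the subject's first positive observation time. The last start matters: with
a floored proportional error the individual likelihood is *flat* while the
subject's lag exceeds its first observation time, and a mode search
started on that plateau would never descend the cliff.

## Outer problem and sequential strategy

All parameters are positive and estimated on the log scale: typical values,
eta variances and the residual SDs (11 free parameters in the PK stage,
8 in the PD stage). The outer search is Nelder-Mead with up to 500
iterations per pass and up to 8 simplex restarts, preceded by a
naive-pooled least-squares refinement of the typical values (all etas at
zero — cheap, and it removes most of the distance from a badly perturbed
start). Convergence is declared when the simplex meets its relative
tolerance ($10^{-8}$) or a full restart improves the −2LL by less than the
pass tolerance — 0.05 absolute, or $10^{-4}$ of the objective magnitude on
large datasets, whichever is larger; either way a gain far below the 3.84
χ² unit of a single parameter, i.e. statistically meaningless. The scale-aware
component matters because the practically unidentifiable clearance
directions (see above) let the simplex crawl indefinitely in sub-0.05
steps without moving any identifiable estimate. Multi-start (±30% log-perturbations) is
available via `control = list(n_starts = ...)`, winner by lowest objective
with ties broken by start index.

The PK and PD stages run **sequentially**: PK first on the drug
concentrations, then PD on glucose with each subject's PK fixed at its
empirical Bayes values (the IPP variant). IPP requires no joint
re-integration in the PD stage and matches the two-stage narrative of the
analysis being reproduced; the PD stage refuses an unconverged PK fit
rather than propagating garbage.

Empirical Bayes estimates, per-parameter shrinkage
$1 - SD(\hat\eta)/\omega$ (flagged above the conventional 0.5) and the
improvement trace (non-increasing by construction) are returned with every
fit.

# Non-compartmental analysis

Conventions, stated because the source does not report its own:

* **Terminal window**: best adjusted $R^2$ over all contiguous terminal
  windows of ≥ 3 positive post-peak points, peak excluded; ties favour the
  longer window. The window length and $R^2$ are reported alongside
  $\lambda_z$.
* **Integration**: linear-up/log-down by default (plain linear
  selectable); the pre-dose zero anchors the AUC at the origin; a trailing
  zero segment is integrated linearly (and a zero final concentration
  leaves nothing to extrapolate, so AUC$_\infty$ = AUC$_{last}$).
* **Extrapolation**: AUC$_\infty$ = AUC$_{last}$ + $C_{last}/\lambda_z$;
  CL/F = dose/AUC$_\infty$; Vd/F = (CL/F)/$\lambda_z$. When $\lambda_z$ is
  not estimable (flat or rising tail, too few points) the extrapolated
  quantities are reported missing while $C_{max}$, $T_{max}$ and
  AUC$_{last}$ survive.
* **Below-limit values** are zero before the first quantifiable
  concentration and missing afterwards; $T_{max}$ ties resolve to the
  earliest time.
* Summaries report mean ± SD for every quantity except $T_{max}$, which is
  reported median (min–max), matching the usual reporting convention.

# Diagnostics

`population_predictions()` returns PRED (typical values, all etas zero) and
IPRED (empirical Bayes etas; individual PK in the PD stage).
`cwres()` implements the FOCE-linearized conditional weighted residuals:
expanding the subject model to first order around the empirical Bayes mode,

$$ E[y] \approx f(\hat\eta) - F\hat\eta, \qquad
   \mathrm{Cov}[y] \approx F \Omega F^{\mathsf T} + R(\hat\eta), $$

and $\mathrm{CWRES} = \mathrm{Cov}^{-1/2} (y - E[y])$ via a symmetric
eigendecomposition (eigenvalues clamped at $10^{-10}$ of the largest, with
a warning, if the linearized covariance degenerates). Under the generating
model these are approximately standard normal; the acceptance suite checks
mean, SD and the fraction inside (−2, 2) on 200 simulated subjects. Drug
and glucose residuals are diagnosed separately — they carry different error
models — and `diagnostic_tables()` emits the four canonical panels (CWRES
vs time, CWRES vs PRED, DV vs IPRED, DV vs PRED) with explicit units and
reference-line metadata.

# Problem sizes and numerical choices in the test suite

The suite simulates at the sizes the analysis questions need, chosen as
this package's own verification design: 200 virtual subjects for parameter
recovery and CWRES calibration, 10 000 samples for Monte-Carlo checks of
the CV transform (the sampling error of a CV near 90% at 1 000 subjects is
of the same order as the 3-point tolerance, so the larger size is the
statistically honest one), 100 random parameter sets for the
analytic-vs-numeric oracle, and single-subject toys for the quadrature
oracle. Every stochastic test fixes its seed; the acceptance script takes
its seed from the command line and derives all randomness from it.

# Known limitations

* Single oral dose only: no multiple dosing, infusions, or nonlinear
  elimination.
* Diagonal $\Omega$; no covariates, no between-occasion variability.
* Standard errors are not computed by default (a finite-difference Hessian
  of the outer objective is the intended route and is deliberately left
  off the hot path).
* $tv_{CL}$ and $tv_{V_2}$ are unidentifiable under the reference design,
  as discussed above.
* The FOCE objective inherits the usual caveats of linearized
  approximations at very sparse designs or very large eta variances; the
  quadrature oracle covers the design actually used, not every imaginable
  one.
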