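---
title: "Modelling B-cell lymphoma growth under combination therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling B-cell lymphoma growth under combination therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lymphodyn)
```

## The model

`lymphodyn` models the malignant B-cell population of a subcutaneous
DoHH2 lymphoma xenograft in SCID mice under three single-dose
interventions: an antisense oligonucleotide down-regulating BCL-2
(as-bcl-2), the anti-CD-20 antibody rituximab, and their combination.
Because the hosts lack an adaptive immune system, there is no
immune-mediated kill term; rituximab enters only through direct cell
kill.

With the population nondimensionalised by its initial value,
$N^* = N/N(0)$, and time by the birth rate, $t^* = t/T$ with
$T = 1/K_b$ the e-folding time of untreated growth, the dynamics are

$$\frac{dN^*}{dt^*} = N^* \;-\; K^*\,\bigl(1 + N^* + K''g\bigr)\,N^*.$$

The three pieces of the loss term are:

* the intrinsic death/birth ratio $K^*$ (written $K'$ when as-bcl-2 is
  present, since the oligonucleotide is assumed to act on apoptosis,
  not on birth);
* the crowding factor $1 + N^*$ — hypoxia and starvation accelerate
  death as the tumor grows, the role played by a carrying capacity in
  classical logistic models;
* the antibody kill term $K''g$, the kill rate expressed relative to
  the death rate, times a dose factor $g$ normalised to 1 at the
  reference dose of 5 µg rituximab per gram body mass. No functional
  form of $g(c)$ is assumed: only the reference point is defined, so
  `g` is a direct input rather than a computed function of dose.

A deliberate structural choice is that the kill term multiplies
$K^*$ — i.e. $K''$ is a kill/*death* ratio, not a kill/birth ratio.
This is what makes the total loss factor
$E = 1 + N^* + K''g$ multiply $K^*$ as a unit, and it is the only
reading under which the lifetime formula below reproduces the
reference lifetime table (e.g. $7/(0.11 \times 5.5) \approx 12$ days
for the antibody arm).

For constant parameters the equation is logistic,
$dN^*/dt^* = rN^* - AN^{*2}$ with $r = 1 - K^*(1 + K''g)$ and
$A = K^*$, and `logistic_solution()` evaluates the exact solution.
Piecewise-constant treatment schedules (`regime_schedule()`,
`simulate_regimes()`) are solved regime by regime with the population
carried continuously across each switch, which guarantees exact
continuity without event detection. An adaptive Runge–Kutta route
(`ode_solution()`, Dormand–Prince via deSolve, rtol 1e-8 / atol 1e-10)
exists alongside the closed form; the two agree to better than 1e-6
relative and cross-validate each other in the test suite. Populations
are clamped at zero if an integration step undershoots at tolerance
level. The nontrivial fixed point, $\max(0, 1/K^* - 1 - K''g)$, is the
crowding-limited plateau; a sufficiently strong kill term drives it to
zero (extinction). All internal computation is in nondimensional
$t^*$; conversion to days happens only at I/O boundaries through the
attached $T$.

## The four-step calibration

The calibration mirrors how the four-arm experiment is informative:
each step frees only the parameter its arm can identify.

1. **Control** (inactive oligonucleotide): free $(T, K^*)$, with
   $K'' = 0$ and $N^*(0) = 1$.
2. **as-bcl-2**: free $K'$ only, $T$ held from step 1.
3. **anti-CD-20**: free the product $K''g$ only, $T$ and $K^*$ held
   ($g = 1$ at the reference dose, so the product is $K''$ itself).
4. **Combination**: no free parameters — the trajectory is *predicted*
   from $(T, K', K''g)$. Agreement with the combination arm is the
   model's validation, and the step-4 "fit" records only the
   prediction loss.

$N^*(0)$ is always pinned to 1 and never estimated: normalisation by
the initial volume is exact by construction.

The original analysis fitted by visual inspection and argued a formal
least-squares would add little on five animals per arm. A reproducible
pipeline needs an objective criterion, so the package minimises
weighted least squares on **log**-transformed normalised volumes,
$\sum_i w_i(\log N^*_{\text{model}}(t_i) - \log N^*_{\text{data},i})^2$.
Log residuals weight early and late epochs of exponential-like growth
evenly; with raw residuals the largest volumes would dominate. When
every SEM is available the weights are $(N^*/\mathrm{sem})^2$, the
delta-method inverse variance of a log-scale residual; otherwise unit
weights are used.

The optimizer is a coarse deterministic grid over the stated bounds
($T \in [1, 30]$ days, rate ratios $\in [0, 10]$; 30 and 101–201 grid
points respectively) followed by local refinement (box-constrained
quasi-Newton for the two-parameter step, golden-section for
one-parameter steps). Grid ties break toward the lexicographically
smallest parameter vector, so identical data and configuration give
bit-identical results. On noiseless fixtures the recovery error is
~1e-5 relative, far inside the 1% round-trip tolerance the tests
assert.

Two fit windows are first-class configuration, because the single-dose
treatments concentrate their effect in the first week and the early
and full windows genuinely support different parameter sets
(`"early"` = days 0–7, `"full"` = all data; reference values
$K' = 0.15$ vs $0.09$ and $K''g = 3.5$ vs $2$). Day 0 is the first
measurement day (dosing occurred five days earlier); treatment is
modelled as active from day 0 with effective average parameters, since
the measured data live on the measurement clock.

For the combination prediction after the first week the data show a
regime change around day 7, and nothing in the single-agent arms says
which kill term persists after the antibody wanes. Both options are
therefore exposed: `predict_mode = "single"` keeps $(K', K''g)$
throughout, and `"two_phase"` runs the early-window parameter set to
`switch_day` (default 7) and continues from the carried-over
population with the full-window set. The shipped default is
`"single"`; the two-phase variant is an explicit modelling choice, not
a claim about drug pharmacokinetics.

## Cell lifetimes and synergy

The total loss factor $E = 1 + N^* + K''g$ yields a characteristic
cell lifetime $L = T/(K E)$ (inverse effective death rate, in days).
Along a growing trajectory $E$ is minimal at $t = 0$, so
$L(0) = T/(K(2 + K''g))$ is the *maximum* lifetime and the quantity
tabulated per arm; the isolated-cell lifetime $T/K^*$ (no crowding, no
antibody) completes the table.

Rounding follows the conventions of the reference presentation,
reconstructed from the printed values: per-arm lifetimes round half-up
to whole days, the isolated lifetime is floored
($7/0.11 = 63.6 \to 63$), lifetime ratios are computed from the
rounded integer lifetimes and reported to one decimal, and the synergy
product multiplies the two rounded single-agent ratios
($1.4 \times 2.7 = 3.78 \to 3.8$). Unrounded values are always carried
alongside; the rounded ones exist only to mirror the conventional
table. One cell resists every standard policy: the full-window
anti-CD-20 lifetime computes to $7/(0.11 \times 4) = 15.9$, which
rounds to 16, while the reference table prints 15. `lifetime_table()`
reports the computed 16 and flags the discrepancy against the
reference values (`dohh2_lifetimes()`) rather than forcing agreement.

The synergy comparison is the multiplicative-ratio heuristic: if the
combination acted as the independent product of the single agents, the
product of the control/single-agent lifetime ratios would equal the
control/combination ratio. The report carries both numbers and their
gap; no formal framework (Bliss, Loewe) is attempted.

## The synthetic cohort generator

No individual-animal measurements are deposited for the reference
experiments, so the package generates cohorts with the statistical
structure the calibration assumes — and the generator's defaults *are*
the documented study conditions: 4 arms × 5 animals, volumes followed
on the sparse grid {0, 5, 7, 11, 15, 19, 23} days (the experiments
report 4–5 points per animal over up to 23 days; the exact days are
not printed, so this plausible grid is a package choice and is
overridable), mean initial volumes 158/114/125/109 mm³ for
control/as-bcl-2/anti-CD-20/combination.

Per-animal initial volumes are lognormal around the arm mean with 15%
CV (a typical spread for xenograft take at first imaging; the
reference data show overlapping initial SEMs). Measurement noise is
multiplicative lognormal with 10% CV, independent across animals and
days: volumes are positive and segmentation error plausibly scales
with size; no error model is published. Between-animal variation in
growth rate is off by default, with an optional lognormal jitter on
$K^*$ for robustness studies. All randomness flows from one mandatory
integer seed, and the ambient RNG state is restored afterwards.

What the generator does *not* emulate: imaging and segmentation
structure (voxelisation, slice thickness), correlated within-animal
errors, dropout, and any real biological deviation from the model's
own dynamics. Passing the round-trip and noisy-recovery tests
therefore shows the pipeline is correct and stable under the assumed
noise, not that the model is true of real tumors.

The noiseless fixtures (`dohh2_fixture()`) are group-mean datasets
built exactly from the reference parameter sets; they are synthetic
stand-ins for the unpublished mean curves and are labelled as such.

## Problem sizes and numerical choices

The test suite and the acceptance script run on deliberately small
problems: fixtures of 7 measurement days per arm, 100 random parameter
sets for the oracle-equivalence check over $t^* \in [0, 5]$, and 50
replicate cohorts (5 animals/arm, 10% noise) for the noisy-recovery
check, which targets the *median* recovered $K^*$ within ±20% and $T$
within ±15% — bands chosen for 5-animal arms with 10% measurement
noise, where $T$ (curvature of early growth) is better identified than
$K^*$ (late-time self-limitation). Degenerate inputs are handled
explicitly: $K^* = 0$ has no finite steady state (signalled), $r = 0$
uses the algebraic limit of the logistic solution, model values are
floored at 1e-12 inside log-residuals, and underdetermined fits
(fewer points than free parameters plus one for step 1) refuse to run.

## Known limitations

* Five animals per arm cannot support per-animal or mixed-effects
  fitting; only group means are fitted, and no confidence intervals on
  the rate ratios are produced. Both restrictions are inherited from
  the data the design emulates.
* $g(c)$ is defined only at the reference dose; dose extrapolation
  needs an empirical form for $g$.
* Immune-effector coupling (T/NK cells) is out of scope — appropriate
  for SCID hosts, wrong for immunocompetent settings.
* The early/full window dichotomy is a coarse stand-in for actual drug
  pharmacokinetics; the day-7 switch is a modelling device, not a
  measured clearance time.
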