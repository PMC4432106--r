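---
title: "Simulating toxicokinetic studies and comparing exposure estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating toxicokinetic studies and comparing exposure estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package answers

Regulatory toxicology studies measure systemic drug exposure (toxicokinetics,
TK) in rodents using very sparse blood sampling, usually in satellite groups,
and summarise it with non-compartmental analysis (NCA) of pooled "composite"
profiles or of a handful of serial profiles. Safety thresholds such as the
NOAEL inherit whatever bias and imprecision those estimates carry. An
alternative is to treat all concentrations from all cohorts, dose groups and
sampling days as one dataset and estimate exposure from a population
(nonlinear mixed-effects, NLME) pharmacokinetic model.

`toxkinsim` quantifies the difference between the two approaches by
simulation: it generates complete virtual toxicology programmes under known
population PK models, runs both classes of estimator on each simulated
study, and scores bias and precision of the derived exposure measures
against the simulated truth, replicate after replicate.

## Structural models and population parameters

Three hypothetical small-molecule drugs span the disposition behaviours most
often met in practice. All are dosed orally once daily with first-order
absorption from a depot; bioavailability is fixed at 1 and no lag time is
modelled (the simplest assumptions closing the dose-to-concentration map).

* **One-compartment, linear elimination** (`ONE_CMT`): KA 13.46 h⁻¹ (BSV
  50%), V 49.4 ml/kg (16%), CL 2.72 ml/h/kg (20%).
* **One-compartment, Michaelis–Menten elimination** (`ONE_CMT_MM`): Vmax
  2.72 mg/h/kg (20%), Km 1 mg/ml (no BSV), same absorption and volume. The
  values put the 100 mg/kg/day dose firmly in the saturated regime — daily
  input at that dose exceeds the maximal daily elimination capacity
  (Vmax × 24 h ≈ 65 mg/kg), so concentrations keep accumulating over the
  study. This is the intended departure from dose proportionality at the
  top dose.
* **Two-compartment, linear elimination** (`TWO_CMT`): KA 0.55 h⁻¹ (50%),
  V 49.4 ml/kg (16%), CL 2.72 ml/h/kg (20%), K12 0.3 h⁻¹ (no BSV), K21
  0.053 h⁻¹ (2%). The slow peripheral return produces drug accumulation
  over roughly two weeks of daily dosing. The reference table prints the
  K21 row as the digit string `0.0532`, which can be read as 0.053 with 2%
  variability or 0.05 with 32%; we adopt the first reading (it parallels
  the `2.72 / 20` layout of the CL row) and expose both the value and its
  BSV as arguments of `default_pop_params()` so the other reading is one
  keystroke away.

Between-subject variability is log-normal with the log-scale SD equal to
CV/100 (the NONMEM convention; at these CV magnitudes the difference from
the `sqrt(log(1+CV^2))` convention is below 1%). Residual variability is
15% proportional. Parameters printed as "per animal" rates (CL in ml/h,
Vmax in mg/h) are interpreted per kg body weight, which is the only reading
that makes them dimensionally consistent with V in ml/kg and doses in
mg/kg; concentrations then come out in mg/ml, matching Km printed in mg/ml,
and the 10 µg/ml adverse-event threshold is 0.01 mg/ml.

## Study designs

`build_cohort_design()` encodes three chronic-toxicity protocols. Doses are
vehicle, 10, 30 and 100 mg/kg/day in every cohort; satellite groups have 3
animals per dose group throughout; sampling times within a day are 0.1,
0.4, 1, 1.5, 4, 8 and 24 h post dose.

| Cohort | Toxicity n | Serial (satellite) days | Composite (toxicity) days |
|---|---|---|---|
| 1 week | 4 | 1 | 1 |
| 1 month | 10 | 1, 28 | 1, 28 |
| 3 months | 12 | 1, 28, 91 | 28, 91 |

Calendar conventions: "1 month" is 28 days, week 4 is day 28, week 13 is
day 91, and "6 months" is 180 days (4320 h) — all multiples of the 24-h
dosing interval so that steady-state days align with doses. The protocol
table states composite sampling days only for the 3-month cohort; for the
two shorter cohorts we sample the toxicity group on the same days as the
satellite group. Composite sampling draws blood from 3 animals per time
point; `allocate_composite_samples()` assigns the 21 daily slots at random
under the constraint that per-animal counts differ by at most one (randomly
permuted dealing, redrawn if a time point would receive a duplicate
animal). For the 10- and 12-animal toxicity groups this reproduces the
protocol's "about two samples per animal"; for smaller groups the
equal-as-possible rule governs. An 8-animal composite group, used in the
sampling-scheme comparison, is available as a `toxicity_n = 8` override.

The vehicle group is simulated (its observations are exactly zero) but
excluded from estimation — it carries no information about the PK
parameters and no assay would report it above the quantification limit.

## The simulated dataset

`simulate_trial()` realises one replicate: every animal gets its own
parameters, every scheduled sample is generated with proportional error
(draws are truncated at zero, an event of probability ~1e-11 at σ = 0.15),
and records are kept in a long NONMEM-like layout (`ID, TIME, AMT, DV,
EVID, MDV, ...`, written and re-read losslessly by `write_tk_csv()` /
`read_tk_csv()`). True concentrations and the realised individual
parameters travel with the dataset for the evaluator's benefit, but
`estimator_view()` strips them, and everything downstream of it — NCA and
the NLME fit alike — sees observations only. A test asserts that corrupting
the truth columns cannot change a fit.

Observations below the lower limit of quantification are omitted, not
imputed (`apply_bql_filter()`). The reference analyses never state an LLOQ;
the default of 0.001 mg/ml (1 µg/ml) censors nothing at the simulated
exposures, but the code path is real and tested. Seeding is hierarchical: a
master seed identifies the study, `replicate_seed()` derives one seed per
replicate, and each replicate draws all its randomness from that single
stream, so studies are reproducible end to end and replicates are
independent of execution order.

## Exposure measures

Five measures are computed from noise-free predicted profiles
(`exposure_from_params()`): the 24-h AUC, 24-h Cmax and 24-h time above the
0.01 mg/ml threshold (TAT) on the evaluation day's dosing interval, and the
cumulative AUC and peak concentration over 180 days of continued daily
dosing. The 24-h window is anchored to the evaluation day's dose (the
definition leaves the anchor free; a dosing interval is the only choice
that makes steady-state AUC24 equal dose/clearance exactly). The evaluation
day of a study is its last serial sampling day.

For linear models the integrals are analytic per dose and superposed in a
numerically stable accumulation form; Cmax uses bounded scalar maximisation
after a coarse bracket; TAT locates threshold crossings by root-finding on
the closed-form curve. For the Michaelis–Menten model a Dormand–Prince
RK45 integration (relative tolerance 1e-8, absolute 1e-10 mg/ml) carries
the cumulative AUC and eliminated amount as extra states; mass balance at
every grid point is asserted in the tests. At the reference exposures the
printed 10 µg/ml threshold lies below every trough, so TAT saturates at
24 h; the threshold is an argument precisely so that non-degenerate
crossings can be exercised (and they are, in the tests).

True exposure for a dose group defaults to the mean of the individual
truths of its animals (`convention = "group_mean"`), the group-level target
both estimator classes aim at; population-typical truth is available as a
switch. With 20% clearance BSV the two differ by about 2% for AUC (Jensen's
inequality), which is visible as a small negative bias of the model arm
when judged against the group mean.

## Non-compartmental estimation

The NCA arms mirror standard practice. Composite analysis averages the
observed concentrations per scheduled time (arithmetic or geometric;
geometric means are taken over positive values only, with the contributing
count decremented — zeros would otherwise annihilate the summary), then
derives AUC by the linear-up/log-down trapezoidal rule, Cmax as the maximum
of the summarised profile (earliest time on ties) and TAT from the same
piecewise interpolant with crossings solved exactly on each segment. Serial
analysis computes the three measures per animal and then averages across
the cohort. A day-1 profile is anchored with a zero pre-dose point; on
steady-state days the profile's own 24-h trough doubles as the t = 0 point
(the profile is periodic there). NCA cannot extrapolate beyond the
observations, so the two 6-month measures have no NCA analogue.

## The FOCE-I estimator

`fit_population()` implements first-order conditional estimation with
interaction from scratch; it is a generic NLME estimator specialised to
these structural models, not a wrapper around any external tool, and its
acceptance is statistical (recovery, bias, precision), not agreement of
objective-function digits with any particular implementation.

Per subject, the **inner problem** maximises the joint density of the data
(proportional- or additive-error likelihood) and the Normal(0, Ω) prior
over the subject's random effects, by Levenberg–Marquardt with analytic
gradients and Gauss–Newton curvature assembled from the prediction
Jacobian (central differences in η). Because the marginal approximation
depends on the mode to first order, the mode is polished with Newton steps
accepted on gradient-norm decrease, past the point where the objective
value saturates in double precision. The per-subject contribution is the
Laplace form of the conditional approximation,
`g(η̂) + log det(H/2) − d·log 2π`, with `g` the joint −2 log-density and
`H` its Gauss–Newton curvature with the residual variance evaluated at the
conditional prediction (the "interaction"). This form is stationary in η̂
— mode error enters only at second order — and collapses to the exact
Gaussian marginal when the model is linear in η with additive error, which
the tests verify against closed-form Gaussian algebra.

The **outer problem** minimises the summed objective over log typical
values, log BSV standard deviations and the log residual SD with a bounded
quasi-Newton (`nlminb`), relative tolerance 1e-7 and an explicit
central-difference gradient (step 1e-3): the objective carries ~1e-6
numerical noise from the inner solves, so the optimiser's own much
smaller-step differencing cannot be trusted, and supplying the gradient is
what makes most "false convergence" stops disappear.

Three further robustness measures deal with the pathologies that an
occasional replicate exhibits. First, a subject can have two near-tied
conditional modes; a warm-started inner solve then flips between them as
the outer parameters move, which makes the objective jump. On the
decisive evaluations (final, polish, covariance) the inner problem is
therefore solved from both the warm start and from η = 0 and the lower
mode wins, turning the objective into a continuous minimum of smooth
sheets. Second, when the optimiser still stops without certifying
convergence, restarts alternate with a damped-Newton polish that applies
the convergence criterion directly (projected gradient norm below 1e-3 on
the log scale); and because an optimum can sit exactly on a mode-tie kink
— where every direction is uphill yet finite differences report a
gradient of order 0.1 — the polish falls back to direct OFV probing:
convergence is certified when no coordinate move of 1e-4 improves the
objective by more than 1e-7, which is the "no attainable OFV decrease"
criterion applied literally. Third, a BSV variance component occasionally
collapses to (effectively) zero; it then sits on the boundary of the
parameter space and its curvature is structurally degenerate, so the
covariance step reports it as collapsed with an undefined standard error
and tests positive-definiteness on the remaining parameters.
Random effects sit on exactly the parameters that carry BSV in the
simulation model (diagonal Ω), matching the no-misspecification premise.
Initial estimates default to the generating values times 1.5, reflecting
the premise that a drug's PK is roughly known before toxicology studies
begin. For the Michaelis–Menten model the outer search runs over (KA, V,
CLint = Vmax/Km, Km): at sub-saturating concentrations only the intrinsic
clearance is well determined, so the natural (Vmax, Km) axes form a curved
likelihood valley that stalls quasi-Newton steps; the transform is linear
on the log scale and estimates and covariances are mapped back.

The **covariance step** takes a central-difference Hessian (step 1e-3) of
the objective at the optimum — with the inner warm starts frozen so the
evaluation is deterministic — declares success if and only if all
eigenvalues are positive, and converts the inverse curvature to standard
errors by the delta method. Non-convergence is data in this package, never
an exception: fits return flags, and the study bookkeeping counts them the
way convergence-rate tables are reported.

Inside the estimator the Michaelis–Menten ODE is integrated on a fixed,
log-spaced step grid per dosing interval rather than with the adaptive
controller. Adaptive step acceptance makes the solution discontinuous in
the parameters at the size of the local tolerance, and the finite-difference
Jacobians amplify that into objective noise; a step sequence that depends
only on the time axis keeps the solution smooth in the parameters
(16 log-spaced steps per dosing interval reproduce the adaptive solution
to about 1e-5 relative — far below the stochastic error scales of
estimation). Simulation and exposure computation keep the
error-controlled adaptive integrator. The dose count is frozen within each
integration segment so that Runge–Kutta stages landing exactly on a dose
time cannot see the next dose early.

## The replicate study and its metrics

`run_study()` ties everything together: per replicate it simulates the
study, filters BQL records, runs the configured NCA arms on the composite
and serial data and the FOCE-I arm on the integrated dataset (all dose
groups, roles and sampling days jointly — the data-integration premise),
derives exposure, and scores each estimate against that replicate's truth.
Failed replicates are recorded, excluded from bias/precision summaries and
reported as rates, mirroring convergence-table bookkeeping. Bias is the
scaled relative mean error, `SMRE = mean((est − true)/true) × 100`;
precision is the replicate coefficient of variation,
`CV = sqrt(sum(((x − mean)/mean)^2))/N × 100`. Note the `1/N` outside the
root: this statistic shrinks like `1/sqrt(N)` as replicates accumulate
(duplicating the sample divides it by √2, a property the tests assert), so
it measures the precision of the replicate study as a whole; the
conventional sample CV is available via `cv_formula = "sample"`, and the
active convention is recorded in every output table. Relative-error
quantiles (5/25/50/75/95) support box-plot style summaries
(`autoplot()`).

Truth is defined per dose group: by default every arm is scored against
the mean individual truth of all animals in the dose group (the shared
estimand when the question is "which estimator class is better"). A
`truth_scope = "sampled_group"` switch instead scores each NCA arm
against the truth of the animals that scheme actually sampled, which
decomposes an arm's bias into scheme-induced and animal-sampling parts;
the replicate CV is a function of the estimates alone and is unaffected
by either choice.

## Problem sizes and what the tests show

The package's reference experiments are desk-scale versions of a 200-
replicate study: the bundled tests and the acceptance script use 50
replicates of the 3-month, one-compartment, 30 mg/kg scenario for the
headline bias/precision/convergence checks (Monte-Carlo error of an SMRE
estimate at 50 replicates is a few tenths of a percent, far inside the
10-percentage-point bounds being checked), and 50-replicate, 1-week
scenarios (with a slimmed composite arm) for the cross-model comparison.
The model-bias ranking across structural models is evaluated on the
predicted 6-month cumulative AUC: within-study measures are interpolations
of observed data and show little model dependence regardless of the
structural model, whereas long-horizon extrapolation is exactly where
mis-estimated nonlinear disposition (the Vmax/Km valley) must surface.
This ranking has a scale limitation worth stating plainly: from a 1-week
(day-1 only) protocol the two-compartment drug's deep peripheral
compartment is essentially unidentified, so its 6-month extrapolation is
erratic for reasons that have nothing to do with nonlinearity — at this
problem size the Michaelis–Menten scenario demonstrably out-biases the
one-compartment scenario, but not the two-compartment one, whose
long-horizon error is design-limited rather than model-limited. The
protocols long enough to identify the two-compartment model (1–3 months)
put 50 Michaelis–Menten population fits outside a desk-scale compute
budget, so the corresponding comparison is reported as a known limitation
rather than silently rescoped. The sampling-scheme comparison pits an
8-animal composite group sampled about twice per animal (two animals per
time point) against 3-animal serial profiles — the composition the
scheme-effect statement itself describes. The composition matters: with
three animals per time point a composite group of eight or more animals
is never less precise than three serial animals (the serial estimate
carries the full within-animal covariance of the profile, the composite
estimate only its diagonal), and simulation confirms the effect's sign
reverses there.

The generator emulates the designed experiment faithfully — hierarchical
variability, sparse scheduled sampling, random composite allocation,
quantification limits — but real TK data also contain features it omits by
construction: absorption lag and variability in bioavailability,
inter-occasion variability, dose-time and sampling-time deviations,
assay-dependent error structure, and model misspecification (the fitted
structural model is always the generating one here, the
no-misspecification premise). Passing tests therefore demonstrate the
relative behaviour of the estimator classes under an idealised but
realistic design, not the absolute performance to expect from any given
real study.

## Known limitations

* No covariates, no inter-occasion variability, no absorption models
  beyond first-order, no PBPK structures.
* Ω is diagonal; correlated random effects are out of scope.
* BQL data are omitted, not modelled (no M3-style likelihood).
* The FOCE-I implementation targets these structural models; it is not a
  general-purpose NLME engine.
* Convergence criteria and covariance conventions are this package's
  documented choices; other implementations' flags are not reproduced
  digit for digit.
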