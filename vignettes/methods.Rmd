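---
title: "Models and methods behind anaerobead"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind anaerobead}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(anaerobead)
```

`anaerobead` simulates anaerobic treatment of high-strength organic
wastewater by communities encapsulated in spherical hydrogel (PEG) beads,
and evaluates the sustainability of candidate designs: percent COD removal
(rCOD), the levelized cost of COD removal (LC, USD per tonne removed) and
the GWP100 carbon intensity (CI, kg CO2eq per tonne removed). This vignette
records the models, the numerical choices, and the boundaries of what the
package's tests demonstrate.

## Biokinetic core

The liquid-phase biochemistry is the standard Anaerobic Digestion Model
No. 1 (ADM1): 24 dynamic components (9 soluble COD species, inorganic
carbon and nitrogen, soluble inerts, 12 particulates including seven
microbial guilds) plus a strong cation/anion pair, connected by 19
processes — first-order disintegration and hydrolysis, eight Monod uptakes
with pH, hydrogen, ammonia and nitrogen-limitation inhibition, and
first-order biomass decay. We use the published benchmark parameterization
(mesophilic reference values; `adm1_params()`), with two temperature
corrections: an exponential factor `exp(theta (T - 35))` (default
`theta = 0.069` per degree, roughly a doubling per 10 degC) on all
biological rate constants, and van't Hoff corrections on the acid-base and
Henry constants. Both ambient (22 degC) and mesophilic (35 degC) operation
use the same parameter set.

Two deliberate closures keep carbon and nitrogen exact: the stoichiometric
coefficients of inorganic carbon and nitrogen are computed as the negative
elemental content of every other coefficient in each process column, so the
matrix conserves COD, C and N to machine precision (asserted in the tests).

pH is solved algebraically at every right-hand-side evaluation from the
charge balance over VFA anions, bicarbonate, ammonium, water and the strong
ion pair, with a safeguarded Newton iteration on the proton concentration.
The balance is strictly monotone, so the root is unique; the iteration is
converged to a relative proton step below 1e-13.

A numerical guard worth recording: biomass concentrations below 1e-9
kg-COD m^-3 (far below one cell per litre) are treated as absent when
computing reaction rates. Without this extinction threshold, integrator
roundoff at the 1e-22 level can "germinate" in a sterile reactor, because
the washout state is an unstable fixed point of the growth equations.

## Bead diffusion-reaction model

Each bead is a sphere discretized into concentric shells of equal
thickness (`bead_spec(shell_count)`, default 30 for the standalone bead
solver; system simulations default to 10 shells, see below). Soluble
components diffuse between shells with a conservative finite-volume scheme;
the effective diffusivity is the aqueous diffusivity times a single
bead-to-water diffusivity ratio applied to all solutes. The center boundary
is zero-flux; at the surface the bulk concentration is clamped (no external
film — only the internal ratio is exposed as a parameter). Particulates,
including the encapsulated biomass, do not diffuse. Every shell runs the
full ADM1 reaction network at its own charge-balance pH.

The numerical solver is verified against the closed-form effectiveness
factor for first-order uptake in a sphere,
`eta = (3/phi^2)(phi coth(phi) - 1)`: at 50 shells the computed surface
flux matches the analytic value within 1% across Thiele moduli from 0.1 to
10, and refining 25 -> 50 -> 100 shells contracts the error with
second-order-like behavior.

**Encapsulation capacity.** The maximum encapsulation density caps the
total biomass a shell can hold. In the ODE system the cap acts as a smooth
crowding law: the fraction of gross growth exported ("sloughed") to the
bulk is `(X_total / capacity)^12`. Shells therefore equilibrate slightly
below the cap (within about 0.5% when growth strongly outpaces decay), the
right-hand side stays smooth for the stiff integrator, and all COD books
stay closed because the overflow becomes suspended biomass that leaves with
the effluent. The discrete operation `apply_capacity_cap()` implements the
exact clip-and-slough bookkeeping for state post-processing. Slough-to-bulk
was chosen over growth arrest so that excess production is not silently
destroyed; this choice is sensitivity-worthy. Inert particulate residue
generated inside shells by disintegration is exported with the slough
stream as well — retained, it would accumulate without bound and no steady
state would exist.

## Flowsheets and steady state

A scenario (`system_config()`) is one or two bulk CSTRs. Encapsulated
reactors (fluidized bed at a bead volume fraction; packed bed at
`1 - voidage` bead fraction) exchange with the bead population through the
surface flux times the specific interfacial area `6 phi / d`. The UASB
benchmark instead retains suspended biomass with a three-phase-separator
retention factor, `SRT = HRT x retention_factor` (default 15; at 1 it
degenerates to a plain chemostat whose washout boundary matches the
closed-form criterion in the tests). HRT is defined on the working volume
including beads, which makes the organic loading rate `COD_in / HRT`
consistent with the loading range spanned by the uncertainty analysis
(1.35-40.6 kg-COD m^-3 d^-1 for 6.76 kg m^-3 COD between 4 h and 5 d).

Each stage has a fixed headspace (15% of working volume) with dynamic H2,
CH4 and CO2 inventories, two-film gas-liquid transfer (`kLa` default
200/d), and a soft valve that holds total pressure at its setpoint
(atmospheric, or the vacuum pressure when first-stage vacuum extraction is
selected). Sidestream membrane H2 extraction removes
`e_mem x recirculation_ratio x Q x S_h2` from the first stage. Two-stage
systems seed stage 1 fermenter-rich and stage 2 methanogen-rich; since the
coupling is strictly downstream, the stages are solved sequentially, which
roughly quarters the cost.

**Convergence.** The stiff system is integrated with `deSolve::lsoda` in
growing chunks (with a BDF fallback when the primary integrator stalls)
until the scaled derivative norm `max |dC/dt| / (|C| + 1e-6)` over the
*reported observables* — every soluble bulk component, the ion pair, the
three gas states, and the bulk particulates as one COD aggregate — falls
below `tol` (default 1e-4 per day). The norm is deliberately not taken over
the bead interior: capped shells host near-neutral community-succession
modes with multi-year time constants (eigenvalues around -6e-4 per day)
that never damp on a practical horizon yet leave every reported stream
stationary to within hundredths of a percentage point of rCOD. UASB
systems, which have no such interior, are additionally polished with a
damped, equilibrated Newton iteration and typically reach residuals below
1e-7. Results that do not meet the criterion are flagged unconverged, never
silently reported. Steady-state COD closure (influent = effluent + gas COD)
is computed for every run and asserted below 0.5% across a reduced
enumeration in the acceptance suite.

## Design, costing, TEA and LCA

Converged scenarios feed parameterized sizing: cylindrical concrete vessels
with rockwool insulation and carbon-steel facing (UASB adds a stainless
separator), encapsulant inventory `working volume x bead fraction x
density` with `ceiling(project / lifetime)` batches over the 30-year
project, Wen-Yu minimum fluidization velocity for fluidized-bed pumping,
the Ergun equation for packed-bed pressure drop, and an
effectiveness-corrected influent heating duty for mesophilic operation.

All cost coefficients live in `inst/extdata/cost_curves.csv` and all GWP100
characterization factors in `inst/extdata/impact_factors.csv`. Both are
editable tables of documented *synthetic placeholders*: vendor-grade cost
algorithms and licensed life-cycle inventory databases (e.g. ecoinvent) are
not redistributable, so absolute LC and CI levels here are illustrative
while scalings, rankings and breakdowns are structurally faithful. Two
entries are anchored to literature equivalences rather than invented: the
grid electricity factor (0.4405 kg CO2eq/kWh) reproduces the
0.79 kWh/kg-COD <-> 348 kg CO2eq/tonne conversion for conventional
activated-sludge treatment, and the avoided-natural-gas credit (0.015 kg
CO2eq/MJ, a supply-chain credit rather than full combustion displacement)
puts the biogas credit in the expected band of roughly -150 to -205 kg
CO2eq per tonne removed for these systems.

LC is the negative annualized net present value per tonne of COD removed:
all outflows (capital at year 0, O&M, scheduled bead replacement batches)
minus the biogas revenue are discounted at 5% per year over 30 years,
annualized with the capital recovery factor (0.06505), and divided by the
annual removal. The LC and CI contribution breakdowns are exact
decompositions: their group shares sum to the net indicator to 1e-9
relative, which the tests assert for every evaluated scenario. Effluent
degassing acts downstream of the reactor train, so both degassing variants
of LC and CI are computed from a single steady-state simulation.

## Three analysis stages

*Stage I.* `enumerate_scenarios()` forms the deterministic cross product of
the 11 decision option sets under structural applicability (bead decisions
only for encapsulated reactors, volume fraction only for fluidized beds,
active H2 extraction — two vacuum pressures or two membrane recirculation
ratios — only on the first stage of two-stage systems; single-stage systems
collect biogas passively). The default sets yield 3552 scenarios, 96 of
them UASB, verified against an independent counting formula. Pairwise
relative impacts divide the indicator difference of scenario pairs that
differ in exactly one decision by the indicator's global range, so
`|deltaY| <= 1` and the measure is antisymmetric under swapping baseline
and alternative.

*Stage II.* `lhs_sample()` draws a Latin hypercube (via `lhs::randomLHS`
under a fixed seed; one sample per equal-probability stratum per parameter,
asserted exactly) from the 18-parameter uncertainty space of each reactor
type (`make_parameter_space()`): the key decision variables (uniform —
full control within a feasible range), six sensitive ADM1 constants
(k_dis, k_hyd_ch, k_m_ac, K_S_ac, k_m_pro, k_m_h2) and configuration-
specific technology parameters. The exact literature distribution table is
not redistributable; the defaults are documented, editable stand-ins, and a
shared union matrix supports paired fluidized-vs-packed comparisons on
identical draws. Monte Carlo filtering splits samples at the 25th/75th
indicator percentile and runs two-sample Kolmogorov-Smirnov tests per
parameter (`stats::ks.test`, asymptotic p-values, verified against a
brute-force ECDF scan). p-values are reported uncorrected across the
parameter-by-indicator grid, as per-test significance; treat multiplicity
accordingly.

*Stage III.* `stage3_map()` sweeps a two-dimensional grid of technology
parameters (default 12 x 15 = 180 points) and, at each point, minimizes CI
over the bounded decision variables (HRT between 1 h and 5 d; fluidized
bead volume fraction between 0.03 and 0.25; 1 mm beads; packed voidage
0.45) with a seeded multi-start L-BFGS-B on the unit-scaled box (default 8
starts, warm-started along the grid). The optimizer tracks the best
objective over all evaluations and flags nonconvergent points rather than
dropping them. Its sanity bound — the minimized CI beats 20 random feasible
decision draws at every point of a reduced map — is part of the acceptance
suite, and the analytic-test-function checks confirm it recovers interior
minimizers within 1% of the bound range.

## What the synthetic data do and do not show

The generator reproduces the case-study conditions: a 50 m^3/d brewery stream at
6760 mg/L total and 5640 mg/L soluble COD, fractionated by configurable
weights (defaults: carbohydrate-rich soluble pool, all particulate COD as
composite; the split is not published, so it is a config input), with
inorganic carbon, nitrogen and alkalinity chosen so the default reactor
buffers near neutral pH. Accelerated toys (`make_toy_system()`) exist
purely for testing: the "tiny" acetate chemostat has a closed-form washout
boundary (its feed is over-buffered and ammonia inhibition is disabled so
the boundary stays clean), and the "small" encapsulated toy converges in
seconds. Passing tests demonstrate internal consistency — conservation,
closed forms, stratification, calibration of the statistics — on these
synthetic conditions. They do not validate the biokinetics against
experiments, do not reproduce the original study's absolute cost or impact
levels (placeholder tables), and say nothing about influent variability,
sulfur or precipitation chemistry, or bead degradation dynamics (lifetime
acts only through the replacement schedule).

## Problem sizes and tolerances used by the checks

The package's own choices for the routine verification runs: system
simulations in the test-suite use 3-4 radial shells and a steady-state
tolerance of 2e-4 to 3e-4 per day; the reduced stage-I enumeration covers
48 scenarios; the paired fluidized/packed comparison uses 50 shared draws;
the reduced stage-III map is 3 x 3 with 20 random draws per point; the
Monte Carlo null calibration uses 100 replicates of N = 1000. The
full-scale settings (10+ shells, 1e-4 tolerance, N = 1000, 180-point maps,
8 optimizer starts) are one-command reproducible through the same
functions.

## Known limitations

- Absolute LC and CI depend on placeholder cost and factor tables and
  should be read comparatively, not as dollar or kilogram predictions.
- The ADM1 parameterization is the published benchmark set, uncalibrated
  to any encapsulated-biomass experiment.
- The UASB separator model (a single retention factor) is a placeholder
  for unavailable hydrodynamic detail.
- Steady state is the only operating mode; dynamic influent and control
  are out of scope.
- The bead interior's community composition equilibrates on multi-year
  horizons; reported results are insensitive to this drift (see
  Convergence), but interior state snapshots should not be
  over-interpreted.
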