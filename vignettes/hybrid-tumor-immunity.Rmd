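---
title: "A hybrid agent-based / delay-equation model of protective anti-tumor CTL immunity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid agent-based / delay-equation model of protective anti-tumor CTL immunity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorCTL)
```

## The question and the model

Can a pool of vaccine-primed memory cytotoxic T lymphocytes (CTLs) eliminate
an incipient solid tumor before it is clinically detectable? `tumorCTL`
simulates this scenario with two coupled compartments operating on a shared
one-minute time step:

* **Tumor site** — a probabilistic, off-lattice, 3-D agent-based model
  (ABM). Every cell is a sphere of radius `rCell` (5 µm); no two cells may
  overlap. Tumor cells are immotile and divide with per-step probability
  `1 - exp(-dt/dTum)`, placing a daughter tangent to the parent in a
  uniformly sampled unoccupied direction (division fails when the cell is
  caged or at the domain boundary). CTLs perform a 3-D Wiener walk
  (per-coordinate displacement `N(0, sigma^2 dt)`), stop at first contact,
  engage adjacent tumor cells, and while engaged independently recruit new
  CTLs (mean time `dRecr`) and kill their target (mean time `dKill`); all
  CTLs die with mean lifespan `dLife`. The simulated region is a sphere of
  radius `rRoi`; CTL exchange with the rest of the body is represented by
  an immigration annulus (the "CTL cloud") that is repopulated each step
  with a Poisson number of CTLs proportional to the peripheral effector
  concentration, followed by removal of every CTL outside the region after
  the motion phase — a probabilistic analog of a constant-concentration
  boundary condition.
* **Draining lymph node** — a deterministic five-population difference
  system (immature APCs in tissue, mature antigen-bearing APCs in the
  node, memory CTLs, effector CTLs in the node, effector CTLs in the
  periphery). Antigen uptake is proportional to the instantaneous tumor
  burden; activated memory CTLs complete a fixed division program of
  `nDiv` divisions (duration `tauProg = 1 + (nDiv-1) tauDiv` days: the
  first division takes a day) and re-enter as `2^nDiv` effectors;
  restimulated effectors return doubled after `tauDiv`. The delayed terms
  make this a delay system; a method-of-steps solution of the continuous
  counterpart (`ddeSolveReference()`, built on `deSolve::dede`) serves as
  a validation oracle for the per-step production stepper.

The compartments exchange synchronously: each step the lymph node consumes
the pre-step tumor count and the ABM consumes the pre-step peripheral
effector concentration.

## Parameters

All parameters live in a single validated S4 object
(`simParams()` / `baseParams()`); derived quantities are computed, not
stored by hand:

| parameter | base | units | meaning |
|---|---|---|---|
| `dt` | 1 | min | shared time step (the fastest dynamic is CTL motion) |
| `rCell` | 5 | µm | cell radius (cell diameters cluster near 10 µm) |
| `dTum` | 7 (1–400) | d | mean tumor division time |
| `sigmaMax` | 10 | µm min^-1/2 | maximal CTL diffusion scale |
| `tAccel` | 5 (0–24) | h | time to re-accelerate after stopping |
| `dLife` | 41 | h | mean CTL lifespan |
| `dRecr` | 8 (2–24) | h | mean recruitment time of an engaged CTL |
| `dKill` | 24 (4–48) | h | mean killing time of an engaged CTL |
| `rRoi` | 500 | µm | radius of the simulated tissue sphere |
| `pCross` | 0.001 | — | target one-step annulus-crossing probability |
| `rVol` | 1000 | — | tissue : lymph-node volume ratio |
| `nDiv` | 10 (7–17) | — | divisions in the memory activation program |
| `tauDiv` | 1/3 (1/6–1) | d | duration of one division |
| `mFrac` | 0.02 (0.01–0.10) | — | memory pool as a fraction of node CTLs |
| `antigenicity` | 1e-7 (1e-8–1e-5) | d^-1 cell^-1 | APC uptake rate per tumor cell |

Quantities derived in code: the APC supply rate `sA = deltaA * a0` (so the
resting tissue is at equilibrium), the program duration `tauProg`, the
equilibrium memory concentration `mEq = mFrac * cCtl`, and the annulus
width `wCloud = qnorm(1 - pCross) * sigmaMax * sqrt(dt)` (≈ 30.9 µm), at
which the one-step crossing probability is exactly `pCross`.

Node concentrations come from the published slice counts (1600 CTLs and
100 dendritic cells in a 1/500 slice of a 1-mm-radius node):
`cCtl ≈ 191`, `cDc ≈ 11.9` in units of 10³ cells/mm³. The tissue APC
*count* is taken to match the node APC count, so the tissue concentration
is `a0 = cDc / rVol`; with `a0 = cDc` instead, the node responds to a
single tumor cell, which contradicts the intended regime in which the
response ignites only once the tumor reaches a few hundred cells. The
mass-action stimulation coefficient is assembled from a pairwise APC–CTL
interaction rate of 2.4/day, a successful-stimulation probability of 0.5,
and the slice-volume unit conversion, giving `b ≈ 10` (10³ cells/mm³)⁻¹
d⁻¹ with a sweep range of 1–10. Several magnitudes in this table
(`rCell`, `sigmaMax`, `rRoi`, `a0`, `b`, `antigenicity`) are estimates
assembled from the cited experimental literature rather than direct
measurements; they are deliberately exposed as plain configuration so that
sweeps can interrogate them, and the package's quantitative claims are
formulated as bounds that are robust to them.

## Numerical choices

* **Per-step probabilities.** All Bernoulli event probabilities use the
  exponential-hazard form `1 - exp(-dt/tau)`, which stays in [0, 1) for
  any step and differs from `dt/tau` by < 0.1% at the base step.
* **Difference-system factors.** Transitions compose as survival first,
  then stimulation, e.g. the immature-APC pool retains
  `exp(-deltaA dt) * exp(-a T dt)` and the matured fraction enters the
  node scaled by `rVol`. The constant APC supply is integrated exactly
  against decay (`(sA/deltaA)(1 - exp(-deltaA dt))`), making the
  unstimulated steady state an exact fixed point of the step map — the
  tests hold it for 10⁴ steps to 10⁻¹². Effector branch order is: survive,
  then (if stimulated) divide, else egress; cohorts in division are not
  subject to additional death during their delay, mirroring the
  undiscounted delayed re-entry of the continuous system. All
  concentrations are nonnegative by construction (fuzzed over 1,000
  random parameter sets in the tests).
* **Collision handling.** A moving CTL performs an exact first-contact
  solve of its displacement segment against every candidate neighbor from
  a uniform spatial grid (cell edge ≥ one cell diameter, dimensions capped
  at 256³), stopping at the earliest contact. Tangent placements
  (division, recruitment) rejection-sample uniform directions with a cap
  of 50 attempts, after which the event fails — reproducing the
  no-space-to-divide behavior without computing free solid angles.
  Contact tolerance is `1e-3 * rCell`, inclusive; near-exact ties in
  engagement break toward the lowest agent id.
* **Phase order.** Within a step: cloud spawn, CTL death, recruitment and
  killing, tumor division, motion (agents visited in a fresh random
  permutation), engagement update, boundary cull. Only spawn-first and
  cull-last are dictated by the boundary construction; the interior order
  is a convention.
* **RNG.** One stream per simulation, drawn from R's generator, so
  `set.seed()` makes every run bit-reproducible; replicate `i` of a batch
  uses `seed0 + i - 1`.
* **Delay bookkeeping.** Ring buffers store the raw histories of the
  memory, mature-APC and effector concentrations (length
  `max(Kprog, Kdiv) + 1` steps) rather than precomposed products, and
  pre-time-zero slots hold the vaccinated steady state.
* **DDE oracle.** `deSolve::dede` with tolerances 10⁻¹⁰, `hmax` bounded by
  half the smallest delay, and an enlarged history buffer. On a
  representative base trajectory (exponential growth at rate `1/dTum`
  from one cell, elimination at day 45, 50-day horizon) the per-step
  system and the continuous solution agree to a few times 10⁻⁴ in
  normwise sup relative error — and to < 10⁻³ with the burden held at 10⁴
  cells for 30 days.

## The surface-kill ODE

During decline, the tumor burden in the ABM falls like a *cubic* in time,
not an exponential: killing is limited to the spherical tumor's surface.
The companion deterministic model makes this mechanism explicit. With
`T` cells treated as an equal-volume sphere, the surface holds at most
`Emax = 4 T^(2/3)` CTLs (surface area over a CTL cross-section), and

* `dT/dt = kappaG * 4 T^(2/3) / dTum - min(Es, Emax) / dKill`
* `dEs/dt = kappaIn * (Etiss * 10^3 * Vshell) * (1 - Es/Emax)
  - deltaE * Es + (Es/dRecr) * (1 - Es/Emax)`

where `Vshell` is a contact shell of thickness `2 rCell` around the tumor
surface and `kappaG`, `kappaIn` are explicit calibration constants
(default 1) standing in for coefficients that could not be fixed from
independent data. Once `Es` saturates at `Emax`,
`d(T^{1/3})/dt` is constant and the burden reaches exactly zero at a
finite time; the integrator locates the crossing inside the step and
clamps the tumor-free state as absorbing. The coupled run (RK4 on the
site, the same difference system for the node) reproduces the
rise-then-fall shape with a final decline whose cube root is linear with
|r| > 0.99.

The density-dependent recruitment term `(Es/dRecr)(1 - Es/Emax)` is
self-amplifying: any positive seed population grows toward capacity even
under negligible peripheral supply. This is a known idealization of the
continuous model — in the ABM, recruitment requires physically engaged
CTLs — so no-response limiting cases should be probed with
`antigenicity = 0` (no antigen ever reaches the node) rather than a
vanishing memory pool.

## Outcome analysis

`summarizeRun()` reports time to extinction (first zero burden, tracked at
full step resolution), the peak burden and its time, an immune-failure
flag (elimination must occur below 10,000 cells and within two years), and
a relapse count. Relapse is formalized as a completed drop-and-recover
cycle on a 1-day moving-median smoothing: the burden falls below 50% of
its running peak and later rises back above that level; peaks under 10
cells are ignored. The thresholds are arguments, since the underlying
notion ("the population peaks and declines") is visual. A final decline
that ends in extinction is not a relapse.

`runSweep()` varies one parameter at a time over a grid, holding the rest
at base, with seeded replicates per value, and reports Spearman rank
correlations (average ranks; exact permutation p-values for n ≤ 9, the t
approximation otherwise) of the parameter against extinction time and
against log10 peak burden. Runs that reach the horizon enter at the
censoring time (conservative; exclusion is available via `censorMode`).

## What the tests do and do not show

The acceptance suite exercises the study design at reduced scale: 2–3
replicates per condition instead of 5, grids of 3–8 values inside the
documented ranges (the division-time sweep uses a log-spaced grid of
1–120 days, since a range-restricted grid mechanically attenuates rank
correlations), and horizons of 250–1,000 days. Under these conditions:
a 3% memory pool holds the mean peak burden under 1,000 cells and a 1%
pool under 30,000; every run across the antigenicity range 10⁻⁸–10⁻⁵ is
eliminated within 300 days; a tumor dividing daily is eliminated in under
100 days; extinction stays under 200 days across `nDiv` 7–17; the division
time correlates with extinction time at rho ≈ +0.9 while antigenicity
correlates negatively with both endpoints. With recruitment slowed to 24 h
the dynamics become oscillatory — burden crashes followed by regrowth —
while the peak stays below 5,700 cells. Because each oscillation carries a
real chance of finishing the tumor, a *typical* stochastic run survives
only one or two cycles; many-relapse trajectories are the long-surviving
tail, so the suite asserts the regime (at least one of ten fixed
replicates shows ≥ 2 completed relapse cycles) rather than a per-run
relapse count.

What passing does **not** show: the generator emulates a single avascular
microtumor in homogeneous tissue with immortal geometry-free stroma — no
mutation or antigen loss, no immunosuppression, no angiogenesis or
metastasis, no explicit chemokine gradients (recruitment teleports new
CTLs next to the recruiter, as in the cited cellular-automata ancestry),
and no stochasticity in the lymph node. Absolute times and burdens inherit
the uncertainty of the estimated constants above; the robust content of
the simulation is the bounds and orderings listed in the previous
paragraph, not exact trajectories — which is also why printed single-run
figures (a specific cell count on day 14, extinction on a specific day)
are not test targets.

## A worked example

```{r example, eval = FALSE}
library(tumorCTL)
run <- runHybrid(baseParams(), stopRule(maxDays = 300), seed = 1)
outcome(run)
#> OutcomeSummary
#>   extinction : day 73.531
#>   max tumor  : 666 cells at day 66.80
#>   relapses   : 0
#>   failed     : FALSE
```

The tumor grows undetected for ~9 weeks; once it passes a few hundred
cells the node output floods the site with CTLs and the burden collapses
to zero. The `timeSeries()` accessor exposes the full per-10-minute record
of both compartments for plotting.
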