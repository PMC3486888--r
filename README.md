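# tumorCTL

Can preventative cancer vaccination work? That is, can a standing pool of
anti-tumor memory cytotoxic T lymphocytes (CTLs) — a few percent of the
CTLs in a draining lymph node — find and destroy an incipient solid tumor
while it is still thousands of cells, far below clinical detection?
`tumorCTL` is a simulator for that question, intended for computational
immunologists and modelers studying tumor immunosurveillance.

## The model

Two compartments advance on a shared 1-minute step:

* **Tumor site (agent-based).** Cells are non-overlapping 5-µm spheres in
  a 500-µm-radius tissue sphere. Tumor cells are immotile and divide with
  per-step probability `1 − exp(−dt/d_tum)`, placing daughters tangent in
  uniformly sampled free directions (no space → no division). CTLs move
  by a 3-D Wiener process (per-coordinate sd `σ(t)·√dt`, with a linear
  acceleration ramp after each stop), halt at first contact, engage
  adjacent tumor cells, and while engaged recruit new CTLs (mean 8 h) and
  kill their target (mean 24 h); CTL lifespan is 41 h. Immigration is a
  Poisson influx in a ~31-µm annulus whose intensity tracks the
  peripheral effector concentration; every CTL outside the region after
  the motion phase is removed (a probabilistic constant-concentration
  boundary).
* **Lymph node (deterministic difference system with delays).** Tissue
  APCs take up tumor antigen at rate `a·T(t)`, mature into the node,
  and activate memory CTLs by mass action. Activated memory CTLs complete
  a division program of `n` divisions (duration `1 + (n−1)·τ_div` days)
  and re-enter as `2^n` effectors; restimulated effectors return doubled
  after `τ_div`; effectors egress to the periphery, which drives the
  ABM's immigration. A method-of-steps DDE solver of the continuous
  system (`deSolve::dede`) validates the per-step stepper to <1%.

A companion deterministic **surface-kill ODE** explains the observed
endgame: growth and killing both scale with the spherical tumor's surface
(`∝ T^(2/3)`), so the cube root of the burden declines linearly and hits
exactly zero in finite time — polynomial, not exponential, decline.

## A worked example

```r
library(tumorCTL)
run <- runHybrid(baseParams(), stopRule(maxDays = 300), seed = 1)
outcome(run)
#> OutcomeSummary
#>   extinction : day 73.531
#>   max tumor  : 666 cells at day 66.80
#>   relapses   : 0
#>   failed     : FALSE
```

With the base 2% memory pool the tumor grows silently for about nine
weeks; once it passes a few hundred cells, antigen reaching the node
ignites clonal expansion, CTLs flood the site, and the burden collapses
to zero on day 73 — elimination well below the 10,000-cell / 2-year
failure criterion (`failed : FALSE`). Slowing CTL recruitment to 24 h
(`simParams(dRecr = 24)`) produces relapsing oscillations instead;
`runSweep("dTum", c(1, 2, 4, 7, 14, 30), ...)` reproduces the strong
positive rank correlation between tumor division time and extinction
time.

Other entry points: `runOdeModel()` (surface-kill ODE),
`lnRun()` / `ddeSolveReference()` (lymph node alone), `runSweep()`
(one-at-a-time Spearman sensitivity), `summarizeRun()` /
`cubeRootFit()` (endpoints), and the `exec/tumorctl` command line
(`simulate`, `ode`, `sweep`, `analyze`, `snapshot` subcommands). The
methods vignette (`vignettes/hybrid-tumor-immunity.Rmd`) documents the
model, parameters, and numerical choices.

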