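# Central S4 classes. All spatial lengths are in micrometres, ABM times in
# minutes, lymph-node rates in day^-1 and concentrations in 1e3 cells/mm^3.

#' Simulation parameters
#'
#' Single source of truth for every model parameter: the time step and
#' geometry of the agent-based tumor site, the per-event mean waiting times
#' of tumor cells and CTLs, and the rate constants of the lymph-node
#' difference/delay system, together with quantities derived from them
#' (APC supply rate, division-program duration, immigration-annulus width,
#' equilibrium memory concentration). Create with [simParams()] or
#' [validateParams()]; do not fill slots by hand.
#'
#' @slot dt time step, minutes.
#' @slot rCell cell radius, micrometres (tumor cells and CTLs alike).
#' @slot dTum mean tumor division time, days.
#' @slot sigmaMax maximum unit standard deviation of CTL diffusion,
#'   um min^(-1/2).
#' @slot tAccel time for a CTL to accelerate from rest to full diffusion
#'   speed, hours.
#' @slot dLife mean CTL lifespan, hours.
#' @slot dRecr mean time for an engaged CTL to recruit another CTL, hours.
#' @slot dKill mean time for an engaged CTL to kill its target, hours.
#' @slot rRoi radius of the simulated spherical region of interest, um.
#' @slot pCross target one-step probability that a CTL crosses the full
#'   immigration annulus; sets the annulus width.
#' @slot wCloud immigration-annulus ("CTL cloud") thickness, um (derived).
#' @slot rVol tissue : lymph-node volume ratio (dimensionless).
#' @slot cCtl lymph-node CTL concentration, 1e3 cells/mm^3.
#' @slot cDc lymph-node dendritic-cell/APC concentration, 1e3 cells/mm^3.
#' @slot a0 initial immature-APC concentration in the tissue, 1e3 cells/mm^3.
#' @slot deltaA immature-APC death/turnover rate, day^-1.
#' @slot sA immature-APC supply rate, 1e3 cells/mm^3/day (derived:
#'   \code{deltaA * a0} so A0 is the unstimulated equilibrium).
#' @slot deltaMA mature-APC death/turnover rate, day^-1.
#' @slot mFrac anti-tumor memory pool as a fraction of \code{cCtl}.
#' @slot mEq equilibrium memory-CTL concentration, 1e3 cells/mm^3 (derived).
#' @slot rhoM logistic replenishment rate of memory CTLs, day^-1.
#' @slot nDiv minimal number of divisions of an activated memory CTL.
#' @slot deltaE effector-CTL death rate, day^-1.
#' @slot b APC-CTL mass-action stimulation coefficient,
#'   (1e3 cells/mm^3)^-1 day^-1.
#' @slot tauDiv duration of one CTL division, days.
#' @slot tauProg duration of the full division program, days (derived:
#'   \code{1 + (nDiv - 1) * tauDiv}).
#' @slot antigenicity per-tumor-cell rate at which tissue APCs take up
#'   antigen and mature, day^-1 per tumor cell.
#' @slot g egress rate of effector CTLs from the lymph node, day^-1.
#' @slot kappaG calibration constant of the surface-growth term of the
#'   deterministic surface-kill ODE (dimensionless, default 1).
#' @slot kappaIn calibration constant of the CTL-influx term of the
#'   surface-kill ODE (dimensionless, default 1).
#' @slot seed RNG seed used when none is supplied to a runner.
#'
#' @seealso [simParams()], [validateParams()], [baseParams()]
#' @export
setClass("SimulationParams",
  representation(
    dt = "numeric", rCell = "numeric", dTum = "numeric",
    sigmaMax = "numeric", tAccel = "numeric", dLife = "numeric",
    dRecr = "numeric", dKill = "numeric", rRoi = "numeric",
    pCross = "numeric", wCloud = "numeric", rVol = "numeric",
    cCtl = "numeric", cDc = "numeric", a0 = "numeric",
    deltaA = "numeric", sA = "numeric", deltaMA = "numeric",
    mFrac = "numeric", mEq = "numeric", rhoM = "numeric",
    nDiv = "integer", deltaE = "numeric", b = "numeric",
    tauDiv = "numeric", tauProg = "numeric", antigenicity = "numeric",
    g = "numeric", kappaG = "numeric", kappaIn = "numeric",
    seed = "integer"
  )
)

#' Lymph-node/periphery state of the difference system
#'
#' Five concentrations (immature APCs in the tissue, mature antigen-bearing
#' APCs in the node, memory CTLs, effector CTLs in the node, effector CTLs
#' in the periphery) plus the ring buffers of past values needed by the
#' delayed re-entry terms (division program, single division).
#'
#' Buffer slot \code{(k mod L)} holds the value at step \code{k}, with
#' \code{L = max(kProg, kDiv) + 1}; pre-time-zero history is the steady
#' state (memory at its equilibrium, all activated pools at zero).
#'
#' @slot A immature-APC concentration, 1e3 cells/mm^3.
#' @slot MA mature-APC concentration in the node.
#' @slot M memory-CTL concentration.
#' @slot eLn effector-CTL concentration in the node.
#' @slot eTiss effector-CTL concentration in the periphery.
#' @slot k step index (state is the value *at* step k).
#' @slot histM,histMA,histELn delay ring buffers.
#' @slot kProg number of steps in the division-program delay.
#' @slot kDiv number of steps in the single-division delay.
#' @seealso [initLnState()], [lnStep()], [lnRun()]
#' @export
setClass("LymphNodeState",
  representation(
    A = "numeric", MA = "numeric", M = "numeric",
    eLn = "numeric", eTiss = "numeric", k = "integer",
    histM = "numeric", histMA = "numeric", histELn = "numeric",
    kProg = "integer", kDiv = "integer"
  ),
  validity = function(object) {
    msg <- character()
    v <- c(object@A, object@MA, object@M, object@eLn, object@eTiss)
    if (any(!is.finite(v)) || any(v < 0))
      msg <- c(msg, "all five concentrations must be finite and nonnegative")
    L <- max(object@kProg, object@kDiv) + 1L
    if (length(object@histM) != L || length(object@histMA) != L ||
        length(object@histELn) != L)
      msg <- c(msg, sprintf("history buffers must have length %d", L))
    if (length(msg)) msg else TRUE
  }
)

#' Off-lattice tumor-site state
#'
#' Agent populations of the 3-D agent-based model: non-motile tumor cells
#' and motile CTLs, all spheres of radius \code{rCell} inside the bounded
#' region of interest. CTLs are either moving (target \code{NA}) or engaged
#' to the tumor cell whose id they store.
#'
#' @slot tumorPos n x 3 matrix of tumor-cell centres, um.
#' @slot tumorId integer ids of tumor cells (stable across steps).
#' @slot ctlPos m x 3 matrix of CTL centres, um.
#' @slot ctlTstop minutes since each CTL last started moving (\code{Inf}
#'   means "at full speed", e.g. cloud immigrants).
#' @slot ctlTarget id of the engaged tumor cell, or \code{NA} if moving.
#' @slot ctlId integer ids of CTLs.
#' @slot step step counter.
#' @slot nextTumorId,nextCtlId id counters for newly created agents.
#' @seealso [initSite()], [abmStep()]
#' @export
setClass("TumorSite",
  representation(
    tumorPos = "matrix", tumorId = "integer",
    ctlPos = "matrix", ctlTstop = "numeric", ctlTarget = "integer",
    ctlId = "integer", step = "integer",
    nextTumorId = "integer", nextCtlId = "integer"
  ),
  validity = function(object) {
    msg <- character()
    if (ncol(object@tumorPos) != 3L || ncol(object@ctlPos) != 3L)
      msg <- c(msg, "position matrices must have 3 columns")
    if (nrow(object@tumorPos) != length(object@tumorId))
      msg <- c(msg, "tumorId length must match tumorPos rows")
    m <- nrow(object@ctlPos)
    if (length(object@ctlTstop) != m || length(object@ctlTarget) != m ||
        length(object@ctlId) != m)
      msg <- c(msg, "CTL attribute lengths must match ctlPos rows")
    eng <- !is.na(object@ctlTarget)
    if (any(eng) && !all(object@ctlTarget[eng] %in% object@tumorId))
      msg <- c(msg, "every engaged CTL must target an existing tumor cell")
    if (length(msg)) msg else TRUE
  }
)

#' Stopping rule for a hybrid run
#'
#' @slot maxDays horizon in days.
#' @slot stopOnExtinction stop as soon as the tumor count reaches zero.
#' @slot failureThresholdCells immune-failure criterion: the tumor must be
#'   eliminated below this burden (default 10,000 cells).
#' @slot failureHorizonDays immune-failure criterion: elimination must occur
#'   within this many days (default 730, i.e. two years).
#' @seealso [stopRule()]
#' @export
setClass("StopRule",
  representation(maxDays = "numeric", stopOnExtinction = "logical",
                 failureThresholdCells = "numeric",
                 failureHorizonDays = "numeric"),
  validity = function(object) {
    if (object@maxDays <= 0) "maxDays must be positive" else TRUE
  }
)

#' Outcome summary of a run
#'
#' @slot extinctionTime first time (days) the tumor count reached zero, or
#'   \code{NA} if it never did within the horizon.
#' @slot maxTumor peak tumor-cell count.
#' @slot tMaxTumor time (days) of the peak.
#' @slot nRelapses number of drop-and-recover cycles (see [summarizeRun()]).
#' @slot failed immune-failure flag per the [StopRule-class] criterion.
#' @export
setClass("OutcomeSummary",
  representation(extinctionTime = "numeric", maxTumor = "numeric",
                 tMaxTumor = "numeric", nRelapses = "integer",
                 failed = "logical"))

#' Result of a hybrid ABM-DDE run
#'
#' @slot series recorded time series (data.frame with columns t_days,
#'   tumor_count, ctl_count_site, ctl_engaged_count, A, MA, M, E_ln, E_tiss).
#' @slot outcome an \linkS4class{OutcomeSummary}.
#' @slot params the \linkS4class{SimulationParams} used.
#' @slot stop the \linkS4class{StopRule} used.
#' @slot seed RNG seed of the run.
#' @seealso [runHybrid()]
#' @export
setClass("HybridRun",
  representation(series = "data.frame", outcome = "OutcomeSummary",
                 params = "SimulationParams", stop = "StopRule",
                 seed = "integer"))

#' Result of a deterministic surface-kill ODE run
#'
#' @slot series data.frame with columns t_days, T, E_s, E_tiss.
#' @slot extinctionTime finite-time extinction day, or \code{NA}.
#' @slot params the \linkS4class{SimulationParams} used.
#' @seealso [runOdeModel()]
#' @export
setClass("SurfaceRun",
  representation(series = "data.frame", extinctionTime = "numeric",
                 params = "SimulationParams"))

#' One-at-a-time sensitivity sweep result
#'
#' @slot param name of the swept parameter.
#' @slot grid values used.
#' @slot outcomes one row per run (value, rep, seed, extinction_time,
#'   censored, max_tumor, n_relapses, failed).
#' @slot rho data.frame of Spearman rank correlations and p-values of the
#'   parameter against extinction time and log10 maximum tumor burden.
#' @slot reps replicates per grid value.
#' @slot seed0 base seed.
#' @seealso [runSweep()]
#' @export
setClass("SensitivityResult",
  representation(param = "character", grid = "numeric",
                 outcomes = "data.frame", rho = "data.frame",
                 reps = "integer", seed0 = "integer"))
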