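# Parameter construction, validation and the derived quantities.

MIN_PER_DAY <- 1440

#' Duration of the CTL division program
#'
#' An activated memory CTL completes a fixed minimal program of `nDiv`
#' divisions before becoming an effector. The first division takes one day;
#' each subsequent division takes `tauDiv` days, so the program lasts
#' `1 + (nDiv - 1) * tauDiv` days.
#'
#' @param nDiv number of divisions (>= 1).
#' @param tauDiv duration of one division, days (> 0).
#' @return Program duration in days.
#' @examples
#' deriveTauProg(10, 1)     # 10 days
#' deriveTauProg(10, 1 / 6) # 2.5 days
#' @export
deriveTauProg <- function(nDiv, tauDiv) {
  if (length(nDiv) != 1L || !is.finite(nDiv) || nDiv < 1 ||
      abs(nDiv - round(nDiv)) > 1e-8)
    stop("nDiv must be a single integer >= 1")
  if (length(tauDiv) != 1L || !is.finite(tauDiv) || tauDiv <= 0)
    stop("tauDiv must be a single positive number of days")
  1 + (round(nDiv) - 1) * tauDiv
}

#' Steady-state supply rate of immature APCs
#'
#' The tissue APC pool obeys dA/dt = sA - deltaA * A in the absence of
#' antigen; choosing `sA = deltaA * A0` makes `A0` the unstimulated
#' equilibrium, so the population stays at its resting level until the
#' tumor appears.
#'
#' @param deltaA death/turnover rate, day^-1 (>= 0).
#' @param a0 equilibrium concentration, 1e3 cells/mm^3 (>= 0).
#' @return Supply rate, 1e3 cells/mm^3/day.
#' @export
deriveSupplyRate <- function(deltaA, a0) {
  if (!is.finite(deltaA) || deltaA < 0) stop("deltaA must be nonnegative")
  if (!is.finite(a0) || a0 < 0) stop("a0 must be nonnegative")
  deltaA * a0
}

#' Width of the CTL immigration annulus
#'
#' CTLs outside the region of interest are represented by a thin annulus
#' (the "CTL cloud") repopulated every step from the well-mixed periphery.
#' The annulus must be thick enough that a CTL just outside it has only a
#' small probability `pCross` of crossing the whole annulus in a single
#' step. One-step orthogonal displacement is N(0, (sigmaMax^2) * dt), so
#' the width is the upper `pCross` normal quantile:
#' `w = qnorm(1 - pCross) * sigmaMax * sqrt(dt)`.
#'
#' @param sigmaMax maximal unit standard deviation of CTL motion,
#'   um min^(-1/2).
#' @param dt time step, minutes.
#' @param pCross target one-step crossing probability, in (0, 0.5).
#' @return Annulus thickness in um.
#' @examples
#' deriveCloudWidth(10, 1, 0.001) # ~30.9 um; crossing probability 0.001
#' @export
deriveCloudWidth <- function(sigmaMax, dt, pCross = 0.001) {
  if (!is.finite(sigmaMax) || sigmaMax <= 0) stop("sigmaMax must be positive")
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  if (!is.finite(pCross) || pCross <= 0 || pCross >= 0.5)
    stop("pCross must lie strictly between 0 and 0.5")
  stats::qnorm(1 - pCross) * sigmaMax * sqrt(dt)
}

#' Lymph-node cell concentrations from slice counts
#'
#' Converts cell counts observed in a fractional slice of a spherical lymph
#' node into concentrations. With the literature values (1600 CTLs and 100
#' dendritic cells in a 1/500 slice of a radius-1-mm node) this gives
#' approximately 191 and 11.9 in units of 1e3 cells/mm^3.
#'
#' @param nCtlSlice,nDcSlice cell counts in the slice.
#' @param nodeRadius lymph-node radius, mm.
#' @param sliceFraction slice volume as a fraction of the node volume.
#' @return Named numeric vector \code{c(cCtl = , cDc = )} in 1e3 cells/mm^3.
#' @export
deriveLnConcentrations <- function(nCtlSlice = 1600, nDcSlice = 100,
                                   nodeRadius = 1, sliceFraction = 1 / 500) {
  if (any(!is.finite(c(nCtlSlice, nDcSlice))) || nCtlSlice < 0 || nDcSlice < 0)
    stop("slice counts must be nonnegative")
  if (!is.finite(nodeRadius) || nodeRadius <= 0 ||
      !is.finite(sliceFraction) || sliceFraction <= 0)
    stop("nodeRadius and sliceFraction must be positive")
  vol <- sliceFraction * (4 / 3) * pi * nodeRadius^3 # mm^3
  c(cCtl = nCtlSlice / vol / 1e3, cDc = nDcSlice / vol / 1e3)
}

#' Per-step event probability from a mean waiting time
#'
#' Exponential-hazard conversion `p = 1 - exp(-dt / meanTime)`, used for
#' all per-step Bernoulli events of the agent-based model (division, death,
#' recruitment, killing). Guarantees p in [0, 1) for any step size and
#' reduces to `dt / meanTime` when `dt << meanTime`.
#'
#' @param meanTime mean waiting time of the event (> 0).
#' @param dt time step, same units as `meanTime` (>= 0).
#' @return Probability that the event fires within one step.
#' @examples
#' perStepProb(480, 1) # 8-h recruitment at a 1-min step: ~2.081e-3
#' @export
perStepProb <- function(meanTime, dt) {
  if (any(!is.finite(meanTime)) || any(meanTime <= 0))
    stop("meanTime must be positive (infinitely fast events are not modeled)")
  if (any(!is.finite(dt)) || any(dt < 0)) stop("dt must be nonnegative")
  -expm1(-dt / meanTime)
}

.paramDefaults <- function() {
  conc <- deriveLnConcentrations()
  list(
    dt = 1, rCell = 5, dTum = 7, sigmaMax = 10, tAccel = 5,
    dLife = 41, dRecr = 8, dKill = 24, rRoi = 500, pCross = 0.001,
    wCloud = NA_real_, rVol = 1000,
    cCtl = unname(conc["cCtl"]), cDc = unname(conc["cDc"]),
    # tissue APC *count* ~ node APC count, spread over a rVol-times larger
    # volume, so the tissue concentration is cDc / rVol
    a0 = unname(conc["cDc"]) / 1000,
    deltaA = 0.03, sA = NA_real_, deltaMA = log(2) / (20 / 24),
    mFrac = 0.02, mEq = NA_real_, rhoM = log(2), nDiv = 10L,
    deltaE = log(2) / (41 / 24),
    # pairwise APC-CTL interaction rate 2.4/day, successful-stimulation
    # probability 0.5, divided by the slice-volume concentration unit
    b = 0.5 * 2.4 / (1 / ((1 / 500) * (4 / 3) * pi) / 1e3),
    tauDiv = 1 / 3, tauProg = NA_real_, antigenicity = 1e-7,
    g = log(2), kappaG = 1, kappaIn = 1, seed = 1L
  )
}

.checkDelayRatio <- function(tau, dt, what) {
  # tau in days, dt in minutes
  ratio <- tau * MIN_PER_DAY / dt
  if (ratio < 1 - 1e-8 || abs(ratio - round(ratio)) > 1e-6 * max(1, ratio)) {
    near <- max(1, round(ratio)) * dt / MIN_PER_DAY
    stop(sprintf(
      "%s (%g days) is not a positive integer multiple of dt (%g min); nearest valid value is %g days",
      what, tau, dt, near))
  }
  as.integer(round(ratio))
}

#' Validate a raw parameter mapping
#'
#' Accepts a named list (or nothing) of parameter overrides, fills every
#' other field with its base estimate, computes the derived quantities
#' (supply rate, division-program duration, annulus width, equilibrium
#' memory concentration) and checks all model invariants: positivity,
#' `0 < mFrac <= 1`, `0 < pCross < 0.5`, integer delay/step ratios, and a
#' region of interest large enough to hold a close-packed spherical tumor
#' of at least 50,000 cells.
#'
#' @param raw named list of overrides; unknown names are an error.
#' @return A validated \linkS4class{SimulationParams}.
#' @seealso [simParams()] for the `...` form, [baseParams()] for the
#'   defaults.
#' @export
validateParams <- function(raw = list()) {
  defs <- .paramDefaults()
  if (length(raw)) {
    if (is.null(names(raw)) || any(names(raw) == ""))
      stop("parameter overrides must be named")
    unknown <- setdiff(names(raw), names(defs))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           "\nvalid names: ", paste(names(defs), collapse = ", "))
    defs[names(raw)] <- raw
  }
  p <- defs
  for (nm in setdiff(names(p), c("nDiv", "seed", "wCloud", "sA", "mEq", "tauProg"))) {
    v <- p[[nm]]
    if (length(v) != 1L || !is.numeric(v) || !is.finite(v))
      stop(sprintf("parameter '%s' must be a single finite number", nm))
  }
  strictlyPos <- c("dt", "rCell", "dTum", "sigmaMax", "tAccel", "dLife",
                   "dRecr", "dKill", "rRoi", "rVol", "cCtl", "cDc", "a0",
                   "deltaA", "deltaMA", "rhoM", "b", "tauDiv",
                   "g", "kappaG", "kappaIn")
  for (nm in strictlyPos)
    if (p[[nm]] <= 0) stop(sprintf("parameter '%s' must be strictly positive", nm))
  # zero is meaningful for these two: a = 0 switches antigen uptake off,
  # deltaE = 0 makes effectors immortal (used in limiting-case analyses)
  for (nm in c("antigenicity", "deltaE"))
    if (p[[nm]] < 0) stop(sprintf("parameter '%s' must be nonnegative", nm))
  if (p$mFrac <= 0 || p$mFrac > 1) stop("mFrac must satisfy 0 < mFrac <= 1")
  if (p$pCross <= 0 || p$pCross >= 0.5) stop("pCross must satisfy 0 < pCross < 0.5")
  nDiv <- p$nDiv
  if (!is.finite(nDiv) || nDiv < 1 || abs(nDiv - round(nDiv)) > 1e-8)
    stop("nDiv must be an integer >= 1")
  nDiv <- as.integer(round(nDiv))

  sA <- if (is.na(p$sA)) deriveSupplyRate(p$deltaA, p$a0) else p$sA
  mEq <- if (is.na(p$mEq)) p$mFrac * p$cCtl else p$mEq
  wCloud <- if (is.na(p$wCloud)) deriveCloudWidth(p$sigmaMax, p$dt, p$pCross) else p$wCloud
  tauProg <- if (is.na(p$tauProg)) deriveTauProg(nDiv, p$tauDiv) else p$tauProg
  if (sA < 0) stop("sA must be nonnegative")
  if (mEq <= 0 || wCloud <= 0 || tauProg <= 0)
    stop("derived mEq, wCloud and tauProg must be positive")

  .checkDelayRatio(p$tauDiv, p$dt, "tauDiv")
  .checkDelayRatio(tauProg, p$dt, "tauProg")

  # region of interest must hold >= 50,000 close-packed cells of radius rCell
  minR <- p$rCell * (5e4 / 0.64)^(1 / 3)
  if (p$rRoi < minR)
    stop(sprintf("rRoi = %g um cannot hold a 50,000-cell tumor; need >= %.0f um",
                 p$rRoi, minR))

  new("SimulationParams",
      dt = p$dt, rCell = p$rCell, dTum = p$dTum, sigmaMax = p$sigmaMax,
      tAccel = p$tAccel, dLife = p$dLife, dRecr = p$dRecr, dKill = p$dKill,
      rRoi = p$rRoi, pCross = p$pCross, wCloud = wCloud, rVol = p$rVol,
      cCtl = p$cCtl, cDc = p$cDc, a0 = p$a0, deltaA = p$deltaA, sA = sA,
      deltaMA = p$deltaMA, mFrac = p$mFrac, mEq = mEq, rhoM = p$rhoM,
      nDiv = nDiv, deltaE = p$deltaE, b = p$b, tauDiv = p$tauDiv,
      tauProg = tauProg, antigenicity = p$antigenicity, g = p$g,
      kappaG = p$kappaG, kappaIn = p$kappaIn,
      seed = as.integer(p$seed))
}

#' Construct simulation parameters
#'
#' Convenience wrapper around [validateParams()]: base estimates for every
#' parameter, overridden by named arguments.
#'
#' @param ... named parameter overrides (see
#'   \linkS4class{SimulationParams} for names and units).
#' @return A validated \linkS4class{SimulationParams}.
#' @examples
#' p <- simParams(mFrac = 0.03, antigenicity = 1e-6)
#' @export
simParams <- function(...) validateParams(list(...))

#' Base parameter set
#'
#' @return The \linkS4class{SimulationParams} holding every base estimate.
#' @export
baseParams <- function() validateParams()

#' @describeIn simParams convert a parameter object back to a named list
#'   (round-trips through [validateParams()]).
#' @param p a \linkS4class{SimulationParams}.
#' @export
paramsAsList <- function(p) {
  stopifnot(is(p, "SimulationParams"))
  nm <- names(.paramDefaults())
  out <- lapply(nm, function(n) slot(p, n))
  names(out) <- nm
  out
}

setMethod("show", "SimulationParams", function(object) {
  cat("SimulationParams (units: min, um, days, 1e3 cells/mm^3)\n")
  cat(sprintf("  ABM : dt=%g min, rCell=%g um, dTum=%g d, sigmaMax=%g, tAccel=%g h\n",
              object@dt, object@rCell, object@dTum, object@sigmaMax, object@tAccel))
  cat(sprintf("        dLife=%g h, dRecr=%g h, dKill=%g h, rRoi=%g um, wCloud=%.2f um\n",
              object@dLife, object@dRecr, object@dKill, object@rRoi, object@wCloud))
  cat(sprintf("  LN  : rVol=%g, A0=%.3g, sA=%.3g, deltaA=%g, deltaMA=%.3g\n",
              object@rVol, object@a0, object@sA, object@deltaA, object@deltaMA))
  cat(sprintf("        mEq=%.3g (%.0f%% of cCtl=%.3g), rhoM=%.3g, nDiv=%d, b=%.3g\n",
              object@mEq, 100 * object@mFrac, object@cCtl, object@rhoM,
              object@nDiv, object@b))
  cat(sprintf("        deltaE=%.3g, tauDiv=%.3g d, tauProg=%.3g d, a=%.3g, g=%.3g\n",
              object@deltaE, object@tauDiv, object@tauProg,
              object@antigenicity, object@g))
  invisible(object)
})

# internal: parameters flattened for the C++ core (ABM times in minutes,
# lymph-node rates per *step*, probabilities precomputed)
.cppParams <- function(p) {
  dtDays <- p@dt / MIN_PER_DAY
  vCloud <- (4 / 3) * pi * ((p@rRoi + p@wCloud)^3 - p@rRoi^3) * 1e-9 # mm^3
  list(
    dt = p@dt, dtDays = dtDays, rCell = p@rCell, rRoi = p@rRoi,
    wCloud = p@wCloud, sigmaMax = p@sigmaMax, tAccelMin = p@tAccel * 60,
    pDiv = perStepProb(p@dTum * MIN_PER_DAY, p@dt),
    pDeath = perStepProb(p@dLife * 60, p@dt),
    pRecr = perStepProb(p@dRecr * 60, p@dt),
    pKill = perStepProb(p@dKill * 60, p@dt),
    vCloud = vCloud,
    sA = p@sA, a0 = p@a0, deltaA = p@deltaA, deltaMA = p@deltaMA, rhoM = p@rhoM,
    mEq = p@mEq, b = p@b, g = p@g, deltaE = p@deltaE,
    aAnt = p@antigenicity, rVol = p@rVol, twoN = 2^p@nDiv,
    kProg = as.integer(round(p@tauProg / dtDays)),
    kDiv = as.integer(round(p@tauDiv / dtDays))
  )
}

#' Stopping rule constructor
#'
#' @param maxDays simulation horizon, days.
#' @param stopOnExtinction stop when the tumor count first reaches zero.
#' @param failureThresholdCells,failureHorizonDays immune-failure criterion:
#'   the tumor must be eliminated below this burden and within this time
#'   for the response to count as a success.
#' @return A \linkS4class{StopRule}.
#' @export
stopRule <- function(maxDays = 730, stopOnExtinction = TRUE,
                     failureThresholdCells = 1e4, failureHorizonDays = 730) {
  new("StopRule", maxDays = maxDays, stopOnExtinction = stopOnExtinction,
      failureThresholdCells = failureThresholdCells,
      failureHorizonDays = failureHorizonDays)
}
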