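# R surface of the agent-based tumor-site model. Each phase function is a
# thin wrapper over the compiled core; the event probabilities default to
# the hazard-consistent per-step values but can be forced (e.g. to 1) to
# construct deterministic scenarios.

.siteAsList <- function(site) {
  list(tumorPos = site@tumorPos, tumorId = site@tumorId,
       ctlPos = site@ctlPos, ctlTstop = site@ctlTstop,
       ctlTarget = site@ctlTarget, ctlId = site@ctlId,
       step = as.double(site@step), nextTumorId = site@nextTumorId,
       nextCtlId = site@nextCtlId)
}

.siteFromList <- function(sl) {
  new("TumorSite",
      tumorPos = sl$tumorPos, tumorId = as.integer(sl$tumorId),
      ctlPos = sl$ctlPos, ctlTstop = as.numeric(sl$ctlTstop),
      ctlTarget = as.integer(sl$ctlTarget), ctlId = as.integer(sl$ctlId),
      step = as.integer(sl$step), nextTumorId = as.integer(sl$nextTumorId),
      nextCtlId = as.integer(sl$nextCtlId))
}

#' Initialize the tumor site
#'
#' The tumor grows from a single cell at the origin at time zero; no CTLs
#' are present until they immigrate or are recruited.
#'
#' @param params a \linkS4class{SimulationParams}.
#' @return A \linkS4class{TumorSite} with one tumor cell and zero CTLs.
#' @export
initSite <- function(params) {
  stopifnot(is(params, "SimulationParams"))
  new("TumorSite",
      tumorPos = matrix(0, 1, 3), tumorId = 1L,
      ctlPos = matrix(0, 0, 3), ctlTstop = numeric(0),
      ctlTarget = integer(0), ctlId = integer(0),
      step = 0L, nextTumorId = 2L, nextCtlId = 1L)
}

#' Add agents to a site
#'
#' Mainly for constructing small test and illustration scenarios.
#'
#' @param site a \linkS4class{TumorSite}.
#' @param pos length-3 numeric position, um.
#' @param tstop minutes since the CTL started moving (`Inf` = full speed,
#'   `0` = freshly stopped/recruited).
#' @return The modified site.
#' @export
addTumorCell <- function(site, pos) {
  site@tumorPos <- rbind(site@tumorPos, as.numeric(pos))
  site@tumorId <- c(site@tumorId, site@nextTumorId)
  site@nextTumorId <- site@nextTumorId + 1L
  validObject(site)
  site
}

#' @rdname addTumorCell
#' @export
addCtl <- function(site, pos, tstop = Inf) {
  site@ctlPos <- rbind(site@ctlPos, as.numeric(pos))
  site@ctlTstop <- c(site@ctlTstop, tstop)
  site@ctlTarget <- c(site@ctlTarget, NA_integer_)
  site@ctlId <- c(site@ctlId, site@nextCtlId)
  site@nextCtlId <- site@nextCtlId + 1L
  validObject(site)
  site
}

#' CTL diffusion coefficient during acceleration
#'
#' A CTL that has just stopped (after an engagement ends, or on
#' recruitment) re-accelerates linearly: its unit standard deviation is
#' `min(t / tAccel, 1) * sigmaMax`, the Wiener-process limit of a random
#' walk whose step size grows linearly with time since rest.
#'
#' @param tSinceStop minutes since the CTL started moving (vectorized).
#' @param params a \linkS4class{SimulationParams}.
#' @return Unit standard deviation, um min^(-1/2).
#' @export
ctlSigma <- function(tSinceStop, params) {
  if (any(tSinceStop < 0, na.rm = TRUE)) stop("tSinceStop must be >= 0")
  pmin(tSinceStop / (params@tAccel * 60), 1) * params@sigmaMax
}

#' ABM phases
#'
#' The individual sub-steps of one ABM time step, exposed separately so
#' that each behavior can be exercised and tested in isolation. The full
#' step applies them in order: cloud spawn, CTL death, recruitment/killing
#' by engaged CTLs, tumor division, CTL motion (agents visited in a fresh
#' random permutation), engagement update, boundary cull.
#'
#' @param site a \linkS4class{TumorSite}.
#' @param params a \linkS4class{SimulationParams}.
#' @param eTiss effector-CTL concentration in the periphery
#'   (1e3 cells/mm^3) driving Poisson immigration into the annulus.
#' @param prob,pRecr,pKill per-step event probability override; default is
#'   the hazard-consistent [perStepProb()] value from `params`.
#' @return The advanced \linkS4class{TumorSite}.
#' @name abm-phases
NULL

#' @describeIn abm-phases move every non-engaged CTL by a 3-D Wiener step
#'   (per-coordinate sd `ctlSigma(tstop) * sqrt(dt)`), stopping at the
#'   first contact with another agent along the displacement segment.
#' @export
moveCtls <- function(site, params) {
  .siteFromList(abm_move_cpp(.cppParams(params), .siteAsList(site)))
}

#' @describeIn abm-phases engage every moving CTL within contact distance
#'   (`2 rCell`, inclusive tolerance `1e-3 rCell`) of a tumor cell to the
#'   nearest such cell (ties to the lowest id).
#' @export
updateEngagements <- function(site, params) {
  .siteFromList(abm_engage_cpp(.cppParams(params), .siteAsList(site)))
}

#' @describeIn abm-phases each tumor cell divides with probability
#'   `perStepProb(dTum, dt)`; the daughter appears tangent to its parent in
#'   a uniformly sampled unoccupied direction, confined to the region of
#'   interest; with no free direction the division fails.
#' @export
attemptTumorDivisions <- function(site, params, prob = NULL) {
  if (is.null(prob)) prob <- perStepProb(params@dTum * MIN_PER_DAY, params@dt)
  .siteFromList(abm_divide_cpp(.cppParams(params), .siteAsList(site), prob))
}

#' @describeIn abm-phases every engaged CTL independently recruits a new
#'   CTL tangent to itself (probability `perStepProb(dRecr, dt)`) and kills
#'   its target (probability `perStepProb(dKill, dt)`); on a kill all CTLs
#'   engaging that tumor cell disengage and re-accelerate from rest.
#' @export
attemptRecruitAndKill <- function(site, params, pRecr = NULL, pKill = NULL) {
  if (is.null(pRecr)) pRecr <- perStepProb(params@dRecr * 60, params@dt)
  if (is.null(pKill)) pKill <- perStepProb(params@dKill * 60, params@dt)
  .siteFromList(abm_recruit_kill_cpp(.cppParams(params), .siteAsList(site),
                                     pRecr, pKill))
}

#' @describeIn abm-phases every CTL dies with probability
#'   `perStepProb(dLife, dt)`.
#' @export
applyCtlDeath <- function(site, params, prob = NULL) {
  if (is.null(prob)) prob <- perStepProb(params@dLife * 60, params@dt)
  .siteFromList(abm_death_cpp(.cppParams(params), .siteAsList(site), prob))
}

#' @describeIn abm-phases draw `Poisson(eTiss * 1e3 * Vcloud)` CTLs and
#'   place them uniformly (non-overlapping) in the immigration annulus at
#'   full speed.
#' @export
spawnCloud <- function(site, eTiss, params) {
  if (!is.finite(eTiss) || eTiss < 0) stop("eTiss must be >= 0")
  .siteFromList(abm_spawn_cpp(.cppParams(params), .siteAsList(site), eTiss))
}

#' @describeIn abm-phases remove every CTL whose centre lies outside the
#'   region of interest — the absorbing exchange with the well-mixed
#'   periphery (cloud-born and resident CTLs alike).
#' @export
cullBeyondRoi <- function(site, params) {
  .siteFromList(abm_cull_cpp(.cppParams(params), .siteAsList(site)))
}

#' One full ABM time step
#'
#' Applies all phases of [abm-phases] in their canonical order and
#' increments the step counter.
#'
#' @inheritParams abm-phases
#' @return The advanced \linkS4class{TumorSite}.
#' @export
abmStep <- function(site, eTiss, params) {
  if (!is.finite(eTiss) || eTiss < 0) stop("eTiss must be >= 0")
  .siteFromList(abm_step_cpp(.cppParams(params), .siteAsList(site), eTiss))
}

#' Run the ABM alone under a constant peripheral concentration
#'
#' Decoupled tumor-site run: the lymph node is replaced by a fixed
#' `eTiss`; with `eTiss = 0` this is CTL-free tumor growth.
#'
#' @param params a \linkS4class{SimulationParams}.
#' @param maxDays horizon, days.
#' @param eTiss constant peripheral effector concentration.
#' @param seed RNG seed.
#' @param thinMinutes recording interval, minutes.
#' @return A list with `series` (data.frame) and `site` (final
#'   \linkS4class{TumorSite}).
#' @export
runAbm <- function(params, maxDays, eTiss = 0, seed = params@seed,
                   thinMinutes = 10) {
  set.seed(seed)
  cp <- .cppParams(params)
  maxSteps <- ceiling(maxDays * MIN_PER_DAY / params@dt)
  res <- run_hybrid_cpp(cp, .siteAsList(initSite(params)), maxSteps,
                        max(1L, round(thinMinutes / params@dt)),
                        FALSE, FALSE, eTiss)
  list(series = .seriesAsDf(res$series), site = .siteFromList(res$finalSite))
}

.seriesAsDf <- function(m) {
  df <- as.data.frame(m)
  names(df) <- c("t_days", "tumor_count", "ctl_count_site",
                 "ctl_engaged_count", "A", "MA", "M", "E_ln", "E_tiss")
  df
}

#' @rdname tumorCount
#' @export
setMethod("tumorCount", "TumorSite", function(x) nrow(x@tumorPos))

#' @rdname ctlCount
#' @export
setMethod("ctlCount", "TumorSite", function(x) nrow(x@ctlPos))

#' @rdname engagedCount
#' @export
setMethod("engagedCount", "TumorSite", function(x) sum(!is.na(x@ctlTarget)))

setMethod("show", "TumorSite", function(object) {
  cat(sprintf("TumorSite @ step %d: %d tumor cells, %d CTLs (%d engaged)\n",
              object@step, tumorCount(object), ctlCount(object),
              engagedCount(object)))
  invisible(object)
})

#' Site snapshot as a data.frame
#'
#' One row per agent, in the taxonomy used for visualisation: tumor cells,
#' moving CTLs, engaged CTLs.
#'
#' @param site a \linkS4class{TumorSite}.
#' @param t_days time stamp to attach.
#' @return data.frame with columns t_days, agent_type, id, x_um, y_um, z_um.
#' @export
siteSnapshot <- function(site, t_days = NA_real_) {
  typ <- c(rep("tumor", tumorCount(site)),
           ifelse(is.na(site@ctlTarget), "ctl_moving", "ctl_engaged"))
  pos <- rbind(site@tumorPos, site@ctlPos)
  data.frame(t_days = t_days, agent_type = typ,
             id = c(site@tumorId, site@ctlId),
             x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3])
}
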