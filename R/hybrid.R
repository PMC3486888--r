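# The coupled two-compartment driver: agent-based tumor site + lymph-node
# difference system, exchanged synchronously every step.

#' Run the hybrid ABM-DDE simulation
#'
#' Per the coupling loop: at each step the current tumor count is read from
#' the ABM and the current peripheral effector concentration from the
#' difference system; both compartments are then advanced one `dt` using
#' those pre-step values, and the cycle repeats until tumor extinction or
#' the horizon.
#'
#' @param params a \linkS4class{SimulationParams}.
#' @param stop a \linkS4class{StopRule}.
#' @param seed RNG seed (defaults to `params@seed`).
#' @param thinMinutes recording interval of the time series in simulated
#'   minutes (extinction time and peak burden are always tracked at full
#'   `dt` resolution).
#' @return A \linkS4class{HybridRun}.
#' @examples
#' \donttest{
#' run <- runHybrid(baseParams(), stopRule(maxDays = 200), seed = 1)
#' outcome(run)
#' }
#' @export
runHybrid <- function(params, stop = stopRule(), seed = params@seed,
                      thinMinutes = 10) {
  stopifnot(is(params, "SimulationParams"), is(stop, "StopRule"))
  set.seed(seed)
  cp <- .cppParams(params)
  maxSteps <- ceiling(stop@maxDays * MIN_PER_DAY / params@dt)
  res <- run_hybrid_cpp(cp, .siteAsList(initSite(params)), maxSteps,
                        max(1L, round(thinMinutes / params@dt)),
                        stop@stopOnExtinction, TRUE, 0)
  series <- .seriesAsDf(res$series)
  dtDays <- params@dt / MIN_PER_DAY
  ext <- if (res$extinctionStep >= 0) res$extinctionStep * dtDays else NA_real_
  out <- summarizeRun(series, stop,
                      exact = list(extinctionTime = ext,
                                   maxTumor = res$maxTumor,
                                   tMaxTumor = res$tMaxStep * dtDays))
  new("HybridRun", series = series, outcome = out, params = params,
      stop = stop, seed = as.integer(seed))
}

#' Run independent replicates
#'
#' Replicate `i` uses seed `seed0 + i - 1`; replicates are independent
#' given distinct seeds. Runs that reach the horizon without extinction are
#' flagged in their outcome, not dropped.
#'
#' @param params,stop as in [runHybrid()].
#' @param nReps number of replicates (>= 1).
#' @param seed0 base seed.
#' @param thinMinutes recording interval, minutes.
#' @return List of \linkS4class{OutcomeSummary}, one per replicate.
#' @export
runReplicates <- function(params, stop = stopRule(), nReps = 5,
                          seed0 = params@seed, thinMinutes = 10) {
  stopifnot(nReps >= 1)
  lapply(seq_len(nReps), function(i)
    outcome(runHybrid(params, stop, seed = seed0 + i - 1L,
                      thinMinutes = thinMinutes)))
}

#' @rdname timeSeries
#' @export
setMethod("timeSeries", "HybridRun", function(x) x@series)

#' @rdname outcome
#' @export
setMethod("outcome", "HybridRun", function(x) x@outcome)

#' @rdname tumorCount
#' @export
setMethod("tumorCount", "HybridRun", function(x) x@series$tumor_count)

#' @rdname extinctionTime
#' @export
setMethod("extinctionTime", "OutcomeSummary", function(x) x@extinctionTime)

#' @rdname extinctionTime
#' @export
setMethod("extinctionTime", "HybridRun", function(x) x@outcome@extinctionTime)

#' @rdname maxTumor
#' @export
setMethod("maxTumor", "OutcomeSummary", function(x) x@maxTumor)

#' @rdname maxTumor
#' @export
setMethod("maxTumor", "HybridRun", function(x) x@outcome@maxTumor)

#' @rdname nRelapses
#' @export
setMethod("nRelapses", "OutcomeSummary", function(x) x@nRelapses)

#' @rdname nRelapses
#' @export
setMethod("nRelapses", "HybridRun", function(x) x@outcome@nRelapses)

setMethod("show", "OutcomeSummary", function(object) {
  cat("OutcomeSummary\n")
  cat(sprintf("  extinction : %s\n",
              if (is.na(object@extinctionTime)) "none (horizon reached)"
              else sprintf("day %.3f", object@extinctionTime)))
  cat(sprintf("  max tumor  : %g cells at day %.2f\n",
              object@maxTumor, object@tMaxTumor))
  cat(sprintf("  relapses   : %d\n", object@nRelapses))
  cat(sprintf("  failed     : %s\n", object@failed))
  invisible(object)
})

setMethod("show", "HybridRun", function(object) {
  cat(sprintf("HybridRun (seed %d, %d recorded steps)\n",
              object@seed, nrow(object@series)))
  show(object@outcome)
  invisible(object)
})
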