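#' @import methods
NULL

#' Number of tumor cells in an object
#'
#' @param x a \linkS4class{TumorSite} or \linkS4class{HybridRun}.
#' @return Integer count of live tumor cells (for a site) or the recorded
#'   tumor-count column (for a run).
#' @export
setGeneric("tumorCount", function(x) standardGeneric("tumorCount"))

#' Number of CTL agents in an object
#'
#' @param x a \linkS4class{TumorSite}.
#' @return Integer count of CTL agents.
#' @export
setGeneric("ctlCount", function(x) standardGeneric("ctlCount"))

#' Number of engaged CTL agents
#'
#' @param x a \linkS4class{TumorSite}.
#' @return Integer count of CTLs currently engaging a tumor cell.
#' @export
setGeneric("engagedCount", function(x) standardGeneric("engagedCount"))

#' Recorded time series of a simulation run
#'
#' @param x a \linkS4class{HybridRun} or \linkS4class{SurfaceRun}.
#' @return A data.frame, one row per recorded step.
#' @export
setGeneric("timeSeries", function(x) standardGeneric("timeSeries"))

#' Outcome summary of a simulation run
#'
#' @param x a \linkS4class{HybridRun}.
#' @return An \linkS4class{OutcomeSummary}.
#' @export
setGeneric("outcome", function(x) standardGeneric("outcome"))

#' Tumor extinction time
#'
#' @param x an \linkS4class{OutcomeSummary}, \linkS4class{HybridRun} or
#'   \linkS4class{SurfaceRun}.
#' @return Extinction time in days, or \code{NA} if the tumor never reached
#'   zero within the simulated horizon.
#' @export
setGeneric("extinctionTime", function(x) standardGeneric("extinctionTime"))

#' Peak tumor burden
#'
#' @param x an \linkS4class{OutcomeSummary} or \linkS4class{HybridRun}.
#' @return Maximum tumor-cell count attained during the run.
#' @export
setGeneric("maxTumor", function(x) standardGeneric("maxTumor"))

#' Number of tumor relapses
#'
#' @param x an \linkS4class{OutcomeSummary} or \linkS4class{HybridRun}.
#' @return Integer count of drop-and-recover cycles of the tumor burden.
#' @export
setGeneric("nRelapses", function(x) standardGeneric("nRelapses"))

#' Effector-CTL concentration in the periphery
#'
#' Accessor for the tissue effector concentration that drives CTL
#' immigration into the agent-based tumor site.
#'
#' @param x a \linkS4class{LymphNodeState}.
#' @return Concentration in units of 1e3 cells/mm^3.
#' @export
setGeneric("effectorTissueConc", function(x) standardGeneric("effectorTissueConc"))
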