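# Lymph-node / periphery dynamics.
#
# Production path: a per-step difference system with multiplicative
# survival/stimulation factors (probabilistic analog of the delay system,
# nonnegative by construction). Validation oracle: a method-of-steps DDE
# solution of the underlying continuous system via deSolve::dede.
#
# lnStep() is the readable single-step R implementation; lnRun() drives the
# compiled stepper over a whole tumor trajectory. The two are cross-checked
# in the test suite.

#' Initialize the lymph-node state
#'
#' Pre-time-zero history is the vaccinated steady state: immature APCs at
#' their equilibrium `a0`, memory CTLs at `mEq`, and all activated pools
#' (mature APCs, effectors in node and tissue) at zero.
#'
#' @param params a \linkS4class{SimulationParams}.
#' @return A \linkS4class{LymphNodeState} at step 0.
#' @export
initLnState <- function(params) {
  cp <- .cppParams(params)
  L <- max(cp$kProg, cp$kDiv) + 1L
  new("LymphNodeState",
      A = params@a0, MA = 0, M = params@mEq, eLn = 0, eTiss = 0,
      k = 0L,
      histM = rep(params@mEq, L), histMA = rep(0, L), histELn = rep(0, L),
      kProg = cp$kProg, kDiv = cp$kDiv)
}

# ring-buffer lookup of the value at step kk (pre-zero -> pristine slots
# still hold the steady-state history)
.ringAt <- function(buf, kk) buf[(kk %% length(buf)) + 1L]

#' Advance the lymph-node difference system by one step
#'
#' One `dt` update given the current tumor burden `Tk`. Each transition is
#' a multiplicative survival/stimulation factor: immature APCs survive
#' (`exp(-deltaA dt)`) and are stimulated with probability
#' `1 - exp(-a Tk dt)`; stimulated APCs enter the node scaled by the volume
#' ratio; memory CTLs replenish logistically toward `mEq` and are activated
#' with probability `1 - exp(-b MA dt)`; activated cohorts re-enter as
#' `2^nDiv` effectors `kProg` steps later; restimulated effectors return
#' doubled `kDiv` steps later; surviving unstimulated effectors egress with
#' probability `1 - exp(-g dt)`, diluted by `1/rVol` on arrival in the
#' tissue. The update is deterministic (mean-field factors, no sampling),
#' and every concentration remains nonnegative by construction.
#'
#' The constant APC supply is integrated exactly against decay
#' (`(sA/deltaA) (1 - exp(-deltaA dt))`), so the unstimulated equilibrium
#' `a0` is an exact fixed point of the step map.
#'
#' @param state a \linkS4class{LymphNodeState}.
#' @param Tk tumor-cell count during this step (>= 0).
#' @param params the \linkS4class{SimulationParams}.
#' @return The advanced \linkS4class{LymphNodeState}.
#' @export
lnStep <- function(state, Tk, params) {
  if (!is.finite(Tk) || Tk < 0) stop("Tk must be a nonnegative tumor count")
  cp <- .cppParams(params)
  dt <- cp$dtDays
  k <- state@k

  survA <- exp(-cp$deltaA * dt)
  stimA <- -expm1(-cp$aAnt * Tk * dt)
  Anew <- (cp$sA / cp$deltaA) * -expm1(-cp$deltaA * dt) +
    survA * (1 - stimA) * state@A
  MAnew <- cp$rVol * survA * stimA * state@A + exp(-cp$deltaMA * dt) * state@MA

  pAct <- -expm1(-cp$b * state@MA * dt)
  Mnew <- state@M - pAct * state@M +
    cp$rhoM * state@M * (1 - state@M / cp$mEq) * dt

  MAp <- .ringAt(state@histMA, k - state@kProg)
  Mp  <- .ringAt(state@histM,  k - state@kProg)
  MAd <- .ringAt(state@histMA, k - state@kDiv)
  Ed  <- .ringAt(state@histELn, k - state@kDiv)
  sE <- exp(-cp$deltaE * dt)
  pG <- -expm1(-cp$g * dt)
  pActP <- -expm1(-cp$b * MAp * dt)
  pActD <- -expm1(-cp$b * MAd * dt)
  Enew <- cp$twoN * pActP * Mp +
    sE * (1 - pAct) * (1 - pG) * state@eLn +
    2 * sE * pActD * Ed
  EtissNew <- sE * state@eTiss + (1 / cp$rVol) * sE * (1 - pAct) * pG * state@eLn

  k1 <- k + 1L
  slot <- (k1 %% length(state@histM)) + 1L
  state@histM[slot] <- Mnew
  state@histMA[slot] <- MAnew
  state@histELn[slot] <- Enew
  state@A <- Anew; state@MA <- MAnew; state@M <- Mnew
  state@eLn <- Enew; state@eTiss <- EtissNew
  state@k <- k1
  state
}

#' Run the lymph-node difference system over a tumor trajectory
#'
#' Applies the per-step update once per element of `Tvec` using the
#' compiled stepper (identical arithmetic to [lnStep()]).
#'
#' @param params a \linkS4class{SimulationParams}.
#' @param Tvec tumor-cell counts, one per step; `Tvec[i]` is the burden
#'   during the i-th step.
#' @return A data.frame with columns `t_days, A, MA, M, E_ln, E_tiss`,
#'   rows at steps `0..length(Tvec)`.
#' @export
lnRun <- function(params, Tvec) {
  if (any(!is.finite(Tvec)) || any(Tvec < 0))
    stop("Tvec must be nonnegative tumor counts")
  cp <- .cppParams(params)
  m <- ln_run_cpp(cp, as.numeric(Tvec))
  df <- as.data.frame(m)
  names(df) <- c("A", "MA", "M", "E_ln", "E_tiss")
  cbind(t_days = (0:length(Tvec)) * cp$dtDays, df)
}

#' @rdname effectorTissueConc
#' @export
setMethod("effectorTissueConc", "LymphNodeState", function(x) x@eTiss)

setMethod("show", "LymphNodeState", function(object) {
  cat(sprintf(
    "LymphNodeState @ step %d (delays: program %d steps, division %d steps)\n",
    object@k, object@kProg, object@kDiv))
  cat(sprintf("  A=%.4g  MA=%.4g  M=%.4g  E_ln=%.4g  E_tiss=%.4g  (1e3 cells/mm^3)\n",
              object@A, object@MA, object@M, object@eLn, object@eTiss))
  invisible(object)
})

#' Method-of-steps DDE reference solution
#'
#' Solves the continuous delay system underlying the difference stepper —
#' the validation oracle for [lnRun()]. Right-hand side:
#' \deqn{A' = s_A - \delta_A A - a T(t) A}
#' \deqn{M_A' = r a T(t) A - \delta_{MA} M_A}
#' \deqn{M' = \rho M (1 - M/M_{eq}) - b M_A M}
#' \deqn{E' = 2^n b M_A(t-\tau_p) M(t-\tau_p) - b M_A E
#'            + 2 b M_A(t-\tau_d) E(t-\tau_d) - \delta_E E - g E}
#' \deqn{E_t' = (g/r) E - \delta_E E_t}
#' integrated with `deSolve::dede` (history = the steady state before time
#' zero), with tight tolerances, dense output sampled on the step grid.
#'
#' @param params a \linkS4class{SimulationParams}.
#' @param T_of_t function of time (days) returning the tumor burden;
#'   typically piecewise constant.
#' @param horizon days to integrate.
#' @param sampleEvery sampling interval for the returned trajectory, days
#'   (default: the difference-system step).
#' @param atol,rtol integration tolerances.
#' @return data.frame with columns `t_days, A, MA, M, E_ln, E_tiss`.
#' @export
ddeSolveReference <- function(params, T_of_t, horizon,
                              sampleEvery = params@dt / MIN_PER_DAY,
                              atol = 1e-10, rtol = 1e-10) {
  if (horizon <= 0) stop("horizon must be positive")
  stopifnot(is.function(T_of_t))
  p <- params
  twoN <- 2^p@nDiv
  y0 <- c(A = p@a0, MA = 0, M = p@mEq, E = 0, Et = 0)
  histVal <- c(p@a0, 0, p@mEq, 0, 0)
  tauP <- p@tauProg
  tauD <- p@tauDiv
  lag <- function(t, i) {
    # requests at (or within roundoff of) time zero come from the
    # steady-state pre-history
    if (t < 1e-8) histVal[i] else deSolve::lagvalue(t, i)
  }
  rhs <- function(t, y, parms) {
    Tt <- T_of_t(t)
    MAp <- lag(t - tauP, 2); Mp <- lag(t - tauP, 3)
    MAd <- lag(t - tauD, 2); Ed <- lag(t - tauD, 4)
    dA <- p@sA - p@deltaA * y[1] - p@antigenicity * Tt * y[1]
    dMA <- p@rVol * p@antigenicity * Tt * y[1] - p@deltaMA * y[2]
    dM <- p@rhoM * y[3] * (1 - y[3] / p@mEq) - p@b * y[2] * y[3]
    dE <- twoN * p@b * MAp * Mp - p@b * y[2] * y[4] +
      2 * p@b * MAd * Ed - p@deltaE * y[4] - p@g * y[4]
    dEt <- (p@g / p@rVol) * y[4] - p@deltaE * y[5]
    list(c(dA, dMA, dM, dE, dEt))
  }
  times <- seq(0, horizon, by = sampleEvery)
  # internal steps must stay below the smallest delay so that lagged
  # lookups never run ahead of the stored history
  sol <- deSolve::dede(y = y0, times = times, func = rhs, parms = NULL,
                       atol = atol, rtol = rtol,
                       hmax = min(tauD, tauP) / 2,
                       control = list(mxhist = 1e6))
  df <- as.data.frame(sol)
  names(df) <- c("t_days", "A", "MA", "M", "E_ln", "E_tiss")
  df
}
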