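# Deterministic surface-limited kill model of the tumor site, coupled to
# the lymph-node difference system. Because both growth and killing act on
# the spherical tumor's surface, the burden declines like (c (t_e - t))^3
# and reaches exactly zero at a finite extinction time.

#' Spherical tumor geometry
#'
#' Treats `T` tumor cells of radius `rCell` as a solid sphere of equal
#' total volume and derives the quantities used by the surface model:
#' volume, radius, surface area, and the maximum number of CTLs that can
#' simultaneously contact the surface (surface area over the CTL
#' cross-sectional area, i.e. `4 T^(2/3)`).
#'
#' @param T tumor-cell count (>= 0, may be fractional).
#' @param rCell cell radius, um.
#' @return Named list with `V` (um^3), `Rt` (um), `S` (um^2), `Emax`.
#' @export
tumorGeometry <- function(T, rCell) {
  if (any(T < 0)) stop("T must be nonnegative")
  V <- (4 / 3) * pi * rCell^3 * T
  Rt <- rCell * T^(1 / 3)
  S <- 4 * pi * Rt^2
  list(V = V, Rt = Rt, S = S, Emax = S / (pi * rCell^2))
}

#' Right-hand side of the surface-kill ODE
#'
#' \deqn{dT/dt = \kappa_g \, 4 T^{2/3} / d_{tum} - \min(E_s, E_{max}) / d_{kill}}
#' \deqn{dE_s/dt = \kappa_{in} (E_{tiss} 10^3 V_{shell})(1 - E_s/E_{max})
#'   - \delta_E E_s + (E_s / d_{recr})(1 - E_s/E_{max})}
#' Growth and killing are both proportional to the number of cell-sized
#' sites on the tumor surface (`4 T^(2/3)`) — contact-limited, not
#' mass-action. CTL arrival from the periphery fills a contact shell of
#' thickness `2 rCell` around the tumor surface, throttled to zero as the
#' local population `E_s` approaches the surface capacity `E_max`;
#' engaged-CTL recruitment is throttled the same way.
#'
#' @param state numeric `c(T, Es)`.
#' @param eTiss peripheral effector concentration, 1e3 cells/mm^3.
#' @param params a \linkS4class{SimulationParams}.
#' @return Numeric `c(dT, dEs)` in units per day.
#' @export
odeRhs <- function(state, eTiss, params) {
  if (length(state) != 2 || any(!is.finite(state)) || any(state < 0))
    stop("state must be nonnegative finite c(T, Es)")
  T <- state[1]; Es <- state[2]
  geo <- tumorGeometry(T, params@rCell)
  Vshell <- (4 * pi / 3) *
    ((geo$Rt + 2 * params@rCell)^3 - geo$Rt^3) * 1e-9 # mm^3
  dens <- if (geo$Emax > 0) 1 - Es / geo$Emax else 0
  kill <- if (geo$Emax > 0) min(Es, geo$Emax) / (params@dKill / 24) else 0
  dT <- params@kappaG * 4 * T^(2 / 3) / params@dTum - kill
  if (T <= 0 && dT < 0) dT <- 0
  dEs <- params@kappaIn * (eTiss * 1e3 * Vshell) * dens -
    params@deltaE * Es + (Es / (params@dRecr / 24)) * dens
  c(dT = dT, dEs = unname(dEs))
}

#' Run the coupled surface-kill model
#'
#' Integrates the deterministic tumor-site ODE (RK4 at the simulation
#' step) coupled synchronously to the lymph-node difference system, from
#' one tumor cell at time zero. The zero crossing of the tumor burden is
#' located by interpolation inside the step and the burden is clamped to
#' exactly zero thereafter (the tumor-free state is absorbing).
#'
#' @param params a \linkS4class{SimulationParams}.
#' @param horizon days to integrate.
#' @param thinMinutes recording interval, minutes.
#' @return A \linkS4class{SurfaceRun}.
#' @examples
#' \donttest{
#' run <- runOdeModel(simParams(antigenicity = 1e-6), horizon = 60)
#' extinctionTime(run)
#' }
#' @export
runOdeModel <- function(params, horizon, thinMinutes = 10) {
  stopifnot(is(params, "SimulationParams"))
  if (horizon <= 0) stop("horizon must be positive")
  cp <- .cppParams(params)
  sp <- list(kappaG = params@kappaG, kappaIn = params@kappaIn,
             dTumDays = params@dTum, dKillDays = params@dKill / 24,
             dRecrDays = params@dRecr / 24)
  maxSteps <- ceiling(horizon * MIN_PER_DAY / params@dt)
  res <- run_surface_cpp(cp, sp, maxSteps,
                         max(1L, round(thinMinutes / params@dt)))
  df <- as.data.frame(res$series)
  names(df) <- c("t_days", "T", "E_s", "E_tiss")
  ext <- if (res$extinctionTime >= 0) res$extinctionTime else NA_real_
  new("SurfaceRun", series = df, extinctionTime = ext, params = params)
}

#' @rdname timeSeries
#' @export
setMethod("timeSeries", "SurfaceRun", function(x) x@series)

#' @rdname extinctionTime
#' @export
setMethod("extinctionTime", "SurfaceRun", function(x) x@extinctionTime)

setMethod("show", "SurfaceRun", function(object) {
  cat(sprintf("SurfaceRun: %d recorded steps, peak burden %.4g\n",
              nrow(object@series), max(object@series$T)))
  cat(sprintf("  extinction: %s\n",
              if (is.na(object@extinctionTime)) "none within horizon"
              else sprintf("day %.3f", object@extinctionTime)))
  invisible(object)
})
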