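# Outcome summarization, cube-root decline regression, relapse counting and
# the one-at-a-time Spearman sensitivity harness.

#' Summarize a simulation time series
#'
#' Computes the endpoints used throughout the analyses: time to tumor
#' extinction (first time the burden is zero; `NA` if never), the peak
#' burden and its time, the number of relapses, and the immune-failure flag
#' of the stopping rule (the tumor must be eliminated below
#' `failureThresholdCells` and within `failureHorizonDays`).
#'
#' A relapse is a completed drop-and-recover cycle of the tumor burden:
#' after smoothing with a moving median of width `smoothDays`, the series
#' falls below `dropFrac` of its running peak and later rises back above
#' that level. Peaks below `minPeak` cells are ignored (formalizes the
#' visual "peaks and declines" count; thresholds configurable).
#'
#' @param ts data.frame with columns `t_days` and `tumor_count`.
#' @param stop a \linkS4class{StopRule}.
#' @param exact optional list with elements `extinctionTime`, `maxTumor`,
#'   `tMaxTumor` tracked at full step resolution by the driver; when
#'   supplied they override the (possibly thinned) series.
#' @param dropFrac relapse drop threshold (fraction of the running peak).
#' @param smoothDays moving-median window, days.
#' @param minPeak smallest peak burden eligible for relapse counting.
#' @return An \linkS4class{OutcomeSummary}.
#' @export
summarizeRun <- function(ts, stop = stopRule(), exact = NULL,
                         dropFrac = 0.5, smoothDays = 1, minPeak = 10) {
  if (!is.data.frame(ts) || !nrow(ts))
    stop("ts must be a nonempty data.frame")
  stopifnot(all(c("t_days", "tumor_count") %in% names(ts)))
  ext <- exact$extinctionTime
  if (is.null(ext)) {
    z <- which(ts$tumor_count == 0)
    ext <- if (length(z)) ts$t_days[z[1]] else NA_real_
  }
  if (is.null(exact$maxTumor)) {
    mx <- max(ts$tumor_count)
    tmx <- ts$t_days[which.max(ts$tumor_count)]
  } else {
    mx <- exact$maxTumor
    tmx <- exact$tMaxTumor
  }
  n <- .countRelapses(ts$t_days, ts$tumor_count, dropFrac, smoothDays, minPeak)
  failed <- is.na(ext) || ext >= stop@failureHorizonDays ||
    mx >= stop@failureThresholdCells
  new("OutcomeSummary", extinctionTime = ext, maxTumor = as.numeric(mx),
      tMaxTumor = as.numeric(tmx), nRelapses = n, failed = failed)
}

.countRelapses <- function(t, y, dropFrac = 0.5, smoothDays = 1, minPeak = 10) {
  if (length(y) < 3) return(0L)
  dtMed <- stats::median(diff(t))
  if (!is.finite(dtMed) || dtMed <= 0) return(0L)
  k <- max(1L, round(smoothDays / dtMed))
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (length(y) %% 2L == 1L) length(y) else length(y) - 1L)
  ys <- if (k >= 3) stats::runmed(y, k) else y
  peak <- ys[1]
  dropped <- FALSE
  n <- 0L
  for (v in ys) {
    if (!dropped) {
      if (v > peak) peak <- v
      if (peak >= minPeak && v < dropFrac * peak) dropped <- TRUE
    } else if (v > dropFrac * peak) {
      n <- n + 1L
      peak <- v
      dropped <- FALSE
    }
  }
  n
}

#' Cube-root decline regression
#'
#' During the final decline the tumor burden follows `N(t) = (c (t_e - t))^3`
#' rather than an exponential: surface-limited killing makes the cube root
#' of the burden decay linearly and hit zero at a finite extinction time.
#' This fits `tumor_count^(1/3)` against time by ordinary least squares on
#' a window and reports the fit correlation and the root of the fitted
#' line as the predicted extinction day.
#'
#' @param ts data.frame with columns `t_days` and `tumor_count`.
#' @param window length-2 numeric, time window (days, inclusive).
#' @return List with `slope`, `intercept`, `r` (signed Pearson correlation
#'   of cube-root burden with time), and `predictedExtinction` (days; `NA`
#'   if the fitted slope is nonnegative).
#' @export
cubeRootFit <- function(ts, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  if (!"tumor_count" %in% names(ts) && "T" %in% names(ts))
    ts$tumor_count <- ts$T # surface-model series
  sel <- ts$t_days >= window[1] & ts$t_days <= window[2]
  t <- ts$t_days[sel]
  y <- ts$tumor_count[sel]
  if (length(t) < 3) stop("cube-root fit needs at least 3 points in the window")
  interior <- seq_along(y)[-c(1L, length(y))]
  if (any(y[interior] <= 0))
    stop("tumor count must be positive on the window interior")
  cr <- y^(1 / 3)
  fit <- stats::lm.fit(cbind(1, t), cr)
  slope <- fit$coefficients[2]
  intercept <- fit$coefficients[1]
  r <- stats::cor(t, cr)
  pe <- if (is.finite(slope) && slope < 0) -intercept / slope else NA_real_
  list(slope = unname(slope), intercept = unname(intercept),
       r = unname(r), predictedExtinction = unname(pe))
}

# all permutations of 1..n (n small), one per row
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Rank correlation with average ranks for ties. The p-value is two-sided:
#' for n <= 9 it is exact, from the full permutation distribution of the
#' statistic; for larger n it uses the t approximation
#' `t = rho sqrt((n-2)/(1-rho^2))` on n-2 degrees of freedom.
#'
#' @param x,y equal-length numeric vectors (length >= 3).
#' @return Named list with `rho` and `p`.
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_))
  rho <- stats::cor(rx, ry)
  if (n <= 9) {
    perms <- .permutations(n)
    sums <- as.vector(matrix(ry[perms], nrow(perms), n) %*% rx)
    rhoAll <- (sums - n * mean(rx) * mean(ry)) /
      ((n - 1) * stats::sd(rx) * stats::sd(ry))
    p <- mean(abs(rhoAll) >= abs(rho) - 1e-12)
  } else {
    r2 <- min(rho^2, 1)
    if (r2 >= 1) {
      p <- 0
    } else {
      tt <- rho * sqrt((n - 2) / (1 - r2))
      p <- 2 * stats::pt(-abs(tt), df = n - 2)
    }
  }
  list(rho = rho, p = p)
}

#' One-at-a-time sensitivity sweep
#'
#' Varies a single parameter over a grid while holding all others at their
#' base values, runs seeded replicates of the hybrid simulation at each
#' value, and reports Spearman rank correlations of the parameter against
#' time to tumor extinction and against log10 of the maximum tumor burden.
#'
#' Runs that reach the horizon without extinction enter the correlation at
#' the censoring time (conservative; set `censorMode = "drop"` to exclude
#' them instead). Quantities derived from the swept parameter (supply
#' rate, division-program duration, annulus width, equilibrium memory
#' concentration) are re-derived at every grid value.
#'
#' @param param name of the parameter to sweep (a
#'   \linkS4class{SimulationParams} field).
#' @param grid numeric vector of values.
#' @param params base parameter set.
#' @param stop a \linkS4class{StopRule}.
#' @param reps replicates per grid value.
#' @param seed0 base seed; run (value j, rep i) uses
#'   `seed0 + (j-1) reps + (i-1)`.
#' @param censorMode `"censor"` (default) or `"drop"` for horizon-reaching
#'   runs.
#' @param thinMinutes recording interval, minutes.
#' @return A \linkS4class{SensitivityResult}.
#' @export
runSweep <- function(param, grid, params = baseParams(), stop = stopRule(),
                     reps = 5, seed0 = params@seed,
                     censorMode = c("censor", "drop"), thinMinutes = 10) {
  censorMode <- match.arg(censorMode)
  stopifnot(length(grid) >= 1, reps >= 1)
  base <- paramsAsList(params)
  if (!param %in% names(base)) stop("unknown parameter: ", param)
  # let quantities depending on the swept value re-derive
  base[c("sA", "mEq", "wCloud", "tauProg")] <- NA_real_
  rows <- list()
  for (j in seq_along(grid)) {
    raw <- base
    raw[[param]] <- grid[j]
    pj <- validateParams(raw)
    for (i in seq_len(reps)) {
      sd <- as.integer(seed0 + (j - 1L) * reps + (i - 1L))
      o <- outcome(runHybrid(pj, stop, seed = sd, thinMinutes = thinMinutes))
      rows[[length(rows) + 1L]] <- data.frame(
        value = grid[j], rep = i, seed = sd,
        extinction_time = if (is.na(o@extinctionTime)) stop@maxDays
                          else o@extinctionTime,
        censored = is.na(o@extinctionTime),
        max_tumor = o@maxTumor, n_relapses = o@nRelapses, failed = o@failed)
    }
  }
  outc <- do.call(rbind, rows)
  use <- if (censorMode == "drop") !outc$censored else rep(TRUE, nrow(outc))
  rho <- data.frame(endpoint = c("extinction_time", "log10_max_tumor"),
                    rho = NA_real_, p = NA_real_)
  if (length(unique(grid)) >= 2 && sum(use) >= 3) {
    s1 <- spearmanRho(outc$value[use], outc$extinction_time[use])
    s2 <- spearmanRho(outc$value[use], log10(outc$max_tumor[use]))
    rho$rho <- c(s1$rho, s2$rho)
    rho$p <- c(s1$p, s2$p)
  }
  new("SensitivityResult", param = param, grid = as.numeric(grid),
      outcomes = outc, rho = rho, reps = as.integer(reps),
      seed0 = as.integer(seed0))
}

setMethod("show", "SensitivityResult", function(object) {
  cat(sprintf("SensitivityResult: %s over %d values x %d reps\n",
              object@param, length(object@grid), object@reps))
  print(object@rho, row.names = FALSE)
  invisible(object)
})
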