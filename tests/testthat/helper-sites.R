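# Helpers to build small, fully specified tumor-site scenarios in code.

# a site with explicit agents (no RNG); positions are row-wise 3-vectors
makeSite <- function(tumor = NULL, ctl = NULL, ctlTstop = NULL) {
  nT <- if (is.null(tumor)) 0L else nrow(tumor)
  nC <- if (is.null(ctl)) 0L else nrow(ctl)
  if (is.null(ctlTstop)) ctlTstop <- rep(Inf, nC)
  new("TumorSite",
      tumorPos = if (nT) tumor else matrix(0, 0, 3),
      tumorId = seq_len(nT),
      ctlPos = if (nC) ctl else matrix(0, 0, 3),
      ctlTstop = as.numeric(ctlTstop),
      ctlTarget = rep(NA_integer_, nC),
      ctlId = seq_len(nC),
      step = 0L, nextTumorId = nT + 1L, nextCtlId = nC + 1L)
}

# lattice of well-separated CTL positions inside a ball of radius rmax
ctlLattice <- function(spacing, rmax) {
  g <- seq(-rmax, rmax, by = spacing)
  pts <- as.matrix(expand.grid(g, g, g))
  pts[sqrt(rowSums(pts^2)) <= rmax, , drop = FALSE]
}

# brute-force minimum centre-centre distance between all agents
minPairDist <- function(site) {
  pos <- rbind(site@tumorPos, site@ctlPos)
  if (nrow(pos) < 2) return(Inf)
  min(stats::dist(pos))
}

# the 12 icosahedron vertex directions (unit vectors): a fully caged cell
icosahedronDirs <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
    c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
    c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1))
  v / sqrt(rowSums(v^2))
}

# representative base-run tumor trajectory: exponential growth from one
# cell at rate 1/dTum, eliminated at killDay, zero afterwards
repTumorTrajectory <- function(params, horizonDays, killDay) {
  n <- horizonDays * 1440 / params@dt
  tt <- (seq_len(n) - 1) * params@dt / 1440
  ifelse(tt < killDay, exp(tt / params@dTum), 0)
}
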