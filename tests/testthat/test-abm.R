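# Agent-based tumor site: motion, collision, engagement, division,
# recruitment/killing, death, immigration, boundary, reproducibility.

test_that("the site starts from a single tumor cell at the origin", {
  p <- baseParams()
  s <- initSite(p)
  expect_equal(tumorCount(s), 1L)
  expect_equal(ctlCount(s), 0L)
  expect_equal(as.numeric(s@tumorPos), c(0, 0, 0))
  set.seed(11); a <- abmStep(s, 0.2, p)
  set.seed(11); b <- abmStep(s, 0.2, p)
  expect_identical(a, b) # same seed, bit-identical states
})

test_that("CTL acceleration ramps sigma linearly up to the maximum", {
  p <- baseParams() # tAccel = 5 h
  expect_equal(ctlSigma(0, p), 0)
  expect_equal(ctlSigma(150, p), p@sigmaMax / 2)
  expect_equal(ctlSigma(300, p), p@sigmaMax)
  expect_equal(ctlSigma(1e5, p), p@sigmaMax)
  expect_equal(ctlSigma(Inf, p), p@sigmaMax)
})

test_that("free-space Wiener displacement has the closed-form variance", {
  p <- baseParams()
  set.seed(101)
  disp <- c()
  for (rep in 1:60) {
    pos <- ctlLattice(100, 420)
    s <- makeSite(ctl = pos) # all at full speed
    s2 <- moveCtls(s, p)
    disp <- c(disp, as.numeric(s2@ctlPos - pos))
  }
  expect_gt(length(disp), 5e4)
  target <- p@sigmaMax^2 * p@dt
  expect_lt(abs(var(disp) - target) / target, 0.02)
  expect_lt(abs(mean(disp)), 0.2) # centered
})

test_that("a CTL stopped at rest does not move", {
  p <- baseParams()
  s <- makeSite(ctl = rbind(c(0, 0, 0)), ctlTstop = 0) # sigma(0) = 0
  set.seed(5)
  s2 <- moveCtls(s, p)
  expect_identical(s2@ctlPos, s@ctlPos)
  expect_equal(s2@ctlTstop, p@dt) # time since stop accrues
})

test_that("motion stops exactly at first contact (segment-sphere oracle)", {
  # replay the same normal draws in R and solve the segment-sphere
  # intersection independently
  p <- simParams(sigmaMax = 40) # long steps provoke frequent contacts
  tumor <- rbind(c(18, 0, 0))
  contacts <- 0
  for (sd in 1:150) {
    s <- makeSite(tumor = tumor, ctl = rbind(c(0, 0, 0)))
    set.seed(sd)
    s2 <- moveCtls(s, p)
    set.seed(sd)
    d <- rnorm(3) * p@sigmaMax * sqrt(p@dt)
    # independent first-contact solve: |p0 + t d - q|^2 = (2 r)^2
    q <- tumor[1, ]; D <- 2 * p@rCell
    qa <- sum(d^2); qb <- sum(d * (-q)); qc <- sum(q^2) - D^2
    disc <- qb^2 - qa * qc
    tstar <- 1
    if (disc > 0 && qb < 0) {
      t0 <- (-qb - sqrt(disc)) / qa
      if (t0 >= 0 && t0 < 1) tstar <- t0
    }
    expect_equal(as.numeric(s2@ctlPos), tstar * d, tolerance = 1e-12)
    if (tstar < 1) {
      contacts <- contacts + 1
      expect_equal(sqrt(sum((s2@ctlPos[1, ] - q)^2)), D, tolerance = 1e-9)
    }
  }
  expect_gt(contacts, 5) # the scenario actually exercised collisions
})

test_that("engagement picks the nearest tumor cell, ties to the lowest id", {
  p <- baseParams()
  # exactly at contact distance -> engaged (inclusive boundary)
  s <- makeSite(tumor = rbind(c(10, 0, 0)), ctl = rbind(c(0, 0, 0)))
  s2 <- updateEngagements(s, p)
  expect_equal(s2@ctlTarget, 1L)
  expect_equal(s2@ctlTstop, 0) # engaging resets the acceleration clock
  # no tumor cells -> no engagement
  s3 <- updateEngagements(makeSite(ctl = rbind(c(0, 0, 0))), p)
  expect_true(is.na(s3@ctlTarget))
  # equidistant between two -> lowest id
  s4 <- makeSite(tumor = rbind(c(10, 0, 0), c(-10, 0, 0)),
                 ctl = rbind(c(0, 0, 0)))
  s5 <- updateEngagements(s4, p)
  expect_equal(s5@ctlTarget, 1L)
  # nearer cell wins regardless of id order
  s6 <- makeSite(tumor = rbind(c(10.004, 0, 0), c(-10, 0, 0)),
                 ctl = rbind(c(0, 0, 0)))
  s7 <- updateEngagements(s6, p)
  expect_equal(s7@ctlTarget, 2L)
  # out of reach -> stays moving
  s8 <- updateEngagements(makeSite(tumor = rbind(c(10.5, 0, 0)),
                                   ctl = rbind(c(0, 0, 0))), p)
  expect_true(is.na(s8@ctlTarget))
})

test_that("division creates a tangent daughter or fails when caged", {
  p <- baseParams()
  set.seed(21)
  # isolated cell, forced division -> daughter at exactly 2 rCell
  s <- attemptTumorDivisions(makeSite(tumor = rbind(c(0, 0, 0))), p, prob = 1)
  expect_equal(tumorCount(s), 2L)
  expect_equal(sqrt(sum((s@tumorPos[2, ] - s@tumorPos[1, ])^2)),
               2 * p@rCell, tolerance = 1e-9)
  # cell caged by 12 tangent neighbors can never place a daughter
  cage <- rbind(c(0, 0, 0), 2 * p@rCell * icosahedronDirs())
  s2 <- makeSite(tumor = cage)
  for (sd in 1:5) {
    set.seed(sd)
    s3 <- attemptTumorDivisions(s2, p, prob = 1)
    expect_equal(tumorCount(s3), 13L + 12L) # only the 12 outer cells divide
    expect_gt(minPairDist(s3), 2 * p@rCell - 1e-6)
  }
  # daughters appear only next step: a single forced division yields +1
  set.seed(3)
  s4 <- attemptTumorDivisions(makeSite(tumor = rbind(c(0, 0, 0))), p, prob = 1)
  expect_equal(tumorCount(s4), 2L)
})

test_that("tumor cells never breach the region of interest", {
  p <- baseParams()
  edge <- c(p@rRoi - p@rCell - 1, 0, 0)
  s <- makeSite(tumor = rbind(edge))
  set.seed(9)
  for (i in 1:40) s <- attemptTumorDivisions(s, p, prob = 1)
  r <- sqrt(rowSums(s@tumorPos^2))
  expect_true(all(r + p@rCell <= p@rRoi + 1e-9))
  expect_gt(minPairDist(s), 2 * p@rCell - 1e-6)
})

test_that("CTL-free growth matches the per-cell division hazard", {
  p <- baseParams()
  finals <- sapply(1:50, function(sd) {
    r <- runAbm(p, maxDays = 10, eTiss = 0, seed = sd, thinMinutes = 1440)
    ts <- r$series
    expect_true(all(diff(ts$tumor_count) >= 0)) # no CTLs: nondecreasing
    tail(ts$tumor_count, 1)
  })
  # branching-process oracle: E[N] = (1 + p)^steps, pre-crowding
  pstep <- perStepProb(p@dTum * 1440, p@dt)
  expected <- (1 + pstep)^(10 * 1440)
  sem <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - expected), 4 * sem + 0.01)
})

test_that("kills disengage every attacker and recruitment is tangent", {
  p <- baseParams()
  tumor <- rbind(c(0, 0, 0))
  d <- 2 * p@rCell
  ctl <- rbind(c(d, 0, 0), c(-d, 0, 0), c(0, d, 0))
  s <- updateEngagements(makeSite(tumor = tumor, ctl = ctl), p)
  expect_equal(sum(!is.na(s@ctlTarget)), 3L)
  # forced kill, no recruitment: tumor removed, all three resume moving
  set.seed(2)
  s2 <- attemptRecruitAndKill(s, p, pRecr = 0, pKill = 1)
  expect_equal(tumorCount(s2), 0L)
  expect_true(all(is.na(s2@ctlTarget)))
  expect_true(all(s2@ctlTstop == 0)) # re-accelerate from rest
  # forced recruitment, no kill: one tangent recruit per engaged CTL
  set.seed(2)
  s3 <- attemptRecruitAndKill(s, p, pRecr = 1, pKill = 0)
  expect_equal(tumorCount(s3), 1L)
  expect_equal(ctlCount(s3), 6L)
  newIdx <- which(s3@ctlId > 3)
  for (i in newIdx) {
    dists <- sqrt(colSums((t(s3@ctlPos[-i, , drop = FALSE]) - s3@ctlPos[i, ])^2))
    expect_gt(min(dists), 2 * p@rCell - 1e-6)
    expect_equal(s3@ctlTstop[i], 0) # recruits start from rest
  }
  expect_gt(minPairDist(s3), 2 * p@rCell - 1e-6)
})

test_that("engaged-CTL actions fire at the expected per-step rate", {
  p <- baseParams()
  # 1,000 engaged CTLs, each on its own tumor cell, forced probability
  # equal to the 8-h recruitment hazard; repeat to sharpen the estimate
  n <- 1000
  centers <- ctlLattice(40, 300)[seq_len(n), ]
  tumor <- centers
  ctl <- centers + matrix(rep(c(2 * p@rCell, 0, 0), each = n), n, 3)
  s <- updateEngagements(makeSite(tumor = tumor, ctl = ctl), p)
  expect_equal(sum(!is.na(s@ctlTarget)), n)
  pr <- perStepProb(p@dRecr * 60, p@dt)
  set.seed(33)
  recruits <- sapply(1:100, function(i) {
    ctlCount(attemptRecruitAndKill(s, p, pRecr = pr, pKill = 0)) - n
  })
  lam <- n * 100 * pr # total expected recruits
  expect_lt(abs(sum(recruits) - lam), 4 * sqrt(lam))
})

test_that("CTL death is binomial at the lifespan hazard", {
  p <- baseParams()
  n <- 4000
  s <- makeSite(ctl = ctlLattice(25, 250)[seq_len(n), ])
  pd <- perStepProb(p@dLife * 60, p@dt)
  set.seed(44)
  dead <- sapply(1:50, function(i) n - ctlCount(applyCtlDeath(s, p, prob = pd)))
  lam <- 50 * n * pd
  expect_lt(abs(sum(dead) - lam), 4 * sqrt(lam))
  # dt = 0 -> no deaths
  expect_equal(ctlCount(applyCtlDeath(s, p, prob = 0)), n)
  # an engaged CTL dying leaves the tumor cell and co-attackers intact
  s2 <- updateEngagements(
    makeSite(tumor = rbind(c(0, 0, 0)),
             ctl = rbind(c(10, 0, 0), c(-10, 0, 0))), p)
  set.seed(1)
  s3 <- applyCtlDeath(s2, p, prob = 1)
  expect_equal(tumorCount(s3), 1L)
  expect_equal(ctlCount(s3), 0L)
})

test_that("cloud immigration is Poisson in the annulus and culled outside", {
  p <- baseParams()
  eT <- 0.5
  lamStep <- eT * 1e3 * (4 * pi / 3) *
    ((p@rRoi + p@wCloud)^3 - p@rRoi^3) * 1e-9
  set.seed(55)
  counts <- sapply(1:300, function(i) ctlCount(spawnCloud(makeSite(), eT, p)))
  expect_lt(abs(mean(counts) - lamStep), 4 * sqrt(lamStep / 300))
  # all spawns lie in the annulus, at full speed, non-overlapping
  set.seed(56)
  s <- spawnCloud(makeSite(), 2, p)
  r <- sqrt(rowSums(s@ctlPos^2))
  expect_true(all(r >= p@rRoi & r <= p@rRoi + p@wCloud))
  expect_true(all(is.infinite(s@ctlTstop)))
  expect_gt(minPairDist(s), 2 * p@rCell - 1e-6)
  # cull removes everything outside the region of interest
  s2 <- cullBeyondRoi(s, p)
  expect_equal(ctlCount(s2), 0L)
  expect_equal(ctlCount(spawnCloud(makeSite(), 0, p)), 0L) # no source
  expect_error(spawnCloud(makeSite(), -1, p), ">= 0")
})

test_that("a full step keeps every invariant and absorbs the tumor-free state", {
  p <- baseParams()
  # empty site stays empty
  set.seed(3)
  s0 <- abmStep(makeSite(), 0, p)
  expect_equal(tumorCount(s0) + ctlCount(s0), 0L)
  # stepped site: non-overlap, confinement, culling
  s <- initSite(p)
  set.seed(77)
  for (i in 1:150) s <- abmStep(s, 0.3, p)
  expect_gt(minPairDist(s), 2 * p@rCell - 1e-6)
  expect_true(all(sqrt(rowSums(s@tumorPos^2)) + p@rCell <= p@rRoi + 1e-9))
  expect_true(all(sqrt(rowSums(s@ctlPos^2)) <= p@rRoi + 1e-9))
  expect_equal(s@step, 150L)
  # engineered kill of the last tumor cell -> absorbing tumor-free state
  s1 <- updateEngagements(
    makeSite(tumor = rbind(c(0, 0, 0)), ctl = rbind(c(10, 0, 0))), p)
  set.seed(8)
  s2 <- attemptRecruitAndKill(s1, p, pRecr = 0, pKill = 1)
  expect_equal(tumorCount(s2), 0L)
  for (i in 1:20) s2 <- abmStep(s2, 0, p)
  expect_equal(tumorCount(s2), 0L)
})

test_that("grid neighbor search agrees with brute force", {
  set.seed(99)
  for (rep in 1:5) {
    n <- sample(50:500, 1)
    pos <- matrix(runif(3 * n, -300, 300), n, 3)
    radius <- runif(1, 5, 40)
    got <- tumorCTL:::neighbor_pairs_cpp(pos, radius)
    got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
    dm <- as.matrix(dist(pos))
    want <- which(upper.tri(dm) & dm <= radius, arr.ind = TRUE)
    want <- cbind(pmin(want[, 1], want[, 2]), pmax(want[, 1], want[, 2]))
    want <- want[order(want[, 1], want[, 2]), , drop = FALSE]
    expect_equal(unname(got), unname(want))
  }
})
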