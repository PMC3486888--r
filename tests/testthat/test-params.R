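# Parameter validation and the derived quantities.

test_that("division-program duration follows the first-division-is-a-day rule", {
  expect_equal(deriveTauProg(10, 1), 10)
  expect_equal(deriveTauProg(10, 1 / 6), 2.5)
  expect_equal(deriveTauProg(1, 0.25), 1) # single division takes the 24-h lag
  expect_error(deriveTauProg(0, 1), "nDiv")
  expect_error(deriveTauProg(10, 0), "tauDiv")
  # both printed endpoints of the tauDiv range at n = 10
  expect_equal(deriveTauProg(10, 1 / 6), 2.5)
  expect_equal(deriveTauProg(10, 1), 10)
  # monotone in both arguments over the printed range
  taus <- seq(1 / 6, 1, length.out = 9)
  expect_true(all(diff(sapply(taus, function(tv) deriveTauProg(10, tv))) > 0))
})

test_that("supply rate balances immature-APC turnover exactly", {
  expect_equal(deriveSupplyRate(0.03, 7), 0.21)
  expect_equal(deriveSupplyRate(0, 7), 0)
  # fixed point: stepping the A-equation with no tumor stays at A0
  p <- baseParams()
  tr <- lnRun(p, rep(0, 1000))
  expect_equal(max(abs(tr$A - p@a0)), 0)
})

test_that("cloud width gives the target one-step crossing probability", {
  p <- 0.001
  w <- deriveCloudWidth(10, 1, p)
  expect_equal(w, qnorm(0.999) * 10, tolerance = 1e-12)
  expect_equal(w / 10, 3.0902, tolerance = 1e-4)
  # normal-tail round trip
  expect_equal(1 - pnorm(w / (10 * sqrt(1))), p, tolerance = 1e-12)
  # monotone decreasing in pCross, and -> 0 as pCross -> 1/2
  ps <- c(0.001, 0.01, 0.1, 0.3, 0.49999)
  ws <- sapply(ps, function(q) deriveCloudWidth(10, 1, q))
  expect_true(all(diff(ws) < 0))
  expect_lt(ws[length(ws)], 1e-3)
  expect_error(deriveCloudWidth(10, 1, 0.7), "pCross")
  expect_error(deriveCloudWidth(10, 1, 0), "pCross")
})

test_that("lymph-node concentrations follow the slice arithmetic", {
  cc <- deriveLnConcentrations(1600, 100, 1, 1 / 500)
  vol <- (1 / 500) * (4 / 3) * pi # mm^3
  expect_equal(unname(cc["cCtl"]), 1600 / vol / 1e3)
  expect_equal(unname(cc["cCtl"]), 191, tolerance = 0.005)
  expect_equal(unname(cc["cDc"]), 11.9, tolerance = 0.005)
  expect_equal(unname(deriveLnConcentrations(0, 0, 1, 1 / 500)), c(0, 0))
  # doubling the node radius at fixed counts divides concentrations by 8
  cc2 <- deriveLnConcentrations(1600, 100, 2, 1 / 500)
  expect_equal(unname(cc2 / cc), c(1 / 8, 1 / 8))
})

test_that("per-step probabilities are hazard-consistent", {
  expect_equal(perStepProb(480, 0), 0)
  expect_equal(perStepProb(480, 1), 1 - exp(-1 / 480))
  expect_equal(perStepProb(480, 1), 2.081e-3, tolerance = 1e-3)
  # monotone increasing in dt, decreasing in mean time
  expect_true(all(diff(perStepProb(480, 1:10)) > 0))
  expect_true(all(diff(perStepProb(c(60, 480, 2460), 1)) < 0))
  expect_error(perStepProb(0, 1), "positive")
  # Monte-Carlo: mean geometric waiting time at p = perStepProb(480, 1)
  set.seed(42)
  p <- perStepProb(480, 1)
  waits <- rgeom(1e5, p) + 1 # steps until the event fires
  se <- sqrt((1 - p) / p^2 / 1e5)
  expect_lt(abs(mean(waits) - 1 / p), 5 * se)
})

test_that("validateParams accepts the base configuration and derives fields", {
  p <- validateParams(list(dt = 1, dTum = 7, tAccel = 5, dLife = 41,
                           dRecr = 8, dKill = 24, rVol = 1000, nDiv = 10,
                           tauDiv = 1 / 3, mFrac = 0.02))
  expect_s4_class(p, "SimulationParams")
  expect_equal(p@tauProg, 4)             # 1 + 9/3 days
  expect_equal(p@sA, p@deltaA * p@a0)
  expect_equal(p@mEq, 0.02 * p@cCtl)
  expect_equal(p@wCloud, qnorm(0.999) * p@sigmaMax * sqrt(p@dt))
})

test_that("invalid parameters are rejected with informative errors", {
  expect_error(simParams(dt = 0), "dt")
  expect_error(simParams(dTum = -1), "dTum")
  expect_error(simParams(mFrac = 0), "mFrac")
  expect_error(simParams(pCross = 0.6), "pCross")
  expect_error(simParams(bogus = 1), "unknown parameter")
  # non-integer delay/step ratio suggests the nearest valid value
  expect_error(validateParams(list(dt = 2, tauDiv = 7 / 1440)),
               "nearest valid")
  # region of interest too small for a 50,000-cell tumor
  expect_error(simParams(rRoi = 100), "50,000")
})

test_that("parameters round-trip through serialization", {
  p <- simParams(dTum = 3, mFrac = 0.05, antigenicity = 1e-6, nDiv = 12L)
  p2 <- validateParams(paramsAsList(p))
  for (nm in slotNames(p)) expect_identical(slot(p, nm), slot(p2, nm))
})
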