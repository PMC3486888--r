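# Outcome summaries, relapse counting, cube-root regression, Spearman.

test_that("summaries capture extinction, peak and failure", {
  st <- stopRule(maxDays = 100, failureThresholdCells = 1e4,
                 failureHorizonDays = 730)
  t <- seq(0, 50, by = 0.1)
  y <- pmax(0, round(1000 - 25 * t))
  ts <- data.frame(t_days = t, tumor_count = y)
  o <- summarizeRun(ts, st)
  expect_equal(o@nRelapses, 0L) # monotone to zero
  expect_equal(o@extinctionTime, t[which(y == 0)[1]])
  expect_equal(o@maxTumor, 1000)
  expect_false(o@failed)
  # a series that never reaches zero is censored and failed
  ts2 <- data.frame(t_days = t, tumor_count = y + 5)
  o2 <- summarizeRun(ts2, st)
  expect_true(is.na(o2@extinctionTime))
  expect_true(o2@failed)
  # exceeding the burden criterion also fails
  o3 <- summarizeRun(data.frame(t_days = t, tumor_count = pmax(0, 2e4 - 500 * t)),
                     st)
  expect_true(o3@failed)
})

test_that("relapse counting matches a constructed sawtooth", {
  # 12 drop-and-recover cycles: each peak (100) falls below 50% (to 30)
  # and recovers
  seg <- function(a, b) seq(a, b, length.out = 40)
  y <- c(unlist(lapply(1:12, function(i) c(seg(30, 100), seg(100, 30)))),
         seg(30, 100))
  t <- seq_along(y) * 0.1
  o <- summarizeRun(data.frame(t_days = t, tumor_count = y), stopRule())
  expect_equal(o@nRelapses, 12L)
  # small-amplitude flicker below minPeak is not counted
  y2 <- c(seg(1, 6), seg(6, 2), seg(2, 6), seg(6, 0))
  o2 <- summarizeRun(data.frame(t_days = seq_along(y2) * 0.1, tumor_count = y2),
                     stopRule())
  expect_equal(o2@nRelapses, 0L)
})

test_that("cube-root regression is exact on a cubic and flags misuse", {
  te <- 40
  t <- seq(10, 39.9, by = 0.05)
  cubic <- data.frame(t_days = t, tumor_count = (0.8 * (te - t))^3)
  f <- cubeRootFit(cubic, c(10, 39.9))
  expect_equal(f$r, -1, tolerance = 1e-10)
  expect_equal(f$predictedExtinction, te, tolerance = 1e-8)
  expect_equal(f$slope, -0.8, tolerance = 1e-8)
  # an exponential is visibly non-cubic: |r| strictly below 1
  expo <- data.frame(t_days = t, tumor_count = 1e5 * exp(-0.3 * t))
  fe <- cubeRootFit(expo, c(10, 39.9))
  expect_lt(abs(fe$r), 0.995)
  expect_lt(abs(fe$r), abs(f$r))
  # zero count in the window interior is an error, as is a tiny window
  bad <- cubic
  bad$tumor_count[500] <- 0
  expect_error(cubeRootFit(bad, c(10, 39.9)), "positive")
  expect_error(cubeRootFit(cubic[1:2, ], c(10, 10.1)), "3 points")
})

test_that("Spearman correlation matches oracles", {
  s <- spearmanRho(1:8, 1:8)
  expect_equal(s$rho, 1)
  expect_lt(s$p, 0.01)
  # monotone invariance: rho depends on ranks only
  x <- c(0.5, 1, 2, 3.5, 7)
  s2 <- spearmanRho(x, -x^2)
  expect_equal(s2$rho, -1)
  # exact small-sample p agrees with the exact test in stats::cor.test
  set.seed(31)
  for (n in c(5, 6, 7, 9)) {
    x <- rnorm(n); y <- rnorm(n)
    mine <- spearmanRho(x, y)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman", exact = TRUE))
    expect_equal(mine$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
  }
  # ties use average ranks
  xt <- c(1, 1, 2, 3, 4, 4)
  yt <- c(2, 1, 3, 3, 5, 6)
  expect_equal(spearmanRho(xt, yt)$rho,
               cor(rank(xt), rank(yt)), tolerance = 1e-12)
  expect_error(spearmanRho(1:4, 1:5), "equal length")
  expect_error(spearmanRho(1:2, 1:2), "at least 3")
})

test_that("sweeps are bookkept and reproducible", {
  st <- stopRule(maxDays = 40)
  p <- baseParams()
  res <- runSweep("antigenicity", c(1e-6, 1e-5), params = p, stop = st,
                  reps = 2, seed0 = 3L)
  expect_equal(nrow(res@outcomes), 4)
  expect_true(all(res@outcomes$value %in% c(1e-6, 1e-5)))
  res2 <- runSweep("antigenicity", c(1e-6, 1e-5), params = p, stop = st,
                   reps = 2, seed0 = 3L)
  expect_identical(res@outcomes, res2@outcomes)
  # a single grid value leaves the correlation undefined
  res3 <- runSweep("antigenicity", 1e-5, params = p, stop = st,
                   reps = 2, seed0 = 3L)
  expect_true(all(is.na(res3@rho$rho)))
  # swept derived quantities are re-derived: nDiv drives tauProg
  res4 <- runSweep("nDiv", c(7, 10), params = p,
                   stop = stopRule(maxDays = 0.01), reps = 1, seed0 = 1L)
  expect_equal(nrow(res4@outcomes), 2)
})
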