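test_that("growth rate from a noiseless exponential is exact for any window and grid", {
  set.seed(3)
  for (i in 1:10) {
    rate <- runif(1, 0.05, 0.5)
    times <- cumsum(runif(12, 0.3, 2))
    y <- 50 * exp(rate * times)
    for (w in c(3, 4)) {
      est <- growthRateFromTimeseries(times, y, window = w)
      expect_equal(est@rate, rate, tolerance = 1e-9)
      expect_false(est@noGrowth)
    }
  }
})

test_that("constant or decaying signals are flagged as no growth", {
  t <- 0:9
  est <- growthRateFromTimeseries(t, rep(5, 10))
  expect_true(est@noGrowth)
  expect_identical(est@rate, 0)
  est2 <- growthRateFromTimeseries(t, 100 * exp(-0.1 * t))
  expect_true(est2@noGrowth)
})

test_that("growth rate equals the brute-force maximum over all window slopes", {
  set.seed(17)
  for (i in 1:5) {
    times <- seq(0, 20, by = 1.5)
    y <- 100 * exp(0.15 * times) * exp(rnorm(length(times), 0, 0.1))
    for (w in c(3L, 4L)) {
      est <- growthRateFromTimeseries(times, y, window = w)
      ly <- log(y / y[1])
      brute <- max(vapply(seq_len(length(times) - w + 1L), function(s) {
        lmWindowSlope(times, ly, s:(s + w - 1L))
      }, numeric(1)))
      expect_equal(est@rate, brute, tolerance = 1e-10)
      expect_length(est@allWindowSlopes, length(times) - w + 1L)
    }
  }
})

test_that("growth rate rejects malformed input", {
  expect_error(growthRateFromTimeseries(0:2, c(1, 2, 3), window = 5),
               "window")
  expect_error(growthRateFromTimeseries(0:1, c(1, 2)), "at least")
  expect_error(growthRateFromTimeseries(0:3, c(1, 2, 0, 3)), "> 0")
  expect_error(growthRateFromTimeseries(c(0, 1, 1, 2), c(1, 2, 3, 4)),
               "increasing")
})

test_that("Moser fit recovers noiseless parameters and rejects bad input", {
  p <- MoserParams(0.44, 2, 2)
  L <- c(0.5, 1, 2, 4, 8, 16, 32, 64)
  fit <- fitMoser(L, moserRate(L, p))
  expect_equal(fit$params@bMax, 0.44, tolerance = 1e-5)
  expect_equal(fit$params@KL, 2, tolerance = 1e-4)
  expect_equal(fit$params@n, 2, tolerance = 1e-4)
  expect_lt(fit$rss, 1e-10)

  expect_error(fitMoser(c(1, 10), c(0.1, 0.4)), "4 distinct")
  expect_error(fitMoser(c(1, 2, 4, 8), rep(0.3, 4)), "degenerate")
})

test_that("Moser fit recovers parameters from noisy replicated data", {
  truth <- MoserParams(0.44, 2, 2)
  L <- rep(c(0.25, 0.5, 1, 2, 4, 8, 16, 32), each = 3)
  ok <- 0L
  nSeeds <- 20L
  for (seed in seq_len(nSeeds)) {
    set.seed(seed)
    b <- moserRate(L, truth) * exp(rnorm(length(L), 0, 0.05))
    fit <- fitMoser(L, b)
    if (abs(fit$params@bMax - 0.44) / 0.44 < 0.05 &&
        abs(fit$params@KL - 2) / 2 < 0.15) ok <- ok + 1L
  }
  expect_gte(ok, 0.9 * nSeeds)
})

test_that("steady-state detection matches the analytic chemostat plateau", {
  expect_equal(detectSteadyState(0:9, rep(4, 10)),
               list(reached = TRUE, tOnset = 0, mean = 4))
  ramp <- detectSteadyState(0:9, seq(1, 1.5, length.out = 10))
  expect_false(ramp$reached)

  cfg <- designChemostat()
  phen <- StrainPhenotype(0.3, 3, kinetics = fastKinetics(0.1))
  traj <- simulateChemostat(cfg, phen, seq(0, 400, by = 4))
  ss <- detectSteadyState(trajTimes(traj), stateVar(traj, "product_uM"))
  expect_true(ss$reached)
  expect_equal(ss$mean, chemostatSteadyState(cfg, phen)$product_uM,
               tolerance = 0.02)
  expect_error(detectSteadyState(0:3, 1:4), "at least 5")
})

test_that("exchange ratio: identities and the simulated-chemostat round trip", {
  expect_equal(exchangeRatio(0.1, 0, 20)@value, 0)
  expect_equal(exchangeRatio(log(2) / 6, 20, 20)@value, log(2) / 6)
  expect_error(exchangeRatio(0.1, 5, 0), "L0")

  phen <- StrainPhenotype(0.3, 3, kinetics = fastKinetics(0.05))
  for (Tdbl in c(4, 6, 8)) {
    cfg <- ChemostatConfig(doublingTime = Tdbl, inflowConc = 20,
                           inoculumLive = 1e5)
    traj <- simulateChemostat(cfg, phen, seq(0, 250, by = 2))
    expect_lt(tail(stateVar(traj, "nutrient_uM"), 1), 0.01 * 20)
    ss <- detectSteadyState(trajTimes(traj), stateVar(traj, "product_uM"))
    est <- exchangeRatio(cfg@dilutionRate, ss$mean, 20)
    expect_equal(est@value, exchangeRatioOf(phen), tolerance = 0.02)
  }
})

test_that("replicate exchange ratios carry a CI around their mean", {
  est <- exchangeRatio(dil = rep(log(2) / 6, 4),
                       Hss = c(16, 17, 18, 17.5), L0 = 20)
  expect_length(est@replicates, 4L)
  expect_equal(est@value, mean(est@replicates))
  expect_true(est@ci[1] < est@value && est@value < est@ci[2])
})

test_that("cytometry densities follow the bead-ratio arithmetic", {
  s <- CytometrySample(2000, 100, 500, beadStockDensity = 1e6,
                       beadVolume = 0.05, sampleVolume = 1)
  d <- cytometryDensities(s)
  expect_equal(unname(d["live_per_ml"]), 4 * 1e6 * 0.05)  # 2e5
  expect_equal(unname(d["dead_per_ml"]), 0.2 * 1e6 * 0.05)

  ident <- CytometrySample(500, 0, 500, 1e6, 1, 1)
  expect_equal(unname(cytometryDensities(ident)["live_per_ml"]), 1e6)
  expect_equal(unname(cytometryDensities(ident)["dead_per_ml"]), 0)
  expect_error(cytometryDensities(CytometrySample(10, 10, 0, 1e6, 0.05, 1)),
               "bead")
})

test_that("bioassay inversion and extrapolation flags", {
  conc <- c(0, 5, 10, 20, 40)
  sc <- fitStandardCurve(conc, 0.05 + 0.02 * conc)
  expect_equal(sc@slope, 0.02, tolerance = 1e-10)
  expect_equal(bioassayConcentration(sc, 0.45), 20, ignore_attr = TRUE)
  expect_equal(bioassayConcentration(sc, sc@intercept), 0,
               ignore_attr = TRUE)
  expect_warning(low <- bioassayConcentration(sc, 0.01), "outside")
  expect_lt(unname(low), 0)
  expect_true(attr(low, "extrapolated"))
  expect_error(fitStandardCurve(c(0, 1), c(0, 1)), "3 calibration")
  expect_error(fitStandardCurve(c(0, 5, 10), c(0.5, 0.3, 0.1)), "slope")
})

test_that("community growth rate fits the exponential regime and skips the lag", {
  t <- seq(0, 24, by = 2)
  pure <- 1e4 * exp(0.12 * t)
  res <- communityGrowthRate(t, pure)
  expect_equal(res$rate, 0.12, tolerance = 1e-10)
  expect_equal(res$window, seq_along(t))

  lagged <- c(rep(1e4, 4), 1e4 * exp(0.1 * (t[5:13] - t[4])))
  res2 <- communityGrowthRate(t, lagged)
  expect_equal(res2$rate, 0.1, tolerance = 1e-10)
  expect_gte(res2$window[1], 4L)

  expect_error(communityGrowthRate(0:2, c(1, 2, 3)), "4 points")
  expect_error(communityGrowthRate(0:5, c(1, 2, 1, 2, 1, 2)), "no steady")
})

test_that("generation counting accumulates density across dilutions", {
  expect_equal(generationsFromOD(c(0.1, 0.2)), c(0, 1))
  expect_equal(generationsFromOD(c(0.1, 0.04), 10), c(0, 2))
  expect_equal(generationsFromOD(rep(0.3, 5)), rep(0, 5))
  expect_error(generationsFromOD(c(0.1, -0.2)), "> 0")
  expect_error(generationsFromOD(c(0.1, 0.2), c(0.5, 1)), ">= 1")
})

test_that("dilution-rate and flow-rate arithmetic", {
  expect_equal(flowRateForDoubling(log(2), 1), 1)
  expect_equal(flowRateForDoubling(8, 19), 19 * log(2) / 8)  # ~1.646 ml/hr
  expect_equal(flowRateForDoubling(1e9, 19), 0, tolerance = 1e-7)
  expect_equal(dilutionFromDoubling(6), log(2) / 6)
  expect_equal(doublingFromDilution(log(2) / 6), 6)
  expect_error(flowRateForDoubling(0, 19), "> 0")
})
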