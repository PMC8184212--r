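test_that("moserRate matches the closed form and its identities", {
  p <- MoserParams(bMax = 0.44, KL = 1, n = 2)
  expect_identical(moserRate(0, p), 0)
  expect_equal(moserRate(1, p), 0.44 / 2)        # half-saturation
  expect_equal(moserRate(3, p), 0.44 * 9 / 10)   # hand evaluation: 0.396
  expect_error(moserRate(-1, p), ">= 0")
})

test_that("moserRate is monotone in L and bounded by bMax", {
  set.seed(11)
  for (i in 1:20) {
    p <- MoserParams(runif(1, 0.1, 2), runif(1, 0.1, 50), runif(1, 0.5, 5))
    L <- sort(c(0, runif(30, 0, 200)))
    b <- moserRate(L, p)
    expect_true(all(diff(b) >= -1e-12))
    expect_true(all(b >= 0 & b < p@bMax))
  }
})

test_that("domain type validity rejects out-of-range parameters", {
  expect_error(MoserParams(-1, 1, 1), "bMax")
  expect_error(StrainPhenotype(releaseRate = -0.1, consumptionPerBirth = 1),
               "releaseRate")
  expect_error(StrainPhenotype(releaseRate = 0.1, consumptionPerBirth = 0),
               "consumptionPerBirth")
  expect_error(ChemostatConfig(dilutionRate = 0, inflowConc = 20),
               "dilutionRate")
  expect_error(ChemostatConfig(inflowConc = 20),
               "dilutionRate|doublingTime")
  expect_error(new("Trajectory", times = c(0, 1, 1),
                   state = matrix(0, 3, 1, dimnames = list(NULL, "x"))),
               "strictly increasing")
  expect_error(new("Trajectory", times = c(0, 1),
                   state = matrix(c(1, -1), 2, 1,
                                  dimnames = list(NULL, "x"))),
               ">= 0")
})

test_that("steady-state growth rate and ratio match the eigen-decomposition oracle", {
  # reduced supply-limited linear system: dN1/dt = (r2/c1) N2,
  # dN2/dt = (r1/c2) N1; oracle via base::eigen on the 2x2 matrix
  set.seed(42)
  for (i in 1:100) {
    p1 <- randomPhenotype(); p2 <- randomPhenotype()
    M <- matrix(c(0, p1@releaseRate / p2@consumptionPerBirth,
                  p2@releaseRate / p1@consumptionPerBirth, 0), 2, 2)
    eig <- eigen(M)
    dom <- which.max(Re(eig$values))
    expect_equal(communitySteadyGrowth(p1, p2), Re(eig$values[dom]),
                 tolerance = 1e-10)
    v <- Re(eig$vectors[, dom])
    expect_equal(communitySteadyRatio(p1, p2), v[1] / v[2],
                 tolerance = 1e-10)
  }
})

test_that("steady-state growth rate is symmetric; ratio inverts under swap", {
  a <- mutantPhen(); b <- partnerPhen()
  expect_equal(communitySteadyGrowth(a, b), communitySteadyGrowth(b, a))
  expect_equal(communitySteadyGrowth(a, b), sqrt(0.16 * 0.10))
  expect_equal(communitySteadyRatio(a, b) * communitySteadyRatio(b, a), 1)
  sym <- StrainPhenotype(0.3, 3)
  expect_equal(communitySteadyGrowth(sym, sym), 0.1)
  expect_equal(communitySteadyRatio(sym, sym), 1)
})

test_that("a 1.6-fold one-sided exchange-ratio change speeds the community by sqrt(1.6)", {
  anc <- ancestorPhen(); part <- partnerPhen()
  mut <- mutantPhen()  # 1.6x the ancestor release rate, same consumption
  gOld <- communitySteadyGrowth(anc, part)
  gNew <- communitySteadyGrowth(mut, part)
  expect_equal(gNew / gOld, sqrt(1.6))
  expect_equal(round(100 * (gNew / gOld - 1)), 26)
})

test_that("chemostat simulation: empty inoculum washes nutrient to L0", {
  cfg <- ChemostatConfig(doublingTime = 6, inflowConc = 20, inoculumLive = 0)
  traj <- simulateChemostat(cfg, ancestorPhen(), seq(0, 120, by = 2))
  expect_true(all(stateVar(traj, "live_per_ml") == 0))
  expect_true(all(stateVar(traj, "dead_per_ml") == 0))
  expect_equal(tail(stateVar(traj, "nutrient_uM"), 1), 20, tolerance = 1e-4)
})

test_that("chemostat simulation converges to the analytic steady state", {
  cfg <- designChemostat()
  phen <- StrainPhenotype(releaseRate = 0.3, consumptionPerBirth = 3,
                          kinetics = fastKinetics(0.1))
  traj <- simulateChemostat(cfg, phen, seq(0, 400, by = 2))
  ss <- chemostatSteadyState(cfg, phen)
  final <- trajState(traj)[nrow(trajState(traj)), ]
  expect_equal(unname(final["live_per_ml"]), ss$live_per_ml,
               tolerance = 1e-4)
  expect_equal(unname(final["product_uM"]), ss$product_uM, tolerance = 1e-4)
  # product plateau identity: Hss = r * Nss * 1e-6 / dil
  expect_equal(ss$product_uM,
               phen@releaseRate * ss$live_per_ml * 1e-6 / cfg@dilutionRate)
  # nutrient mass balance at steady state
  b <- moserRate(final["nutrient_uM"], phen@kinetics)
  influx <- cfg@dilutionRate * cfg@inflowConc
  outflux <- cfg@dilutionRate * final["nutrient_uM"] +
    phen@consumptionPerBirth * b * final["live_per_ml"] * 1e-6
  expect_equal(unname(outflux), influx, tolerance = 1e-5)
})

test_that("chemostat trajectories stay non-negative across random configs", {
  set.seed(7)
  for (i in 1:10) {
    cfg <- ChemostatConfig(dilutionRate = runif(1, 0.05, 0.3),
                           inflowConc = runif(1, 5, 50),
                           inoculumLive = 10^runif(1, 3, 6),
                           inoculumDead = 10^runif(1, 0, 4))
    phen <- randomPhenotype()
    traj <- simulateChemostat(cfg, phen, seq(0, 48, by = 2))
    expect_true(all(trajState(traj) >= 0))
  }
})

test_that("community simulation: missing partner means no growth for either strain", {
  cfg <- CommunityConfig(ancestorPhen(), partnerPhen(), N1 = 0, N2 = 1e5)
  traj <- simulateCommunity(cfg, seq(0, 48, by = 1))
  expect_true(all(stateVar(traj, "N1_per_ml") == 0))
  # with no strain 1 there is no metabolite B, so strain 2 cannot grow
  expect_true(all(diff(stateVar(traj, "N2_per_ml")) <= 1e-6))
})

test_that("community simulation: symmetric strains stay identical", {
  sym <- StrainPhenotype(0.3, 3, kinetics = fastKinetics(0.5))
  cfg <- CommunityConfig(sym, sym, N1 = 1e5, N2 = 1e5)
  traj <- simulateCommunity(cfg, seq(0, 48, by = 1))
  expect_equal(stateVar(traj, "N1_per_ml"), stateVar(traj, "N2_per_ml"),
               tolerance = 1e-8)
  expect_equal(stateVar(traj, "A_uM"), stateVar(traj, "B_uM"),
               tolerance = 1e-6)
})

test_that("community late-time log-slope approaches the geometric-mean rate", {
  cfg <- CommunityConfig(mutantPhen(0.3), partnerPhen(0.3),
                         N1 = 1e5, N2 = 1e5)
  traj <- simulateCommunity(cfg, seq(0, 120, by = 2))
  tot <- stateVar(traj, "N1_per_ml") + stateVar(traj, "N2_per_ml")
  g <- communitySteadyGrowth(cfg@phenotype1, cfg@phenotype2)
  expect_equal(g, sqrt(0.016), tolerance = 1e-12)
  rate <- communityGrowthRate(trajTimes(traj), tot)$rate
  expect_equal(rate, g, tolerance = 0.05)
})

test_that("competition: neutral genotypes keep a constant frequency", {
  cfg <- ChemostatConfig(doublingTime = 8, inflowConc = 20,
                         inoculumLive = 2e5)
  phen <- ancestorPhen(0.5)
  traj <- simulateCompetition(cfg, phen, phen, seq(0, 72, by = 2))
  a <- stateVar(traj, "liveA_per_ml"); b <- stateVar(traj, "liveB_per_ml")
  expect_equal(a / (a + b), rep(0.5, length(a)), tolerance = 1e-8)
})

test_that("competition: the faster genotype at residual nutrient takes over", {
  cfg <- ChemostatConfig(doublingTime = 8, inflowConc = 20,
                         inoculumLive = 2e5)
  # genotype A reaches a much higher birth rate at low nutrient (lower KL)
  fast <- StrainPhenotype(0.3, 3, kinetics = MoserParams(0.44, 0.2, 2))
  slow <- StrainPhenotype(0.3, 3, kinetics = MoserParams(0.44, 3, 2))
  traj <- simulateCompetition(cfg, fast, slow, seq(0, 168, by = 4))
  a <- stateVar(traj, "liveA_per_ml"); b <- stateVar(traj, "liveB_per_ml")
  freq <- a / (a + b)
  expect_gt(tail(freq, 1), 0.99)   # takeover within a simulated week
  late <- freq[trajTimes(traj) > 24]
  expect_true(all(diff(late) > -1e-10))  # monotone after transients

  onlyA <- simulateCompetition(cfg, fast, slow, seq(0, 48, by = 2),
                               inoculumA = 2e5, inoculumB = 0)
  expect_true(all(stateVar(onlyA, "liveB_per_ml") == 0))
})

test_that("trajectory accessors and data.frame coercion agree", {
  traj <- simulateChemostat(designChemostat(), ancestorPhen(),
                            seq(0, 10, by = 1))
  df <- as.data.frame(traj)
  expect_named(df, c("time_hr", "live_per_ml", "dead_per_ml", "nutrient_uM",
                     "product_uM"))
  expect_equal(df$time_hr, trajTimes(traj))
  expect_equal(df$live_per_ml, stateVar(traj, "live_per_ml"))
  expect_equal(length(traj), 11L)
  expect_error(stateVar(traj, "bogus"), "no state variable")
})
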