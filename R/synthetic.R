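## Seeded synthetic-data generators. Each returns a list with a `data`
## data.frame shaped like the corresponding assay table and a `truth` list
## carrying the generating parameters, so round-trip tests read ground truth
## from the sidecar rather than re-deriving it. All randomness is confined
## to a local RNG scope keyed by the NoiseSpec seed, so outputs are
## deterministic given the seed and the session RNG is left untouched.

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

.lognoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)  # mean 1
}

#' Default synthetic strain phenotypes
#'
#' The ancestor-like phenotype has exchange ratio 0.10/hr (matching the
#' ancestral community's ~0.1/hr steady-state growth rate) with
#' consumptionPerBirth 3 fmol/cell (back-computed from a 21 uM reservoir
#' supporting ~7e6 cells/ml); the mutant-like phenotype raises the release
#' rate 1.6-fold. The partner phenotype is a synthetic stand-in with the
#' same exchange ratio as the ancestor.
#'
#' @param which one of "ancestor", "mutant", "partner"
#' @param KL half-saturation (uM); small values keep community metabolite
#'   pools supply-limited
#' @return a [StrainPhenotype-class]
#' @export
syntheticPhenotype <- function(which = c("ancestor", "mutant", "partner"),
                               KL = 0.5) {
  which <- match.arg(which)
  kin <- MoserParams(bMax = 0.44, KL = KL, n = 2)
  switch(which,
    ancestor = StrainPhenotype(releaseRate = 0.30, consumptionPerBirth = 3,
                               kinetics = kin),
    mutant = StrainPhenotype(releaseRate = 0.48, consumptionPerBirth = 3,
                             kinetics = kin),
    partner = StrainPhenotype(releaseRate = 0.20, consumptionPerBirth = 2,
                              kinetics = kin))
}

#' Synthetic microscopy growth-assay time course
#'
#' A fluorescence intensity series: flat baseline during the lag, then
#' exponential growth at `rate`, each point multiplied by lognormal noise of
#' the given coefficient of variation.
#'
#' @param rate true growth rate (1/hr), >= 0
#' @param lag lag duration (hr)
#' @param nPoints number of time points
#' @param dt sampling interval (hr)
#' @param noise a [NoiseSpec-class]
#' @param baseline intensity at time zero (arbitrary units)
#' @return list with `data` (data.frame: time_hr, intensity) and `truth`
#'   (list: rate, lag, baseline, cv, seed)
#' @examples
#' gm <- genMicroscopySeries(0.2, lag = 2, nPoints = 20, dt = 1,
#'                           noise = NoiseSpec(0, seed = 7))
#' growthRateFromTimeseries(gm$data$time_hr, gm$data$intensity)
#' @export
genMicroscopySeries <- function(rate, lag = 0, nPoints = 20, dt = 1,
                                noise = NoiseSpec(), baseline = 100) {
  if (rate < 0 || dt <= 0) stop("'rate' must be >= 0 and 'dt' > 0")
  times <- seq(0, by = dt, length.out = nPoints)
  clean <- baseline * exp(rate * pmax(times - lag, 0))
  intensity <- .withSeed(noise@seed,
                         clean * .lognoise(nPoints, noise@multiplicativeCV))
  list(data = data.frame(time_hr = times, intensity = intensity),
       truth = list(rate = rate, lag = lag, baseline = baseline,
                    cv = noise@multiplicativeCV, seed = noise@seed))
}

#' Synthetic chemostat assay series
#'
#' Simulates the chemostat ODE model on a sampling grid and applies
#' multiplicative lognormal observational noise to the sampled live/dead
#' densities and concentrations, emulating periodic cytometry and bioassay
#' measurements of a nutrient-limited chemostat converging to steady state.
#'
#' @param phen a [StrainPhenotype-class]
#' @param cfg a [ChemostatConfig-class]
#' @param times sampling times (hr), starting at 0
#' @param noise a [NoiseSpec-class]
#' @return list with `data` (data.frame: time_hr, live_per_ml, dead_per_ml,
#'   nutrient_uM, product_uM) and `truth` (releaseRate, consumptionPerBirth,
#'   exchangeRatio, dil, L0, and the analytic steady states)
#' @export
genChemostatSeries <- function(phen, cfg, times = seq(0, 72, by = 2),
                               noise = NoiseSpec()) {
  traj <- simulateChemostat(cfg, phen, times)
  obs <- as.data.frame(traj)
  cv <- noise@multiplicativeCV
  obs[-1] <- .withSeed(noise@seed, {
    lapply(obs[-1], function(col) col * .lognoise(length(col), cv))
  })
  ss <- chemostatSteadyState(cfg, phen)
  list(data = obs,
       truth = list(releaseRate = phen@releaseRate,
                    consumptionPerBirth = phen@consumptionPerBirth,
                    exchangeRatio = exchangeRatioOf(phen),
                    dil = cfg@dilutionRate, L0 = cfg@inflowConc,
                    steadyState = ss, cv = cv, seed = noise@seed))
}

#' Synthetic community growth series
#'
#' Simulates the closed two-strain community and applies multiplicative
#' lognormal noise to the two abundance columns, emulating periodic absolute
#' abundance measurements of a growing cross-feeding patch (initial lag, then
#' steady exponential growth).
#'
#' @param cfg a [CommunityConfig-class]
#' @param times sampling times (hr), starting at 0
#' @param noise a [NoiseSpec-class]
#' @return list with `data` (data.frame: time_hr, N1_per_ml, N2_per_ml,
#'   total_per_ml) and `truth` (steadyGrowthRate, steadyRatio, the two
#'   exchange ratios, cv, seed)
#' @export
genCommunitySeries <- function(cfg, times = seq(0, 72, by = 3),
                               noise = NoiseSpec()) {
  traj <- simulateCommunity(cfg, times)
  n1 <- stateVar(traj, "N1_per_ml"); n2 <- stateVar(traj, "N2_per_ml")
  cv <- noise@multiplicativeCV
  noisy <- .withSeed(noise@seed, {
    list(n1 = n1 * .lognoise(length(n1), cv),
         n2 = n2 * .lognoise(length(n2), cv))
  })
  list(data = data.frame(time_hr = trajTimes(traj), N1_per_ml = noisy$n1,
                         N2_per_ml = noisy$n2,
                         total_per_ml = noisy$n1 + noisy$n2),
       truth = list(
         steadyGrowthRate = communitySteadyGrowth(cfg@phenotype1,
                                                  cfg@phenotype2),
         steadyRatio = communitySteadyRatio(cfg@phenotype1, cfg@phenotype2),
         exchangeRatio1 = exchangeRatioOf(cfg@phenotype1),
         exchangeRatio2 = exchangeRatioOf(cfg@phenotype2),
         cv = cv, seed = noise@seed))
}

#' Synthetic bead-calibrated cytometry events
#'
#' Draws Poisson event counts for live cells, dead cells and spiked beads
#' from their expected values given true densities, the bead configuration
#' and the acquired fraction of the prepared sample.
#'
#' @param trueLive,trueDead true densities (cells/ml)
#' @param beadStockDensity bead stock density (beads/ml)
#' @param beadVolume bead stock volume added (ml)
#' @param sampleVolume culture sample volume (ml)
#' @param acquisitionFraction fraction of the prepared sample the cytometer
#'   actually reads
#' @param noise a [NoiseSpec-class]; `countNoise = FALSE` returns rounded
#'   expectations
#' @return list with `sample` (a [CytometrySample-class]) and `truth`
#' @export
genCytometryEvents <- function(trueLive, trueDead, beadStockDensity = 1e6,
                               beadVolume = 0.05, sampleVolume = 1,
                               acquisitionFraction = 0.02,
                               noise = NoiseSpec()) {
  if (trueLive < 0 || trueDead < 0) stop("true densities must be >= 0")
  expLive <- trueLive * sampleVolume * acquisitionFraction
  expDead <- trueDead * sampleVolume * acquisitionFraction
  expBead <- beadStockDensity * beadVolume * acquisitionFraction
  counts <- if (noise@countNoise) {
    .withSeed(noise@seed, stats::rpois(3, c(expLive, expDead, expBead)))
  } else round(c(expLive, expDead, expBead))
  if (counts[3] == 0) counts[3] <- 1  # a bead-free acquisition is re-run
  sample <- CytometrySample(fluorEvents = counts[1],
                            nonfluorEvents = counts[2],
                            beadEvents = counts[3],
                            beadStockDensity = beadStockDensity,
                            beadVolume = beadVolume,
                            sampleVolume = sampleVolume)
  list(sample = sample,
       truth = list(live = trueLive, dead = trueDead,
                    expectedEvents = c(live = expLive, dead = expDead,
                                       bead = expBead),
                    seed = noise@seed))
}

#' Synthetic bioassay standard curve and spiked samples
#'
#' Generates calibration turbidities from a linear response with
#' multiplicative noise, plus spiked unknown samples with known true
#' concentrations.
#'
#' @param slope true response slope (turbidity per uM)
#' @param intercept true blank turbidity
#' @param concentrations calibration concentrations (uM)
#' @param spiked true concentrations of unknown samples (uM)
#' @param noise a [NoiseSpec-class]
#' @return list with `curveData` (data.frame: conc_uM, turbidity),
#'   `samples` (data.frame: true_conc_uM, turbidity), `truth`
#' @export
genBioassayCurve <- function(slope = 0.02, intercept = 0.05,
                             concentrations = c(0, 5, 10, 20, 40),
                             spiked = numeric(), noise = NoiseSpec()) {
  if (slope <= 0) stop("'slope' must be > 0")
  cv <- noise@multiplicativeCV
  res <- .withSeed(noise@seed, {
    curveT <- (intercept + slope * concentrations) *
      .lognoise(length(concentrations), cv)
    spikedT <- (intercept + slope * spiked) * .lognoise(length(spiked), cv)
    list(curveT = curveT, spikedT = spikedT)
  })
  list(curveData = data.frame(conc_uM = concentrations,
                              turbidity = res$curveT),
       samples = data.frame(true_conc_uM = spiked, turbidity = res$spikedT),
       truth = list(slope = slope, intercept = intercept, cv = cv,
                    seed = noise@seed))
}
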