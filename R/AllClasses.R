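#' @import methods
NULL

## Unit conventions used throughout:
##   concentrations uM at every interface; internal mass fluxes fmol/ml with
##   1 uM == 1e6 fmol/ml; densities cells/ml; rates 1/hr; times hr.
.UM_PER_FMOL_ML <- 1e-6

#' Moser (Hill-type Monod) growth kinetics parameters
#'
#' Parameters of the saturating birth-rate law
#' \eqn{b(L) = b_{max} L^n / (K_L^n + L^n)}: the maximum birth rate in excess
#' nutrient, the half-saturation concentration, and the cooperativity
#' exponent describing the sigmoidal shape of the curve (\eqn{n = 1} recovers
#' classical Monod kinetics).
#'
#' @slot bMax maximum birth rate (1/hr); must be > 0
#' @slot KL half-saturation concentration (uM); must be > 0
#' @slot n cooperativity exponent (dimensionless); must be > 0
#' @seealso [moserRate()], [fitMoser()]
#' @export
setClass("MoserParams",
  representation(bMax = "numeric", KL = "numeric", n = "numeric"),
  prototype(bMax = 0.44, KL = 1, n = 1))

setValidity("MoserParams", function(object) {
  msg <- character()
  for (s in c("bMax", "KL", "n")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("'%s' must be a single finite value > 0", s))
  }
  if (length(msg)) msg else TRUE
})

#' Construct Moser kinetics parameters
#'
#' @param bMax maximum birth rate (1/hr)
#' @param KL half-saturation concentration (uM)
#' @param n cooperativity exponent (default 1, i.e. Monod)
#' @return a [MoserParams-class] object
#' @examples
#' MoserParams(bMax = 0.44, KL = 1, n = 2)
#' @export
MoserParams <- function(bMax, KL, n = 1) {
  new("MoserParams", bMax = as.numeric(bMax), KL = as.numeric(KL),
      n = as.numeric(n))
}

#' Per-strain cross-feeding phenotype
#'
#' The quantitative phenotype of one auxotrophic strain in a metabolite
#' exchange: the per-cell release rate of the metabolite it overproduces, the
#' amount of partner-supplied metabolite consumed to make one new cell, its
#' growth kinetics on that metabolite, and a per-capita death rate. The
#' derived quantity releaseRate / consumptionPerBirth (units 1/hr) is the
#' strain's exchange ratio: benefit supply rate per intake benefit.
#'
#' @slot releaseRate metabolite released per live cell per hour (fmol/cell/hr)
#' @slot consumptionPerBirth metabolite consumed per cell birth (fmol/cell)
#' @slot kinetics a [MoserParams-class] object for growth on the consumed
#'   metabolite
#' @slot deathRate per-capita death rate (1/hr); defaults to 0
#' @seealso [exchangeRatioOf()], [communitySteadyGrowth()]
#' @export
setClass("StrainPhenotype",
  representation(releaseRate = "numeric", consumptionPerBirth = "numeric",
                 kinetics = "MoserParams", deathRate = "numeric"),
  prototype(releaseRate = 0, consumptionPerBirth = 1,
            kinetics = new("MoserParams"), deathRate = 0))

setValidity("StrainPhenotype", function(object) {
  msg <- character()
  if (length(object@releaseRate) != 1L || !is.finite(object@releaseRate) ||
      object@releaseRate < 0)
    msg <- c(msg, "'releaseRate' must be a single finite value >= 0")
  if (length(object@consumptionPerBirth) != 1L ||
      !is.finite(object@consumptionPerBirth) || object@consumptionPerBirth <= 0)
    msg <- c(msg, "'consumptionPerBirth' must be a single finite value > 0")
  if (length(object@deathRate) != 1L || !is.finite(object@deathRate) ||
      object@deathRate < 0)
    msg <- c(msg, "'deathRate' must be a single finite value >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a strain phenotype
#'
#' @param releaseRate per-cell metabolite release rate (fmol/cell/hr)
#' @param consumptionPerBirth metabolite consumed per cell birth (fmol/cell)
#' @param kinetics a [MoserParams-class] object (growth on the consumed
#'   metabolite)
#' @param deathRate per-capita death rate (1/hr), default 0
#' @return a [StrainPhenotype-class] object
#' @examples
#' anc <- StrainPhenotype(releaseRate = 0.3, consumptionPerBirth = 3,
#'                        kinetics = MoserParams(0.44, 1, 2))
#' exchangeRatioOf(anc)  # 0.1 /hr
#' @export
StrainPhenotype <- function(releaseRate, consumptionPerBirth,
                            kinetics = MoserParams(0.44, 1, 2),
                            deathRate = 0) {
  new("StrainPhenotype", releaseRate = as.numeric(releaseRate),
      consumptionPerBirth = as.numeric(consumptionPerBirth),
      kinetics = kinetics, deathRate = as.numeric(deathRate))
}

#' Chemostat configuration
#'
#' Operating parameters of a continuous culture: dilution rate (flow rate over
#' culture volume), nutrient concentration in the inflow medium, inocula, and
#' initial vessel concentrations. At steady state the net growth rate of the
#' resident population equals the dilution rate.
#'
#' @slot dilutionRate 1/hr; > 0
#' @slot inflowConc nutrient concentration in fresh medium (uM); > 0
#' @slot inoculumLive initial live density (cells/ml); >= 0
#' @slot inoculumDead initial dead density (cells/ml); >= 0
#' @slot initialNutrient initial vessel nutrient concentration (uM); >= 0
#' @slot initialProduct initial vessel product concentration (uM); >= 0
#' @export
setClass("ChemostatConfig",
  representation(dilutionRate = "numeric", inflowConc = "numeric",
                 inoculumLive = "numeric", inoculumDead = "numeric",
                 initialNutrient = "numeric", initialProduct = "numeric"),
  prototype(dilutionRate = log(2) / 6, inflowConc = 20, inoculumLive = 1e5,
            inoculumDead = 0, initialNutrient = 0, initialProduct = 0))

setValidity("ChemostatConfig", function(object) {
  msg <- character()
  if (object@dilutionRate <= 0 || !is.finite(object@dilutionRate))
    msg <- c(msg, "'dilutionRate' must be > 0")
  if (object@inflowConc <= 0 || !is.finite(object@inflowConc))
    msg <- c(msg, "'inflowConc' must be > 0")
  for (s in c("inoculumLive", "inoculumDead", "initialNutrient",
              "initialProduct")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v < 0)
      msg <- c(msg, sprintf("'%s' must be a single finite value >= 0", s))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a chemostat configuration
#'
#' Either `dilutionRate` or a doubling time `doublingTime` (with
#' dilutionRate = ln(2)/doublingTime) must be given.
#'
#' @param dilutionRate dilution rate (1/hr)
#' @param doublingTime alternative to `dilutionRate`: target doubling time (hr)
#' @param inflowConc inflow nutrient concentration (uM)
#' @param inoculumLive,inoculumDead inoculum densities (cells/ml)
#' @param initialNutrient,initialProduct initial vessel concentrations (uM)
#' @return a [ChemostatConfig-class] object
#' @examples
#' ChemostatConfig(doublingTime = 6, inflowConc = 20)
#' @export
ChemostatConfig <- function(dilutionRate = NULL, doublingTime = NULL,
                            inflowConc = 20, inoculumLive = 1e5,
                            inoculumDead = 0, initialNutrient = 0,
                            initialProduct = 0) {
  if (is.null(dilutionRate)) {
    if (is.null(doublingTime))
      stop("one of 'dilutionRate' or 'doublingTime' is required")
    dilutionRate <- log(2) / doublingTime
  }
  new("ChemostatConfig", dilutionRate = as.numeric(dilutionRate),
      inflowConc = as.numeric(inflowConc),
      inoculumLive = as.numeric(inoculumLive),
      inoculumDead = as.numeric(inoculumDead),
      initialNutrient = as.numeric(initialNutrient),
      initialProduct = as.numeric(initialProduct))
}

#' Two-strain community configuration
#'
#' A closed, well-mixed patch of two obligately cross-feeding strains. Strain
#' 1 consumes metabolite A and releases metabolite B; strain 2 consumes B and
#' releases A.
#'
#' @slot phenotype1,phenotype2 [StrainPhenotype-class] objects
#' @slot N1,N2 initial abundances (cells/ml); >= 0
#' @slot A0,B0 initial metabolite pools (uM); >= 0
#' @export
setClass("CommunityConfig",
  representation(phenotype1 = "StrainPhenotype", phenotype2 = "StrainPhenotype",
                 N1 = "numeric", N2 = "numeric", A0 = "numeric",
                 B0 = "numeric"),
  prototype(N1 = 1e5, N2 = 1e5, A0 = 0, B0 = 0))

setValidity("CommunityConfig", function(object) {
  msg <- character()
  for (s in c("N1", "N2", "A0", "B0")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v < 0)
      msg <- c(msg, sprintf("'%s' must be a single finite value >= 0", s))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a community configuration
#'
#' @param phenotype1 strain 1 phenotype (consumes A, releases B)
#' @param phenotype2 strain 2 phenotype (consumes B, releases A)
#' @param N1,N2 initial abundances (cells/ml)
#' @param A0,B0 initial metabolite pools (uM)
#' @return a [CommunityConfig-class] object
#' @export
CommunityConfig <- function(phenotype1, phenotype2, N1 = 1e5, N2 = 1e5,
                            A0 = 0, B0 = 0) {
  new("CommunityConfig", phenotype1 = phenotype1, phenotype2 = phenotype2,
      N1 = as.numeric(N1), N2 = as.numeric(N2), A0 = as.numeric(A0),
      B0 = as.numeric(B0))
}

#' Time-course container
#'
#' Holds a strictly increasing time grid (hr) and a matrix of non-negative
#' state values with one column per state variable. Specialized as
#' [ChemostatTrajectory-class] (live, dead, nutrient, product) and
#' [CommunityTrajectory-class] (N1, N2, A, B).
#'
#' @slot times numeric vector, hr, strictly increasing
#' @slot state numeric matrix, rows aligned to `times`
#' @export
setClass("Trajectory",
  representation(times = "numeric", state = "matrix"))

setValidity("Trajectory", function(object) {
  msg <- character()
  if (length(object@times) != nrow(object@state))
    msg <- c(msg, "length(times) must equal nrow(state)")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    msg <- c(msg, "'times' must be strictly increasing")
  if (any(!is.finite(object@state)))
    msg <- c(msg, "state values must be finite")
  else if (any(object@state < 0))
    msg <- c(msg, "state values must be >= 0")
  if (is.null(colnames(object@state)))
    msg <- c(msg, "state matrix must have column names")
  if (length(msg)) msg else TRUE
})

#' @rdname Trajectory-class
#' @export
setClass("ChemostatTrajectory", contains = "Trajectory")

#' @rdname Trajectory-class
#' @export
setClass("CommunityTrajectory", contains = "Trajectory")

Trajectory <- function(times, state, class = "Trajectory") {
  state <- as.matrix(state)
  new(class, times = as.numeric(times), state = state)
}

#' Chemostat exchange-ratio estimate
#'
#' The population-level exchange ratio dil * H_ss / L_0 (1/hr): dilution rate
#' times steady-state product concentration over inflow nutrient
#' concentration. At steady state with near-complete nutrient depletion this
#' equals the individual-level ratio releaseRate / consumptionPerBirth.
#'
#' @slot value the estimate (1/hr)
#' @slot dil dilution rate used (1/hr)
#' @slot Hss steady-state product concentration (uM)
#' @slot L0 inflow nutrient concentration (uM)
#' @slot replicates optional per-run values (1/hr)
#' @slot ci optional two-element confidence interval
#' @slot level confidence level of `ci`
#' @export
setClass("ExchangeRatioEstimate",
  representation(value = "numeric", dil = "numeric", Hss = "numeric",
                 L0 = "numeric", replicates = "numeric", ci = "numeric",
                 level = "numeric"),
  prototype(replicates = numeric(), ci = numeric(), level = 0.95))

setValidity("ExchangeRatioEstimate", function(object) {
  msg <- character()
  if (object@value < 0) msg <- c(msg, "'value' must be >= 0")
  expected <- object@dil * object@Hss / object@L0
  if (is.finite(expected) &&
      abs(object@value - expected) > 1e-8 * max(1, abs(expected)))
    msg <- c(msg, "'value' must equal dil * Hss / L0")
  if (length(object@ci) && length(object@ci) != 2L)
    msg <- c(msg, "'ci' must have length 2")
  if (length(msg)) msg else TRUE
})

#' Growth-rate estimate from a log-slope sliding window
#'
#' @slot rate the growth rate (1/hr): the maximum positive window slope, or 0
#'   if no window has positive slope
#' @slot windowSize number of consecutive points per window (3 or 4)
#' @slot windowStartIndex 1-based index of the first point of the winning
#'   window (NA when no growth)
#' @slot allWindowSlopes slopes of every window, in order
#' @slot noGrowth TRUE when no window had a positive slope
#' @export
setClass("GrowthRateEstimate",
  representation(rate = "numeric", windowSize = "integer",
                 windowStartIndex = "integer", allWindowSlopes = "numeric",
                 noGrowth = "logical"))

#' Bead-calibrated cytometry sample
#'
#' Event counts from one flow-cytometry acquisition into which a known volume
#' of reference beads of known stock density was spiked. Fluorescent cell
#' events count live cells, non-fluorescent cell events dead cells; densities
#' are recovered from each cell-to-bead event ratio.
#'
#' @slot fluorEvents fluorescent (live) cell events
#' @slot nonfluorEvents non-fluorescent (dead) cell events
#' @slot beadEvents bead events; must be > 0 to compute densities
#' @slot beadStockDensity beads/ml of the bead stock
#' @slot beadVolume ml of bead stock added
#' @slot sampleVolume ml of culture sample
#' @export
setClass("CytometrySample",
  representation(fluorEvents = "numeric", nonfluorEvents = "numeric",
                 beadEvents = "numeric", beadStockDensity = "numeric",
                 beadVolume = "numeric", sampleVolume = "numeric"))

setValidity("CytometrySample", function(object) {
  msg <- character()
  for (s in c("fluorEvents", "nonfluorEvents", "beadEvents")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v < 0)
      msg <- c(msg, sprintf("'%s' must be a single count >= 0", s))
  }
  for (s in c("beadStockDensity", "beadVolume", "sampleVolume")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("'%s' must be > 0", s))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a cytometry sample
#'
#' @param fluorEvents,nonfluorEvents,beadEvents event counts
#' @param beadStockDensity bead stock density (beads/ml)
#' @param beadVolume volume of bead stock added (ml)
#' @param sampleVolume culture sample volume (ml)
#' @return a [CytometrySample-class] object
#' @export
CytometrySample <- function(fluorEvents, nonfluorEvents, beadEvents,
                            beadStockDensity, beadVolume, sampleVolume) {
  new("CytometrySample", fluorEvents = as.numeric(fluorEvents),
      nonfluorEvents = as.numeric(nonfluorEvents),
      beadEvents = as.numeric(beadEvents),
      beadStockDensity = as.numeric(beadStockDensity),
      beadVolume = as.numeric(beadVolume),
      sampleVolume = as.numeric(sampleVolume))
}

#' Linear bioassay standard curve
#'
#' A fitted line through (concentration, turbidity) calibration points of a
#' yield-based bioassay, in which the final turbidity of an auxotrophic
#' tester strain increases linearly with the input concentration of the
#' assayed metabolite. Unknown concentrations are read off by inverting the
#' line; the valid range records the calibrated concentration span.
#'
#' @slot points data.frame with columns `conc_uM` and `turbidity`
#' @slot slope fitted slope (turbidity per uM); must be > 0
#' @slot intercept fitted intercept (turbidity at 0 uM)
#' @slot validRange calibrated concentration range (uM)
#' @export
setClass("StandardCurve",
  representation(points = "data.frame", slope = "numeric",
                 intercept = "numeric", validRange = "numeric"))

setValidity("StandardCurve", function(object) {
  msg <- character()
  if (nrow(object@points) < 3L)
    msg <- c(msg, "a standard curve needs at least 3 calibration points")
  if (length(object@slope) != 1L || !is.finite(object@slope) ||
      object@slope <= 0)
    msg <- c(msg, "'slope' must be a single finite value > 0")
  if (length(object@validRange) != 2L)
    msg <- c(msg, "'validRange' must have length 2")
  if (length(msg)) msg else TRUE
})

#' Fold-change estimate with confidence interval
#'
#' @slot point point estimate of the fold change (dimensionless)
#' @slot ci two-element confidence interval (lo, hi)
#' @slot level confidence level
#' @export
setClass("FoldChangeEstimate",
  representation(point = "numeric", ci = "numeric", level = "numeric"))

setValidity("FoldChangeEstimate", function(object) {
  msg <- character()
  if (object@point <= 0) msg <- c(msg, "'point' must be > 0")
  if (length(object@ci) != 2L) msg <- c(msg, "'ci' must have length 2")
  else {
    tol <- 1e-8 * max(1, object@point)
    if (object@ci[1] > object@point + tol ||
        object@ci[2] < object@point - tol)
      msg <- c(msg, "'ci' must bracket 'point'")
    if (any(object@ci <= 0)) msg <- c(msg, "'ci' must be positive")
  }
  if (object@level <= 0 || object@level >= 1)
    msg <- c(msg, "'level' must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Observational noise specification for the synthetic-data generators
#'
#' @slot multiplicativeCV coefficient of variation of lognormal
#'   multiplicative noise applied to continuous signals; 0 disables it
#' @slot countNoise apply Poisson noise to event counts
#' @slot seed integer seed; every generator is deterministic given its seed
#' @export
setClass("NoiseSpec",
  representation(multiplicativeCV = "numeric", countNoise = "logical",
                 seed = "integer"),
  prototype(multiplicativeCV = 0, countNoise = TRUE, seed = 1L))

setValidity("NoiseSpec", function(object) {
  if (object@multiplicativeCV < 0) "'multiplicativeCV' must be >= 0" else TRUE
})

#' Construct a noise specification
#'
#' @param multiplicativeCV coefficient of variation of multiplicative
#'   lognormal noise (0 = noiseless)
#' @param countNoise logical; Poisson-sample event counts
#' @param seed integer seed
#' @return a [NoiseSpec-class] object
#' @export
NoiseSpec <- function(multiplicativeCV = 0, countNoise = TRUE, seed = 1L) {
  new("NoiseSpec", multiplicativeCV = as.numeric(multiplicativeCV),
      countNoise = as.logical(countNoise), seed = as.integer(seed))
}
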