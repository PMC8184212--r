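## ODE right-hand sides and integration wrappers.
##
## State conventions: cell densities in cells/ml, metabolite concentrations
## in uM. Per-cell fluxes (fmol/cell/hr) times density (cells/ml) give
## fmol/ml/hr; multiplying by .UM_PER_FMOL_ML (1e-6) converts to uM/hr.

.integrate <- function(y, times, func, parms, label) {
  sol <- try(deSolve::lsoda(y = y, times = times, func = func, parms = parms,
                            rtol = 1e-8, atol = 1e-10), silent = TRUE)
  if (inherits(sol, "try-error") || nrow(sol) < length(times) ||
      any(!is.finite(sol))) {
    stop(sprintf("ODE integration failed for %s with parameters: %s", label,
                 paste(names(parms), signif(unlist(parms), 4), sep = "=",
                       collapse = ", ")))
  }
  state <- sol[, -1, drop = FALSE]
  # metabolite pools can graze zero; clip integrator overshoot
  state[state < 0] <- 0
  state
}

.checkGrid <- function(tGrid) {
  if (length(tGrid) < 2L || tGrid[1] != 0 || any(diff(tGrid) <= 0))
    stop("'tGrid' must start at 0 and be strictly increasing")
}

#' Simulate a single-strain nutrient-limited chemostat
#'
#' Integrates the dynamics of one auxotrophic strain growing in a chemostat
#' supplied with its required nutrient at concentration L0 and dilution rate
#' dil, while releasing its overproduced metabolite:
#' \deqn{dN/dt = (b(L) - d - dil) N}
#' \deqn{dD/dt = d N - dil D}
#' \deqn{dL/dt = dil (L_0 - L) - c\, b(L) N u}
#' \deqn{dH/dt = r N u - dil H}
#' with N live and D dead densities (cells/ml), L the residual nutrient and H
#' the released product (uM), b(L) Moser kinetics, c the consumption per
#' birth, r the per-cell release rate, and u = 1e-6 uM per fmol/ml. At steady
#' state nutrient mass balance holds: dil L0 = dil L_ss + c b(L_ss) N_ss u.
#'
#' @param cfg a [ChemostatConfig-class]
#' @param phen a [StrainPhenotype-class]
#' @param tGrid output times (hr), starting at 0, strictly increasing
#' @return a [ChemostatTrajectory-class] with state columns `live_per_ml`,
#'   `dead_per_ml`, `nutrient_uM`, `product_uM`
#' @examples
#' cfg <- ChemostatConfig(doublingTime = 6, inflowConc = 20, inoculumLive = 1e5)
#' phen <- StrainPhenotype(releaseRate = 0.3, consumptionPerBirth = 3,
#'                         kinetics = MoserParams(0.44, 1, 2))
#' traj <- simulateChemostat(cfg, phen, seq(0, 60, by = 0.5))
#' @export
simulateChemostat <- function(cfg, phen, tGrid) {
  stopifnot(is(cfg, "ChemostatConfig"), is(phen, "StrainPhenotype"))
  validObject(cfg); validObject(phen)
  .checkGrid(tGrid)
  parms <- list(dil = cfg@dilutionRate, L0 = cfg@inflowConc,
                bMax = phen@kinetics@bMax, KL = phen@kinetics@KL,
                n = phen@kinetics@n, c = phen@consumptionPerBirth,
                r = phen@releaseRate, d = phen@deathRate)
  rhs <- function(t, y, p) {
    L <- max(y[3], 0)
    b <- p$bMax * L^p$n / (p$KL^p$n + L^p$n)
    if (L == 0) b <- 0
    uptake <- p$c * b * y[1] * .UM_PER_FMOL_ML
    list(c(N = (b - p$d - p$dil) * y[1],
           D = p$d * y[1] - p$dil * y[2],
           L = p$dil * (p$L0 - L) - uptake,
           H = p$r * y[1] * .UM_PER_FMOL_ML - p$dil * y[4]))
  }
  y0 <- c(N = cfg@inoculumLive, D = cfg@inoculumDead,
          L = cfg@initialNutrient, H = cfg@initialProduct)
  state <- .integrate(y0, tGrid, rhs, parms, "simulateChemostat")
  colnames(state) <- c("live_per_ml", "dead_per_ml", "nutrient_uM",
                       "product_uM")
  Trajectory(tGrid, state, "ChemostatTrajectory")
}

#' Analytic chemostat steady state
#'
#' Closed-form steady state of the chemostat model for a surviving
#' population: the residual nutrient satisfies b(L_ss) = d + dil (inverted
#' from the Moser law), live density follows from nutrient mass balance, dead
#' density from the death/washout balance, and the product plateau from
#' release/washout balance, H_ss = r N_ss u / dil.
#'
#' @inheritParams simulateChemostat
#' @return named list with `nutrient_uM`, `live_per_ml`, `dead_per_ml`,
#'   `product_uM`; NULL when the strain cannot sustain b = d + dil (washout)
#' @export
chemostatSteadyState <- function(cfg, phen) {
  stopifnot(is(cfg, "ChemostatConfig"), is(phen, "StrainPhenotype"))
  k <- phen@kinetics
  target <- phen@deathRate + cfg@dilutionRate
  if (target >= k@bMax) return(NULL)
  Lss <- k@KL * (target / (k@bMax - target))^(1 / k@n)
  if (Lss >= cfg@inflowConc) return(NULL)
  b <- target
  Nss <- cfg@dilutionRate * (cfg@inflowConc - Lss) /
    (phen@consumptionPerBirth * b * .UM_PER_FMOL_ML)
  Dss <- phen@deathRate * Nss / cfg@dilutionRate
  Hss <- phen@releaseRate * Nss * .UM_PER_FMOL_ML / cfg@dilutionRate
  list(nutrient_uM = Lss, live_per_ml = Nss, dead_per_ml = Dss,
       product_uM = Hss)
}

#' Simulate a closed two-strain cross-feeding community
#'
#' Integrates a well-mixed closed patch in which strain 1 consumes metabolite
#' A and releases B while strain 2 consumes B and releases A:
#' \deqn{dN_1/dt = (b_1(A) - d_1) N_1, \quad dN_2/dt = (b_2(B) - d_2) N_2}
#' \deqn{dA/dt = r_2 N_2 u - c_1 b_1(A) N_1 u, \quad
#'       dB/dt = r_1 N_1 u - c_2 b_2(B) N_2 u}
#' When both pools stay supply-limited (half-saturation constants small
#' relative to the quasi-steady pool levels) and the geometric-mean rate
#' sqrt((r_1/c_2)(r_2/c_1)) lies below both strains' bMax - d, the late-time
#' log-slope of total abundance approaches [communitySteadyGrowth()].
#'
#' @param cfg a [CommunityConfig-class]
#' @param tGrid output times (hr), starting at 0, strictly increasing
#' @return a [CommunityTrajectory-class] with state columns `N1_per_ml`,
#'   `N2_per_ml`, `A_uM`, `B_uM`
#' @export
simulateCommunity <- function(cfg, tGrid) {
  stopifnot(is(cfg, "CommunityConfig"))
  validObject(cfg)
  .checkGrid(tGrid)
  p1 <- cfg@phenotype1; p2 <- cfg@phenotype2
  parms <- list(b1 = p1@kinetics@bMax, K1 = p1@kinetics@KL, n1 = p1@kinetics@n,
                c1 = p1@consumptionPerBirth, r1 = p1@releaseRate,
                d1 = p1@deathRate,
                b2 = p2@kinetics@bMax, K2 = p2@kinetics@KL, n2 = p2@kinetics@n,
                c2 = p2@consumptionPerBirth, r2 = p2@releaseRate,
                d2 = p2@deathRate)
  rhs <- function(t, y, p) {
    A <- max(y[3], 0); B <- max(y[4], 0)
    bA <- p$b1 * A^p$n1 / (p$K1^p$n1 + A^p$n1); if (A == 0) bA <- 0
    bB <- p$b2 * B^p$n2 / (p$K2^p$n2 + B^p$n2); if (B == 0) bB <- 0
    u <- .UM_PER_FMOL_ML
    list(c(N1 = (bA - p$d1) * y[1],
           N2 = (bB - p$d2) * y[2],
           A = p$r2 * y[2] * u - p$c1 * bA * y[1] * u,
           B = p$r1 * y[1] * u - p$c2 * bB * y[2] * u))
  }
  y0 <- c(N1 = cfg@N1, N2 = cfg@N2, A = cfg@A0, B = cfg@B0)
  state <- .integrate(y0, tGrid, rhs, parms, "simulateCommunity")
  colnames(state) <- c("N1_per_ml", "N2_per_ml", "A_uM", "B_uM")
  Trajectory(tGrid, state, "CommunityTrajectory")
}

#' Simulate two genotypes competing in one chemostat
#'
#' Integrates two live compartments sharing a single limiting nutrient pool
#' under dilution (no cross-feeding between them):
#' \deqn{dN_A/dt = (b_A(L) - d_A - dil) N_A, \quad
#'       dN_B/dt = (b_B(L) - d_B - dil) N_B}
#' \deqn{dL/dt = dil (L_0 - L) - (c_A b_A(L) N_A + c_B b_B(L) N_B) u}
#' After transients the genotype with the higher net birth rate at the common
#' residual nutrient rises monotonically in frequency.
#'
#' @param cfg a [ChemostatConfig-class]; `inoculumLive` is used for genotype A
#'   and `inoculumDead` is ignored — pass inocula via `inoculumA`/`inoculumB`
#' @param phenA,phenB [StrainPhenotype-class] objects for the two genotypes
#' @param tGrid output times (hr)
#' @param inoculumA,inoculumB initial densities (cells/ml); default both to
#'   `cfg@inoculumLive / 2`
#' @return a [Trajectory-class] with state columns `liveA_per_ml`,
#'   `liveB_per_ml`, `nutrient_uM`
#' @export
simulateCompetition <- function(cfg, phenA, phenB, tGrid,
                                inoculumA = cfg@inoculumLive / 2,
                                inoculumB = cfg@inoculumLive / 2) {
  stopifnot(is(cfg, "ChemostatConfig"), is(phenA, "StrainPhenotype"),
            is(phenB, "StrainPhenotype"))
  .checkGrid(tGrid)
  if (inoculumA < 0 || inoculumB < 0) stop("inocula must be >= 0")
  parms <- list(dil = cfg@dilutionRate, L0 = cfg@inflowConc,
                bA = phenA@kinetics@bMax, KA = phenA@kinetics@KL,
                nA = phenA@kinetics@n, cA = phenA@consumptionPerBirth,
                dA = phenA@deathRate,
                bB = phenB@kinetics@bMax, KB = phenB@kinetics@KL,
                nB = phenB@kinetics@n, cB = phenB@consumptionPerBirth,
                dB = phenB@deathRate)
  rhs <- function(t, y, p) {
    L <- max(y[3], 0)
    bA <- p$bA * L^p$nA / (p$KA^p$nA + L^p$nA); if (L == 0) bA <- 0
    bB <- p$bB * L^p$nB / (p$KB^p$nB + L^p$nB); if (L == 0) bB <- 0
    u <- .UM_PER_FMOL_ML
    list(c(NA_ = (bA - p$dA - p$dil) * y[1],
           NB_ = (bB - p$dB - p$dil) * y[2],
           L = p$dil * (p$L0 - L) - (p$cA * bA * y[1] + p$cB * bB * y[2]) * u))
  }
  y0 <- c(NA_ = inoculumA, NB_ = inoculumB, L = cfg@initialNutrient)
  state <- .integrate(y0, tGrid, rhs, parms, "simulateCompetition")
  colnames(state) <- c("liveA_per_ml", "liveB_per_ml", "nutrient_uM")
  Trajectory(tGrid, state, "Trajectory")
}
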