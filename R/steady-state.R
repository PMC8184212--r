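#' Steady-state community growth rate
#'
#' In an obligate two-strain cross-feeding community, once growth is limited
#' by the partner-supplied metabolites, both strains (and so the whole
#' community) settle onto a common exponential growth rate equal to the
#' geometric mean of the two strains' exchange ratios:
#' \deqn{g = \sqrt{(r_1/c_1)(r_2/c_2)}}
#' where \eqn{r_i} is strain i's release rate and \eqn{c_i} its
#' consumption-per-birth of the partner-supplied metabolite. This is the
#' dominant eigenvalue of the supply-limited linear system
#' dN1/dt = (r2/c1') N2 ... equivalently of the 2x2 matrix with the two
#' cross-feeding rates off-diagonal, and is symmetric in the two strains.
#'
#' @param phen1,phen2 [StrainPhenotype-class] objects for the two strains
#' @return growth rate, 1/hr
#' @examples
#' a <- StrainPhenotype(releaseRate = 0.48, consumptionPerBirth = 3)
#' b <- StrainPhenotype(releaseRate = 0.20, consumptionPerBirth = 2)
#' communitySteadyGrowth(a, b)  # sqrt(0.16 * 0.10)
#' @seealso [communitySteadyRatio()], [simulateCommunity()]
#' @export
communitySteadyGrowth <- function(phen1, phen2) {
  stopifnot(is(phen1, "StrainPhenotype"), is(phen2, "StrainPhenotype"))
  sqrt(exchangeRatioOf(phen1) * exchangeRatioOf(phen2))
}

#' Steady-state abundance ratio of the two strains
#'
#' The dominant eigenvector of the supply-limited linear system fixes the
#' strain composition: N1/N2 = sqrt((r2/c1) / (r1/c2)), i.e. the strain whose
#' partner supplies generously (relative to its own demand) ends up more
#' abundant. Swapping the arguments inverts the ratio.
#'
#' @param phen1 phenotype of strain 1 (consumes what strain 2 releases)
#' @param phen2 phenotype of strain 2
#' @return N1/N2, dimensionless
#' @export
communitySteadyRatio <- function(phen1, phen2) {
  stopifnot(is(phen1, "StrainPhenotype"), is(phen2, "StrainPhenotype"))
  # strain 1 grows at (r2/c1) N2 / N1; equal growth fixes the composition
  sqrt((phen2@releaseRate / phen1@consumptionPerBirth) /
       (phen1@releaseRate / phen2@consumptionPerBirth))
}
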