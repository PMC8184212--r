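# Shared fixtures: small, fast phenotypes/configs used across tests.

fastKinetics <- function(KL = 0.1) MoserParams(bMax = 0.44, KL = KL, n = 2)

ancestorPhen <- function(KL = 0.5)
  StrainPhenotype(releaseRate = 0.30, consumptionPerBirth = 3,
                  kinetics = fastKinetics(KL))

mutantPhen <- function(KL = 0.5)
  StrainPhenotype(releaseRate = 0.48, consumptionPerBirth = 3,
                  kinetics = fastKinetics(KL))

partnerPhen <- function(KL = 0.5)
  StrainPhenotype(releaseRate = 0.20, consumptionPerBirth = 2,
                  kinetics = fastKinetics(KL))

designChemostat <- function()
  ChemostatConfig(dilutionRate = log(2) / 11, inflowConc = 21,
                  inoculumLive = 1e5)

# independent brute-force OLS slope over one window, via stats::lm
lmWindowSlope <- function(times, y, idx) {
  unname(coef(lm(y[idx] ~ times[idx]))[2])
}

randomPhenotype <- function() {
  StrainPhenotype(releaseRate = runif(1, 0.05, 2),
                  consumptionPerBirth = runif(1, 0.5, 5),
                  kinetics = MoserParams(runif(1, 0.2, 1), runif(1, 0.1, 5),
                                         runif(1, 0.8, 3)),
                  deathRate = 0)
}
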