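#' Exchange ratio from chemostat steady-state measurements
#'
#' The population-level exchange ratio of a strain in a nutrient-limited
#' chemostat is \eqn{dil \cdot H_{ss} / L_0}: dilution rate times the
#' steady-state concentration of the released product, divided by the inflow
#' concentration of the consumed nutrient. At steady state with near-complete
#' nutrient depletion this population-level measure equals the
#' individual-level ratio releaseRate / consumptionPerBirth.
#'
#' When per-replicate (dil, Hss) pairs are supplied, the returned estimate
#' carries the replicate values and a t-based confidence interval on their
#' mean.
#'
#' @param dil dilution rate(s), 1/hr
#' @param Hss steady-state product concentration(s), uM; recycled against
#'   `dil`
#' @param L0 inflow nutrient concentration (uM), > 0; fixed across replicates
#' @param level confidence level for the replicate CI (default 0.95)
#' @return an [ExchangeRatioEstimate-class]; with replicates, `value` is the
#'   replicate mean
#' @examples
#' exchangeRatio(dil = log(2) / 6, Hss = 18, L0 = 20)
#' @export
exchangeRatio <- function(dil, Hss, L0, level = 0.95) {
  if (length(L0) != 1L || !is.finite(L0) || L0 <= 0)
    stop("'L0' must be a single value > 0")
  if (any(dil < 0) || any(Hss < 0)) stop("'dil' and 'Hss' must be >= 0")
  vals <- dil * Hss / L0
  if (length(vals) == 1L) {
    new("ExchangeRatioEstimate", value = vals, dil = dil, Hss = Hss, L0 = L0,
        replicates = numeric(), ci = numeric(), level = level)
  } else {
    ci <- if (stats::sd(vals) > 0) {
      tt <- stats::t.test(vals, conf.level = level)
      as.numeric(tt$conf.int)
    } else rep(mean(vals), 2)
    # effective Hss consistent with the replicate-mean value at the mean dil
    new("ExchangeRatioEstimate", value = mean(vals), dil = mean(dil),
        Hss = mean(vals) * L0 / mean(dil),
        L0 = L0, replicates = vals, ci = ci, level = level)
  }
}

#' Dilution-rate / flow-rate arithmetic
#'
#' `flowRateForDoubling()` gives the pump flow rate (ml/hr) that makes a
#' culture of the given volume turn over at the target doubling time:
#' volume * ln(2) / T. `dilutionFromDoubling()` and `doublingFromDilution()`
#' convert between doubling time (hr) and dilution rate (1/hr) via
#' dil = ln(2)/T.
#'
#' @param doublingTime target doubling time T (hr), > 0
#' @param volume culture volume (ml), > 0
#' @return flow rate in ml/hr
#' @examples
#' flowRateForDoubling(8, volume = 19)   # ~1.646 ml/hr
#' dilutionFromDoubling(6)               # ln(2)/6
#' @export
flowRateForDoubling <- function(doublingTime, volume) {
  if (any(doublingTime <= 0) || any(volume <= 0))
    stop("'doublingTime' and 'volume' must be > 0")
  volume * log(2) / doublingTime
}

#' @rdname flowRateForDoubling
#' @export
dilutionFromDoubling <- function(doublingTime) {
  if (any(doublingTime <= 0)) stop("'doublingTime' must be > 0")
  log(2) / doublingTime
}

#' @rdname flowRateForDoubling
#' @param dilutionRate dilution rate (1/hr), > 0
#' @export
doublingFromDilution <- function(dilutionRate) {
  if (any(dilutionRate <= 0)) stop("'dilutionRate' must be > 0")
  log(2) / dilutionRate
}
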