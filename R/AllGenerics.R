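#' Exchange ratio of a strain phenotype
#'
#' A strain's exchange ratio is its benefit supply rate per intake benefit:
#' per-cell release rate of the overproduced metabolite divided by the amount
#' of partner-supplied metabolite consumed per cell birth. Units 1/hr.
#'
#' @param object a [StrainPhenotype-class]
#' @return numeric, 1/hr
#' @export
setGeneric("exchangeRatioOf", function(object) standardGeneric("exchangeRatioOf"))

#' @rdname exchangeRatioOf
#' @export
setMethod("exchangeRatioOf", "StrainPhenotype", function(object) {
  object@releaseRate / object@consumptionPerBirth
})

#' Accessors for trajectory objects
#'
#' `trajTimes()` returns the time grid (hr); `trajState()` the state matrix;
#' `stateVar()` one named state column.
#'
#' @param object a [Trajectory-class]
#' @param name column name of the state variable
#' @return numeric vector or matrix
#' @export
setGeneric("trajTimes", function(object) standardGeneric("trajTimes"))

#' @rdname trajTimes
#' @export
setGeneric("trajState", function(object) standardGeneric("trajState"))

#' @rdname trajTimes
#' @export
setGeneric("stateVar", function(object, name) standardGeneric("stateVar"))

#' @rdname trajTimes
#' @export
setMethod("trajTimes", "Trajectory", function(object) object@times)

#' @rdname trajTimes
#' @export
setMethod("trajState", "Trajectory", function(object) object@state)

#' @rdname trajTimes
#' @export
setMethod("stateVar", "Trajectory", function(object, name) {
  if (!name %in% colnames(object@state))
    stop(sprintf("no state variable '%s'; available: %s", name,
                 paste(colnames(object@state), collapse = ", ")))
  object@state[, name]
})

#' @describeIn trajTimes number of time points
#' @export
setMethod("length", "Trajectory", function(x) length(x@times))

#' Coerce a trajectory to a data.frame
#'
#' Produces the tabular form used for CSV output: a `time_hr` column followed
#' by one column per state variable.
#'
#' @param x a [Trajectory-class]
#' @param row.names,optional,... ignored, present for the generic
#' @return a data.frame
#' @export
as.data.frame.Trajectory <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  data.frame(time_hr = x@times, as.data.frame(x@state), check.names = FALSE)
}

setMethod("show", "MoserParams", function(object) {
  cat(sprintf("MoserParams: bMax = %.4g /hr, KL = %.4g uM, n = %.4g\n",
              object@bMax, object@KL, object@n))
})

setMethod("show", "StrainPhenotype", function(object) {
  cat(sprintf(paste0(
    "StrainPhenotype\n",
    "  releaseRate:         %.4g fmol/cell/hr\n",
    "  consumptionPerBirth: %.4g fmol/cell\n",
    "  exchange ratio:      %.4g /hr\n",
    "  deathRate:           %.4g /hr\n"),
    object@releaseRate, object@consumptionPerBirth, exchangeRatioOf(object),
    object@deathRate))
  cat("  kinetics: ")
  show(object@kinetics)
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("%s: %d time points over [%.3g, %.3g] hr\n", class(object),
              length(object@times), min(object@times), max(object@times)))
  cat(sprintf("  state variables: %s\n",
              paste(colnames(object@state), collapse = ", ")))
})

setMethod("show", "ExchangeRatioEstimate", function(object) {
  cat(sprintf("ExchangeRatioEstimate: %.4g /hr (dil %.4g /hr, Hss %.4g uM, L0 %.4g uM)\n",
              object@value, object@dil, object@Hss, object@L0))
  if (length(object@replicates))
    cat(sprintf("  %d replicates, mean %.4g /hr\n", length(object@replicates),
                mean(object@replicates)))
  if (length(object@ci) == 2L)
    cat(sprintf("  %.0f%% CI [%.4g, %.4g]\n", 100 * object@level,
                object@ci[1], object@ci[2]))
})

setMethod("show", "GrowthRateEstimate", function(object) {
  if (object@noGrowth)
    cat("GrowthRateEstimate: no growth (no window with positive slope)\n")
  else
    cat(sprintf("GrowthRateEstimate: %.4g /hr (window of %d starting at point %d)\n",
                object@rate, object@windowSize, object@windowStartIndex))
})

setMethod("show", "StandardCurve", function(object) {
  cat(sprintf("StandardCurve: turbidity = %.4g + %.4g * conc_uM (%d points, %.4g-%.4g uM)\n",
              object@intercept, object@slope, nrow(object@points),
              object@validRange[1], object@validRange[2]))
})

setMethod("show", "FoldChangeEstimate", function(object) {
  cat(sprintf("FoldChangeEstimate: %.4g-fold (%.0f%% CI [%.4g, %.4g])\n",
              object@point, 100 * object@level, object@ci[1], object@ci[2]))
})
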