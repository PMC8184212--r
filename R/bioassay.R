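#' Fit a linear bioassay standard curve
#'
#' Ordinary least-squares fit of turbidity against known input concentration
#' for a yield-based bioassay, whose tester-strain final turbidity increases
#' linearly with the assayed metabolite concentration.
#'
#' @param conc known concentrations (uM), >= 3 points
#' @param turbidity measured final turbidities, same length
#' @return a [StandardCurve-class]
#' @examples
#' fitStandardCurve(c(0, 10, 20, 40), 0.05 + 0.02 * c(0, 10, 20, 40))
#' @export
fitStandardCurve <- function(conc, turbidity) {
  if (length(conc) != length(turbidity))
    stop("'conc' and 'turbidity' must have the same length")
  if (length(conc) < 3L) stop("need at least 3 calibration points")
  fit <- stats::lm(turbidity ~ conc)
  co <- stats::coef(fit)
  if (!is.finite(co[2]) || co[2] <= 0)
    stop("fitted slope must be > 0; calibration points do not increase with concentration")
  new("StandardCurve",
      points = data.frame(conc_uM = conc, turbidity = turbidity),
      slope = unname(co[2]), intercept = unname(co[1]),
      validRange = range(conc))
}

#' Read a concentration off a bioassay standard curve
#'
#' Inverts the fitted line: concentration = (turbidity - intercept) / slope.
#' Turbidities outside the calibrated range (including values below the
#' intercept, which invert to negative concentrations) still return the
#' inverted value but carry a warning and an `extrapolated` flag, since the
#' assay's behavior outside calibration (e.g. plate saturation) is not
#' characterized.
#'
#' @param curve a [StandardCurve-class]
#' @param turbidity measured turbidity (scalar or vector)
#' @return numeric concentration(s), uM, with attribute `extrapolated`
#'   (logical vector)
#' @examples
#' sc <- fitStandardCurve(c(0, 10, 20, 40), 0.05 + 0.02 * c(0, 10, 20, 40))
#' bioassayConcentration(sc, 0.45)  # 20 uM
#' @export
bioassayConcentration <- function(curve, turbidity) {
  stopifnot(is(curve, "StandardCurve"))
  validObject(curve)
  conc <- (turbidity - curve@intercept) / curve@slope
  lo <- curve@validRange[1]; hi <- curve@validRange[2]
  outside <- conc < lo | conc > hi
  if (any(outside))
    warning(sprintf(
      "%d turbidity value(s) invert outside the calibrated range [%.4g, %.4g] uM",
      sum(outside), lo, hi))
  attr(conc, "extrapolated") <- outside
  conc
}
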