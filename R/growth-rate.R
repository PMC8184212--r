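#' Growth rate from an exponentially growing signal time course
#'
#' Estimates a growth rate from a fluorescence (or other abundance-
#' proportional) time course the way the microscopy growth assay does:
#' intensities are normalized to their time-zero value, the ordinary
#' least-squares slope of ln(normalized signal) against time is computed over
#' every run of `window` consecutive points (overlapping windows), and the
#' maximal slope is taken as the growth rate. If no window has a positive
#' slope the estimate is 0, flagged as no growth.
#'
#' @param times observation times (hr), strictly increasing
#' @param intensities positive signal values, same length as `times`
#' @param window number of consecutive points per window: 3 (default) or 4
#' @return a [GrowthRateEstimate-class]
#' @examples
#' t <- seq(0, 10, by = 0.5)
#' growthRateFromTimeseries(t, 100 * exp(0.2 * t))  # rate 0.2 /hr
#' @export
growthRateFromTimeseries <- function(times, intensities, window = 3) {
  window <- as.integer(window)
  if (!window %in% c(3L, 4L)) stop("'window' must be 3 or 4")
  n <- length(times)
  if (length(intensities) != n)
    stop("'times' and 'intensities' must have the same length")
  if (n < window)
    stop(sprintf("need at least %d points, got %d", window, n))
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (any(!is.finite(intensities)) || any(intensities <= 0))
    stop("'intensities' must be finite and > 0")

  y <- log(intensities / intensities[1])
  nWin <- n - window + 1L
  slopes <- vapply(seq_len(nWin), function(i) {
    idx <- i:(i + window - 1L)
    tt <- times[idx]; yy <- y[idx]
    sum((tt - mean(tt)) * (yy - mean(yy))) / sum((tt - mean(tt))^2)
  }, numeric(1))

  if (all(slopes <= 0)) {
    new("GrowthRateEstimate", rate = 0, windowSize = window,
        windowStartIndex = NA_integer_, allWindowSlopes = slopes,
        noGrowth = TRUE)
  } else {
    best <- which.max(slopes)
    new("GrowthRateEstimate", rate = slopes[best], windowSize = window,
        windowStartIndex = best, allWindowSlopes = slopes, noGrowth = FALSE)
  }
}
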