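#' Steady-state growth rate of a growing community time course
#'
#' Fits the exponential (log-linear) regime of a total-abundance time course,
#' excluding an initial lag: consecutive log-slopes
#' \eqn{s_i = (\ln y_{i+1} - \ln y_i)/(t_{i+1} - t_i)} are computed, the
#' longest trailing run of points whose consecutive slopes all lie within
#' `relTol` (relative) of the run mean is taken as the steady regime, and the
#' growth rate is the OLS slope of ln(abundance) against time over that
#' window.
#'
#' @param times observation times (hr), >= 4 points
#' @param abundances total abundances (> 0), same length
#' @param relTol relative tolerance on consecutive slopes (default 0.15)
#' @return list with `rate` (1/hr), `window` (integer indices of the fitted
#'   points)
#' @examples
#' t <- 0:12
#' y <- c(rep(1e4, 4), 1e4 * exp(0.1 * (4:12 - 3)))
#' communityGrowthRate(t, y)$rate  # 0.1
#' @export
communityGrowthRate <- function(times, abundances, relTol = 0.15) {
  n <- length(times)
  if (length(abundances) != n)
    stop("'times' and 'abundances' must have the same length")
  if (n < 4L) stop("need at least 4 points")
  if (any(abundances <= 0)) stop("'abundances' must be > 0")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")

  ly <- log(abundances)
  slopes <- diff(ly) / diff(times)

  # longest trailing run of consecutive slopes consistent with their mean
  window <- NULL
  for (start in seq_len(n - 2L)) {
    s <- slopes[start:(n - 1L)]
    m <- mean(s)
    if (m > 0 && all(abs(s - m) <= relTol * abs(m))) {
      window <- start:n
      break
    }
  }
  if (is.null(window) || length(window) < 3L)
    stop("no steady exponential regime of >= 3 points found")

  tt <- times[window]; yy <- ly[window]
  rate <- sum((tt - mean(tt)) * (yy - mean(yy))) / sum((tt - mean(tt))^2)
  list(rate = rate, window = window)
}
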