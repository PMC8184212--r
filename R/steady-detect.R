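#' Detect a steady-state plateau in a time course
#'
#' Declares steady state using a trailing-window relative criterion with a
#' drift guard. The trailing `windowFraction` of the points defines the
#' candidate plateau mean m. The onset is the earliest point from which
#' (i) every later value stays within `relTol` (relative) of m, and
#' (ii) the total drift across the candidate steady segment — the OLS slope
#' of value against time multiplied by the segment duration — is within
#' `relTol` of m. The drift guard rejects slow monotone ramps whose local
#' fluctuations are small but which never flatten. The steady segment must
#' extend at least one point beyond the trailing window.
#'
#' `relTol` should be commensurate with the observation noise: for a series
#' with multiplicative noise of coefficient of variation cv, a band of
#' roughly 3-4 cv keeps plateau points inside while the trailing-window mean
#' still averages the noise away.
#'
#' @param times observation times (hr)
#' @param values observed values, same length
#' @param windowFraction fraction of points in the trailing window
#'   (default 0.3)
#' @param relTol relative tolerance (default 0.10)
#' @return list with `reached` (logical), `tOnset` (hr, NA if not reached),
#'   `mean` (plateau mean, NA if not reached)
#' @examples
#' detectSteadyState(0:9, c(5, 3, 2, 1.5, rep(1.2, 6)))
#' @export
detectSteadyState <- function(times, values, windowFraction = 0.3,
                              relTol = 0.10) {
  n <- length(times)
  if (length(values) != n) stop("'times' and 'values' must match in length")
  if (n < 5L) stop("need at least 5 points")
  if (windowFraction <= 0 || windowFraction > 1)
    stop("'windowFraction' must be in (0, 1]")

  w <- max(2L, ceiling(windowFraction * n))
  m <- mean(values[(n - w + 1L):n])
  scale <- max(abs(m), .Machine$double.eps)
  band <- abs(values - m) <= relTol * scale

  notReached <- list(reached = FALSE, tOnset = NA_real_, mean = NA_real_)
  segmentOK <- function(i) {
    idx <- i:n
    tt <- times[idx]; vv <- values[idx]
    slope <- sum((tt - mean(tt)) * (vv - mean(vv))) / sum((tt - mean(tt))^2)
    abs(slope) * (times[n] - times[i]) <= relTol * scale
  }
  for (i in seq_len(max(n - w, 1L))) {
    if (all(band[i:n]) && segmentOK(i))
      return(list(reached = TRUE, tOnset = times[i], mean = m))
  }
  notReached
}
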