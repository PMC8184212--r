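#' Fit Moser kinetics to (concentration, rate) measurements
#'
#' Nonlinear least-squares fit of \eqn{b(L) = b_{max} L^n / (K_L^n + L^n)}
#' to measured growth rates across nutrient concentrations, via
#' Levenberg-Marquardt with box constraints. Initial guesses: bMax at 1.1x
#' the largest observed rate, KL at the concentration of half-maximal rate
#' (linear interpolation), n = 2; bounds bMax in (0, 10], KL in (0, 1e4],
#' n in [0.5, 10]. These give robust convergence on saturating data.
#'
#' @param conc nutrient concentrations (uM)
#' @param rate measured growth rates (1/hr), same length; replicate
#'   concentrations allowed
#' @return a list with `params` ([MoserParams-class]), `rss` (residual sum of
#'   squares), `se` (named approximate standard errors, NA when the Jacobian
#'   is singular), `fit` (the underlying `nls`-like object)
#' @examples
#' p <- MoserParams(0.44, 2, 2)
#' L <- c(0.5, 1, 2, 4, 8, 16, 32, 64)
#' fitMoser(L, moserRate(L, p))$params
#' @export
fitMoser <- function(conc, rate) {
  if (length(conc) != length(rate))
    stop("'conc' and 'rate' must have the same length")
  keep <- is.finite(conc) & is.finite(rate)
  conc <- conc[keep]; rate <- rate[keep]
  if (length(unique(conc)) < 4L)
    stop("need measurements at >= 4 distinct concentrations")
  if (diff(range(rate)) == 0)
    stop("degenerate data: all rates identical")

  ord <- order(conc)
  Ls <- conc[ord]; bs <- rate[ord]
  bMax0 <- 1.1 * max(bs)
  halfIdx <- which(bs >= max(bs) / 2)[1]
  KL0 <- if (halfIdx > 1) {
    # interpolate the concentration where the rate first crosses half-max
    stats::approx(bs[(halfIdx - 1):halfIdx], Ls[(halfIdx - 1):halfIdx],
                  xout = max(bs) / 2, ties = "ordered")$y
  } else Ls[1]
  if (!is.finite(KL0) || KL0 <= 0) KL0 <- stats::median(Ls)
  start <- c(bMax = min(bMax0, 10), KL = min(KL0, 1e4), n = 2)

  df <- data.frame(L = conc, b = rate)
  fit <- try(minpack.lm::nlsLM(
    b ~ bMax * L^n / (KL^n + L^n), data = df, start = as.list(start),
    lower = c(bMax = 1e-8, KL = 1e-8, n = 0.5),
    upper = c(bMax = 10, KL = 1e4, n = 10),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error"))
    stop(sprintf(
      "Moser fit did not converge (start: bMax=%.4g, KL=%.4g, n=%.4g): %s",
      start["bMax"], start["KL"], start["n"], attr(fit, "condition")$message))

  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, 3),
                                                     names(est)))
  list(params = MoserParams(est["bMax"], est["KL"], est["n"]),
       rss = sum(stats::residuals(fit)^2), se = se, fit = fit)
}
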