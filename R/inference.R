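#' Predicted partner growth-rate change from an exchange-ratio fold change
#'
#' Because the community (and partner) steady-state growth rate is the
#' geometric mean of the two strains' exchange ratios, multiplying one
#' strain's exchange ratio by `fold` while the partner's stays fixed
#' multiplies the steady-state growth rate by sqrt(fold). The relative
#' change is therefore
#' \deqn{\sqrt{fold} - 1.}
#' A 1.6-fold exchange-ratio increase predicts a ~26\% faster partner.
#'
#' @param fold exchange-ratio fold change, > 0
#' @return relative growth-rate change (dimensionless; 0.26 means +26\%)
#' @examples
#' predictPartnerGrowthChange(1.6)  # 0.2649
#' @export
predictPartnerGrowthChange <- function(fold) {
  if (any(!is.finite(fold)) || any(fold <= 0)) stop("'fold' must be > 0")
  sqrt(fold) - 1
}

#' Fold change between two replicate groups, with confidence interval
#'
#' Point estimate: ratio of group arithmetic means (mutant over ancestor).
#' Confidence interval: a Welch t-interval on the difference of log-means,
#' exponentiated back to the fold scale. Because the square root is monotone,
#' a CI on the predicted partner growth change is obtained by applying
#' [predictPartnerGrowthChange()] to the interval endpoints.
#'
#' @param mutant,ancestor replicate measurements (> 0), >= 2 each
#' @param level confidence level (default 0.95)
#' @return a [FoldChangeEstimate-class]
#' @examples
#' foldChangeCI(c(0.15, 0.17, 0.16), c(0.10, 0.11, 0.095))
#' @export
foldChangeCI <- function(mutant, ancestor, level = 0.95) {
  if (length(mutant) < 2L || length(ancestor) < 2L)
    stop("need at least 2 replicates per group")
  if (any(mutant <= 0) || any(ancestor <= 0))
    stop("all replicate values must be > 0")
  point <- mean(mutant) / mean(ancestor)
  lx <- log(mutant); ly <- log(ancestor)
  d <- mean(lx) - mean(ly)
  vx <- stats::var(lx) / length(lx); vy <- stats::var(ly) / length(ly)
  se <- sqrt(vx + vy)
  if (se == 0) {
    ci <- rep(exp(d), 2)
    # zero-variance groups: geometric and arithmetic means coincide
    point <- exp(d)
  } else {
    # Welch-Satterthwaite degrees of freedom
    dof <- (vx + vy)^2 /
      (vx^2 / (length(lx) - 1L) + vy^2 / (length(ly) - 1L))
    q <- stats::qt(1 - (1 - level) / 2, dof)
    ci <- exp(d + c(-1, 1) * q * se)
    ci <- c(min(ci[1], point), max(ci[2], point))
  }
  new("FoldChangeEstimate", point = point, ci = ci, level = level)
}

#' Two-group comparison with F-test-gated t-test
#'
#' Mirrors the testing scheme used for replicate exchange ratios and
#' community growth rates: a two-sided F-test of variance equality at
#' `alphaVar` decides between the pooled-variance two-tailed t-test (variance
#' equality not rejected) and Welch's unequal-variance t-test.
#'
#' @param x,y replicate values, >= 2 each
#' @param alphaVar significance level of the variance F-test (default 0.05)
#' @return list with `p` (two-sided t-test p-value), `method` ("pooled" or
#'   "welch"), `pVar` (F-test p-value), `t` (t statistic)
#' @examples
#' compareGroups(c(1, 2, 3), c(11, 12, 13))
#' @export
compareGroups <- function(x, y, alphaVar = 0.05) {
  if (length(x) < 2L || length(y) < 2L)
    stop("need at least 2 replicates per group")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    # degenerate but well-defined: identical-variance branch
    if (mean(x) == mean(y))
      return(list(p = 1, method = "pooled", pVar = 1, t = 0))
    return(list(p = 0, method = "pooled", pVar = 1, t = Inf))
  }
  pVar <- stats::var.test(x, y)$p.value
  if (pVar >= alphaVar) {
    tt <- stats::t.test(x, y, var.equal = TRUE)
    list(p = tt$p.value, method = "pooled", pVar = pVar,
         t = unname(tt$statistic))
  } else {
    tt <- stats::t.test(x, y, var.equal = FALSE)
    list(p = tt$p.value, method = "welch", pVar = pVar,
         t = unname(tt$statistic))
  }
}
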