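#' Moser birth rate
#'
#' Evaluates the saturating growth law
#' \eqn{b(L) = b_{max} L^n / (K_L^n + L^n)} at nutrient concentration L.
#' b(0) = 0, b(K_L) = b_max / 2, and b is monotone non-decreasing and bounded
#' above by b_max.
#'
#' @param L nutrient concentration (uM), scalar or vector, >= 0
#' @param params a [MoserParams-class] object
#' @return birth rate(s), 1/hr
#' @examples
#' p <- MoserParams(bMax = 0.44, KL = 1, n = 2)
#' moserRate(1, p)    # half-maximal: 0.22
#' moserRate(3, p)    # 0.396
#' @export
moserRate <- function(L, params) {
  stopifnot(is(params, "MoserParams"))
  if (any(!is.finite(L)) || any(L < 0))
    stop("'L' must be finite and >= 0")
  Ln <- L^params@n
  # 0^n with L = 0 is 0 for n > 0, so the 0/0 guard only fires when both are 0
  r <- params@bMax * Ln / (params@KL^params@n + Ln)
  r[L == 0] <- 0
  r
}
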