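#' Accumulated generations from OD readings across serial dilutions
#'
#' Reconstructs the accumulated population density of a periodically diluted
#' culture and converts it to generations. If reading k was taken after
#' applying fold-dilutions \eqn{f_1, ..., f_{k-1}} (each applied after the
#' preceding reading), the accumulated density is
#' \eqn{OD_k \prod_{j<k} f_j}, and generations elapsed are
#' \eqn{\log_2} of the accumulated density over its initial value.
#'
#' @param od optical density readings (> 0), in chronological order
#' @param foldDilution fold-dilution applied after each reading (>= 1);
#'   same length as `od` (the last entry is unused) or length(od) - 1
#' @return numeric vector of accumulated generations at each reading
#'   (first element 0)
#' @examples
#' # reading 0.1, 10x dilution, next reading 0.04: accumulated 0.4, 2 gens
#' generationsFromOD(c(0.1, 0.04), c(10))
#' @export
generationsFromOD <- function(od, foldDilution = rep(1, length(od))) {
  if (any(!is.finite(od)) || any(od <= 0)) stop("'od' must be > 0")
  if (length(foldDilution) == length(od) - 1L)
    foldDilution <- c(foldDilution, 1)
  if (length(foldDilution) != length(od))
    stop("'foldDilution' must match 'od' in length (or be one shorter)")
  if (any(foldDilution < 1)) stop("'foldDilution' must be >= 1")
  cumFold <- c(1, cumprod(foldDilution)[-length(foldDilution)])
  accumulated <- od * cumFold
  log2(accumulated / accumulated[1])
}
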