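#' Absolute cell densities from bead-calibrated cytometry counts
#'
#' Converts event counts to absolute densities using the spiked-in reference
#' beads: each cell-to-bead event ratio scales the number of beads added
#' (stock density x bead volume) per sample volume,
#' \deqn{live = \frac{fluor}{beads} \cdot
#'       \frac{beadStock \cdot beadVol}{sampleVol}}
#' and analogously for dead cells from the non-fluorescent events.
#'
#' @param sample a [CytometrySample-class]
#' @return named numeric vector with `live_per_ml` and `dead_per_ml`
#' @examples
#' s <- CytometrySample(fluorEvents = 2000, nonfluorEvents = 100,
#'                      beadEvents = 500, beadStockDensity = 1e6,
#'                      beadVolume = 0.05, sampleVolume = 1)
#' cytometryDensities(s)  # live 2e5 /ml
#' @export
cytometryDensities <- function(sample) {
  stopifnot(is(sample, "CytometrySample"))
  validObject(sample)
  if (sample@beadEvents <= 0)
    stop("bead events must be > 0 to calibrate densities")
  scale <- sample@beadStockDensity * sample@beadVolume / sample@sampleVolume
  c(live_per_ml = sample@fluorEvents / sample@beadEvents * scale,
    dead_per_ml = sample@nonfluorEvents / sample@beadEvents * scale)
}
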