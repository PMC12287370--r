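# Deterministic transforms applied to flow-cytometry median
# fluorescence intensities (MFI) before plotting: isotype noise
# correction, log10 with a floor, and DMSO-anchored differences.

#' Noise-correct raw MFI against an isotype control
#'
#' Subtracts the isotype-control signal from the raw MFI. The result
#' may legitimately be non-positive (marker at or below background);
#' such values are flagged via the \code{"flagged"} attribute rather
#' than clipped.
#'
#' @param raw,isotype Finite MFI values in arbitrary units (vectorized).
#' @return \code{raw - isotype}, with attribute \code{flagged} marking
#'   entries \code{<= 0}.
#' @export
noise_correct <- function(raw, isotype) {
  if (any(!is.finite(raw)) || any(!is.finite(isotype))) {
    stop("MFI values must be finite")
  }
  out <- raw - isotype
  attr(out, "flagged") <- out <= 0
  out
}

#' Log10-transform corrected MFI with a positivity floor
#'
#' \code{log10(max(corrected, floor))}; the floor (default 1 AU) keeps
#' background-subtracted values that dip to or below zero finite.
#'
#' @param corrected Noise-corrected MFI (vectorized).
#' @param floor Positive floor in AU.
#' @return log10-transformed values.
#' @export
log10_mfi <- function(corrected, floor = 1) {
  if (!is.finite(floor) || floor <= 0) stop("floor must be positive")
  log10(pmax(as.numeric(corrected), floor))
}

#' Express corrected MFI relative to the DMSO control
#'
#' Linear difference of noise-corrected MFI, so the DMSO control maps
#' to exactly zero and treatment-induced decreases are negative.
#'
#' @param corrected_drug,corrected_dmso Finite corrected MFI values
#'   (vectorized).
#' @return \code{corrected_drug - corrected_dmso}.
#' @export
relative_to_dmso <- function(corrected_drug, corrected_dmso) {
  if (any(!is.finite(corrected_drug)) || any(!is.finite(corrected_dmso))) {
    stop("MFI values must be finite")
  }
  as.numeric(corrected_drug) - as.numeric(corrected_dmso)
}
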