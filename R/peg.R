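#' PEG-8000 concentration for a target water potential
#'
#' Germination at reduced water availability is imposed with polyethylene
#' glycol 8000 solutions. Concentrations are interpolated linearly between
#' the calibration anchors used in the reference design at 20 degrees C:
#' 0 MPa = 0 g/L, -0.1 MPa = 73.7 g/L, -0.5 MPa = 195 g/L,
#' -0.75 MPa = 250 g/L, -1.5 MPa = 376 g/L. No extrapolation outside
#' `[-1.5, 0]` MPa; the calibration is valid at 20 degrees C only (the
#' temperature-dependent Michel relation is not implemented).
#'
#' @param psi Water potential in MPa, in `[-1.5, 0]` (vector).
#' @return Grams of PEG-8000 per litre of solution.
#' @seealso [psi_from_peg()]
#' @examples
#' peg_concentration(c(0, -0.5, -0.75))
#' @export
peg_concentration <- function(psi) {
  if (any(!is.finite(psi)) || any(psi < -1.5) || any(psi > 0)) {
    abort("`psi` must lie in [-1.5, 0] MPa (no extrapolation).",
          class = "germresp_range_error")
  }
  approx(peg_anchors$psi, peg_anchors$conc, xout = psi, method = "linear")$y
}

#' Water potential of a PEG-8000 solution
#'
#' Inverse of [peg_concentration()]: linear interpolation through the same
#' anchors, mapping a concentration in g/L back to water potential in MPa.
#'
#' @param conc PEG-8000 concentration in g/L, in `[0, 376]` (vector).
#' @return Water potential in MPa.
#' @export
psi_from_peg <- function(conc) {
  if (any(!is.finite(conc)) || any(conc < 0) || any(conc > 376)) {
    abort("`conc` must lie in [0, 376] g/L (no extrapolation).",
          class = "germresp_range_error")
  }
  approx(peg_anchors$conc, peg_anchors$psi, xout = conc, method = "linear")$y
}

peg_anchors <- data.frame(
  psi = c(-1.5, -0.75, -0.5, -0.1, 0),
  conc = c(376, 250, 195, 73.7, 0)
)
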