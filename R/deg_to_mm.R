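#' Convert a visual angle to a retinal distance
#'
#' Converts degrees of visual angle to millimetres on the retina using a
#' Bennett-style schematic-eye scaling in which the conversion factor grows
#' linearly with axial length:
#' \deqn{q = 0.01306 \cdot (AL - 1.82) \ \mathrm{mm/deg}}
#' so that \code{mm = angle_deg * q}.  The 1.82 mm offset is the distance
#' between the eye's second principal plane and the cornea in the schematic
#' eye; at the emmetropic axial length of 24.00 mm one degree subtends
#' 0.2897 mm of retina.
#'
#' @param angle_deg visual angle in degrees (vectorised).
#' @param axial_length_mm ocular axial length in mm; must lie in
#'   \code{[20, 30]}, the plausible adult range.
#' @return retinal distance in mm, same length as \code{angle_deg}.
#' @examples
#' deg_to_mm(1, 24)            # 0.2897 mm
#' deg_to_mm(2.8, 23.98)       # width of a 2.8 degree AOSLO field
#' @export
deg_to_mm <- function(angle_deg, axial_length_mm) {
  if (!is.numeric(angle_deg) || !is.numeric(axial_length_mm))
    stopf("angle_deg and axial_length_mm must be numeric")
  if (any(!is.finite(axial_length_mm)) ||
      any(axial_length_mm < 20) || any(axial_length_mm > 30))
    stopf("axial_length_mm outside the plausible range [20, 30] mm")
  angle_deg * 0.01306 * (axial_length_mm - 1.82)
}

# mm of retina per degree for a given axial length
mm_per_deg <- function(axial_length_mm) deg_to_mm(1, axial_length_mm)
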