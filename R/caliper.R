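#' Tumor volume from caliper measurements
#'
#' Converts vernier-caliper length and width readings to an ellipsoid-style
#' tumor volume, `0.5 * length * width^2`, the standard convention for
#' subcutaneous flank tumors.
#'
#' By convention the width is the shorter of the two perpendicular diameters.
#' A reading with `width > length` usually indicates the two calipers were
#' recorded in the wrong order; the function warns but computes with the
#' values as given, so data-entry errors stay visible rather than being
#' silently repaired.
#'
#' @param length Tumor length in mm (the longer diameter). Vectorized.
#' @param width Tumor width in mm (the shorter diameter). Vectorized.
#'
#' @return Tumor volume(s) in mm^3.
#' @examples
#' caliper_volume(10, 10) # 500
#' caliper_volume(20, 10) # 1000
#' @export
caliper_volume <- function(length, width) {
  if (any(length < 0, na.rm = TRUE) || any(width < 0, na.rm = TRUE)) {
    abort("caliper_volume(): length and width must be nonnegative.",
          class = "tumorgri_validation_error")
  }
  if (any(width > length, na.rm = TRUE)) {
    warn(paste0(
      "caliper_volume(): width > length for ",
      sum(width > length, na.rm = TRUE),
      " measurement(s); caliper convention may be swapped. ",
      "Computing with the values as given."
    ))
  }
  0.5 * length * width^2
}
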