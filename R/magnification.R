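# Ocular magnification correction (Littman / modified Bennett).

#' Lateral magnification correction factor from axial length
#'
#' The modified Bennett relation gives the retinal image scale as
#' q = 0.01306 (AL - 1.82) mm/deg, so for a device calibrated to an assumed
#' axial length the true-to-nominal lateral scale factor is
#' \deqn{f = (AL_{subject} - 1.82) / (AL_{assumed} - 1.82).}
#' Lengths scale by `f`, areas by `f^2`; the factor is exactly 1 when the
#' subject matches the device assumption and increases strictly with subject
#' axial length.  A user-supplied function of (axial length, refraction,
#' keratometry) can replace the default via `custom_q`.
#'
#' @param subject_axial_length_mm measured axial length of the eye (mm).
#' @param assumed_axial_length_mm axial length assumed by the device
#'   calibration (default 23.95 mm; override per device).
#' @param custom_q optional function(axial_length_mm, refraction_D,
#'   keratometry_mm) returning a relative image scale; applied to both eyes'
#'   parameters to form the ratio.
#' @param refraction_D,keratometry_mm forwarded to `custom_q` when supplied.
#' @return scalar factor multiplying the nominal micrometers-per-pixel scale.
#' @export
magnification_factor <- function(subject_axial_length_mm,
                                 assumed_axial_length_mm = 23.95,
                                 custom_q = NULL,
                                 refraction_D = NA_real_,
                                 keratometry_mm = NA_real_) {
  if (subject_axial_length_mm <= 2 || assumed_axial_length_mm <= 2)
    stop("axial lengths must exceed 2 mm")
  if (!is.null(custom_q)) {
    num <- custom_q(subject_axial_length_mm, refraction_D, keratometry_mm)
    den <- custom_q(assumed_axial_length_mm, NA_real_, NA_real_)
    if (!is.finite(den) || den <= 0) stop("custom_q gave nonpositive scale")
    return(num / den)
  }
  k <- 1.82
  den <- assumed_axial_length_mm - k
  if (den <= 0) stop("nonpositive denominator in magnification formula")
  (subject_axial_length_mm - k) / den
}
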