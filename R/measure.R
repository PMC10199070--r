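# End-to-end per-eye measurement: quality gate -> average -> binarize ->
# magnification-correct -> densities + FAZ metrics.

#' Measure vessel density and FAZ morphometrics for one eye
#'
#' Runs the full quantification chain on one eye's frames: signal-strength
#' quality gate, frame averaging, binarization at the configured threshold,
#' magnification correction of the pixel scale via the eye's axial length,
#' skeleton-based densities and FAZ shape metrics.
#'
#' @param frames list of [en_face_angiogram()] frames (>= 1).
#' @param config list overriding defaults: `binarize_threshold` (0.5),
#'   `min_signal` (50), `assumed_axial_length_mm` (23.95), `max_bridge_px`
#'   (2), `align_frames` (FALSE), `measure_faz` (TRUE).
#' @return list with `density` (perfusion_density, vessel_density),
#'   `faz` ([faz_shape_metrics()] or NULL), `scale_um_per_px`,
#'   `magnification`, and `qc` (pass flag, reasons, frames used).
#' @export
measure_eye <- function(frames, config = list()) {
  cfg <- modifyList(list(
    binarize_threshold = 0.5,
    min_signal = 50,
    assumed_axial_length_mm = 23.95,
    max_bridge_px = 2L,
    align_frames = FALSE,
    measure_faz = TRUE
  ), config)
  if (inherits(frames, "en_face_angiogram")) frames <- list(frames)
  if (length(frames) == 0L) stop("at least one frame required")

  pass <- vapply(frames, passes_quality, logical(1), min_signal = cfg$min_signal)
  if (!any(pass)) {
    return(list(
      density = NULL, faz = NULL, scale_um_per_px = NA_real_,
      magnification = NA_real_,
      qc = list(pass = FALSE,
                reason = "poor quality retinal imaging: no frame with signal strength above gate",
                frames_used = 0L, frames_total = length(frames))
    ))
  }
  used <- frames[pass]
  avg <- average_frames(used, align = cfg$align_frames)
  mask <- binarize(avg, cfg$binarize_threshold)
  mag <- magnification_factor(avg$axial_length_mm,
                              cfg$assumed_axial_length_mm)
  mask$scale_um_per_px <- mask$scale_um_per_px * mag

  dens <- vessel_density(mask)
  faz <- NULL
  qc_notes <- character(0)
  if (isTRUE(cfg$measure_faz)) {
    faz <- tryCatch({
      reg <- extract_faz(mask, cfg$max_bridge_px)
      if (reg$touches_border) qc_notes <- c(qc_notes, "FAZ touches raster border")
      faz_shape_metrics(reg, mask$scale_um_per_px)
    }, error = function(e) {
      qc_notes <<- c(qc_notes, conditionMessage(e))
      NULL
    })
  }
  list(
    density = list(perfusion_density = dens$perfusion_density,
                   vessel_density = dens$vessel_density),
    faz = faz,
    scale_um_per_px = mask$scale_um_per_px,
    magnification = mag,
    qc = list(pass = TRUE, reason = if (length(qc_notes)) qc_notes else NULL,
              frames_used = sum(pass), frames_total = length(frames))
  )
}
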