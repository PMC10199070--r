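#' Construct an en-face angiogram object
#'
#' An `en_face_angiogram` is a grayscale raster of vessel probabilities in
#' \[0, 1\] together with the per-eye acquisition metadata needed downstream:
#' the nominal scan width (mm), the device signal strength (0--100, may be
#' absent), the subject's axial length (mm) and, optionally, refraction and
#' keratometry (carried but unused by the default magnification correction).
#'
#' @param pixels numeric matrix with values in \[0, 1\].
#' @param nominal_scan_width_mm positive scalar, e.g. 3.0 or 3.1.
#' @param signal_strength scalar in \[0, 100\] or `NA` if not recorded.
#' @param axial_length_mm positive scalar (mm).
#' @param refraction_D,keratometry_mm optional scalars, carried in metadata.
#' @param eye_id optional identifier used in logs and output tables.
#' @return An object of class `en_face_angiogram`.
#' @export
en_face_angiogram <- function(pixels, nominal_scan_width_mm = 3.0,
                              signal_strength = NA_real_,
                              axial_length_mm = 23.95,
                              refraction_D = NA_real_,
                              keratometry_mm = NA_real_,
                              eye_id = NA_character_) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0L)
    stop("pixels must be a non-empty numeric matrix")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stop("pixel values must lie in [0, 1] with no NA")
  if (!is.numeric(nominal_scan_width_mm) || nominal_scan_width_mm <= 0)
    stop("nominal_scan_width_mm must be positive")
  if (axial_length_mm <= 0) stop("axial_length_mm must be positive")
  structure(list(
    pixels = pixels,
    nominal_scan_width_mm = nominal_scan_width_mm,
    signal_strength = signal_strength,
    axial_length_mm = axial_length_mm,
    refraction_D = refraction_D,
    keratometry_mm = keratometry_mm,
    eye_id = eye_id
  ), class = "en_face_angiogram")
}

#' @export
print.en_face_angiogram <- function(x, ...) {
  cat(sprintf("<en_face_angiogram> %d x %d px, %.2f mm scan, AL %.2f mm, SS %s\n",
              nrow(x$pixels), ncol(x$pixels), x$nominal_scan_width_mm,
              x$axial_length_mm,
              ifelse(is.na(x$signal_strength), "absent",
                     format(x$signal_strength))))
  invisible(x)
}

#' Write a grayscale raster as plain-text PGM (P2)
#'
#' Values in \[0, 1\] are rescaled to 16-bit integers (maxval 65535).  PGM is
#' used as the primary interchange format because it is plain text; PNG is
#' supported through [write_png_raster()] when the `png` package is installed.
#'
#' @param pixels numeric matrix in \[0, 1\].
#' @param path output file path.
#' @param maxval integer maximum gray value (default 65535).
#' @export
write_pgm <- function(pixels, path, maxval = 65535L) {
  stopifnot(is.matrix(pixels), maxval >= 1)
  q <- round(pmin(pmax(pixels, 0), 1) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(q), nrow(q)), as.character(maxval)), con)
  # one raster row per line
  writeLines(apply(q, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' Read a PGM image (P2 ASCII or P5 binary) rescaled to \[0, 1\]
#'
#' @param path file path.
#' @return numeric matrix with values in \[0, 1\].
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  # token reader skipping whitespace and '#' comments
  next_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || ch == "") {
        if (nzchar(tok)) return(tok) else stop("truncated PGM header")
      }
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "" || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) return(tok)
      } else tok <- paste0(tok, ch)
    }
  }
  w <- suppressWarnings(as.integer(next_token()))
  h <- suppressWarnings(as.integer(next_token()))
  maxval <- suppressWarnings(as.integer(next_token()))
  if (anyNA(c(w, h, maxval)) || w < 1L || h < 1L || maxval < 1L)
    stop("malformed PGM header: ", path)
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = w * h, quiet = TRUE)
  } else {
    bytes <- if (maxval > 255L) 2L else 1L
    raw <- readBin(con, "integer", n = w * h, size = bytes,
                   signed = FALSE, endian = "big")
    vals <- raw
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) / maxval
}

#' Write a raster as 16-bit grayscale PNG (requires the `png` package)
#' @param pixels numeric matrix in \[0, 1\].
#' @param path output path.
#' @export
write_png_raster <- function(pixels, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is not installed; use write_pgm()")
  png::writePNG(pmin(pmax(pixels, 0), 1), path)
  invisible(path)
}

#' Read a grayscale angiogram image (PGM or PNG) with its JSON sidecar
#'
#' The sidecar `<image>.json` carries acquisition metadata
#' (`axial_length_mm`, `signal_strength`, `nominal_scan_width_mm`, ...).
#'
#' @param path image path (`.pgm` or `.png`).
#' @return An [en_face_angiogram()] object.
#' @export
read_angiogram <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    pgm = read_pgm(path),
    png = {
      if (!requireNamespace("png", quietly = TRUE))
        stop("the 'png' package is required to read PNG")
      p <- png::readPNG(path)
      if (length(dim(p)) == 3L) p <- p[, , 1L]
      p
    },
    stop("unsupported image extension: ", ext)
  )
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  meta <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else list()
  en_face_angiogram(
    pixels = px,
    nominal_scan_width_mm = meta$nominal_scan_width_mm %||% 3.0,
    signal_strength = meta$signal_strength %||% NA_real_,
    axial_length_mm = meta$axial_length_mm %||% 23.95,
    refraction_D = meta$refraction_D %||% NA_real_,
    keratometry_mm = meta$keratometry_mm %||% NA_real_,
    eye_id = meta$eye_id %||% tools::file_path_sans_ext(basename(path))
  )
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
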