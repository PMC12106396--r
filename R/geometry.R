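# Planck constant times speed of light in keV * Angstrom, for
# photon-energy <-> wavelength conversion.
.hc_keV_A <- 12.3984

#' Transmission-geometry calibration for a 2D scattering detector
#'
#' Bundles the beamline parameters needed to map detector pixels to
#' momentum transfer q: X-ray wavelength, sample-to-detector (camera)
#' length, pixel pitch, detector shape and beam center.
#'
#' Pixel coordinates are zero-based: pixel `(0, 0)` is the first row and
#' column, and the geometric center of an `n`-pixel axis is `(n - 1) / 2`.
#' The beam center may be fractional and must lie within
#' `[-0.5, dim - 0.5]` on each axis.
#'
#' @param wavelength_A X-ray wavelength in Angstrom. Exactly one of
#'   `wavelength_A` and `beam_energy_keV` must be supplied.
#' @param beam_energy_keV photon energy in keV; converted to wavelength
#'   via `lambda = hc / E` with `hc = 12.3984` keV A.
#' @param camera_length_mm sample-to-detector distance in mm.
#' @param pixel_size_um pixel pitch in micrometres, length 1 (square
#'   pixels) or 2 as `c(x, y)` (column, row directions).
#' @param detector_shape integer pair `c(rows, cols)`.
#' @param beam_center beam center as `c(x, y)` = (column, row) in
#'   zero-based, possibly fractional pixels. Defaults to the geometric
#'   image center (a message records the default being used).
#' @return An object of class `waxs_geometry`.
#' @examples
#' waxs_geometry(beam_energy_keV = 15, camera_length_mm = 693.9,
#'               pixel_size_um = 172, detector_shape = c(1475, 1679))
#' @export
waxs_geometry <- function(wavelength_A = NULL, beam_energy_keV = NULL,
                          camera_length_mm,
                          pixel_size_um = 172,
                          detector_shape = c(1475L, 1679L),
                          beam_center = NULL) {
  if (is.null(wavelength_A) && is.null(beam_energy_keV)) {
    stop("supply either `wavelength_A` or `beam_energy_keV`", call. = FALSE)
  }
  if (is.null(wavelength_A)) {
    if (beam_energy_keV <= 0) stop("beam energy must be positive", call. = FALSE)
    wavelength_A <- energy_to_wavelength(beam_energy_keV)
  }
  if (length(pixel_size_um) == 1L) pixel_size_um <- rep(pixel_size_um, 2L)
  detector_shape <- as.integer(detector_shape)
  stopifnot(length(detector_shape) == 2L, length(pixel_size_um) == 2L)
  if (wavelength_A <= 0 || camera_length_mm <= 0 || any(pixel_size_um <= 0) ||
      any(detector_shape < 1L)) {
    stop("wavelength, camera length, pixel sizes and shape must be positive",
         call. = FALSE)
  }
  if (is.null(beam_center)) {
    beam_center <- c((detector_shape[2L] - 1) / 2, (detector_shape[1L] - 1) / 2)
    message(sprintf(
      "beam center not supplied; defaulting to geometric center (x = %.1f, y = %.1f) px",
      beam_center[1L], beam_center[2L]))
  }
  if (length(beam_center) != 2L ||
      beam_center[1L] < -0.5 || beam_center[1L] > detector_shape[2L] - 0.5 ||
      beam_center[2L] < -0.5 || beam_center[2L] > detector_shape[1L] - 0.5) {
    stop("beam center must lie on the detector ([-0.5, dim - 0.5] each axis)",
         call. = FALSE)
  }
  structure(list(
    wavelength_A = wavelength_A,
    camera_length_mm = camera_length_mm,
    pixel_size_x_um = pixel_size_um[1L],
    pixel_size_y_um = pixel_size_um[2L],
    detector_shape = detector_shape,
    beam_center_x = beam_center[1L],
    beam_center_y = beam_center[2L]
  ), class = "waxs_geometry")
}

#' @export
print.waxs_geometry <- function(x, ...) {
  cat(sprintf(
    "WAXS geometry: lambda = %.4f A, camera = %.1f mm, pixels %g x %g um,\n  detector %d x %d px, beam center (x = %.2f, y = %.2f) px\n",
    x$wavelength_A, x$camera_length_mm, x$pixel_size_x_um, x$pixel_size_y_um,
    x$detector_shape[1L], x$detector_shape[2L], x$beam_center_x, x$beam_center_y))
  invisible(x)
}

#' Convert photon energy to X-ray wavelength and back
#'
#' `lambda = hc / E` with `hc = 12.3984` keV A, so 15 keV gives the
#' 0.8266 A wavelength of a typical WAXS beamline setting.
#'
#' @param energy_keV photon energy (keV).
#' @param wavelength_A wavelength (Angstrom).
#' @return wavelength in Angstrom (resp. energy in keV).
#' @export
energy_to_wavelength <- function(energy_keV) {
  stopifnot(all(energy_keV > 0))
  .hc_keV_A / energy_keV
}

#' @rdname energy_to_wavelength
#' @export
wavelength_to_energy <- function(wavelength_A) {
  stopifnot(all(wavelength_A > 0))
  .hc_keV_A / wavelength_A
}

#' Read a calibration geometry from a YAML or JSON config file
#'
#' The config is a flat key-value document with keys `wavelength_A` or
#' `beam_energy_keV`, `camera_length_mm`, `pixel_size_um` (scalar or
#' `[x, y]`), `detector_shape` (`[rows, cols]`) and optionally
#' `beam_center` (`[x, y]`, zero-based px). A list may be passed
#' directly in place of a path.
#'
#' @param config path to a `.yaml`/`.yml`/`.json` file, or a named list.
#' @return A [waxs_geometry] object.
#' @export
load_geometry <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("geometry config not found: ", config, call. = FALSE)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) stop("geometry config must be a file path or a list", call. = FALSE)
  if (is.null(config$camera_length_mm)) {
    stop("geometry config must provide `camera_length_mm`", call. = FALSE)
  }
  waxs_geometry(
    wavelength_A = config$wavelength_A,
    beam_energy_keV = config$beam_energy_keV,
    camera_length_mm = config$camera_length_mm,
    pixel_size_um = if (is.null(config$pixel_size_um)) 172 else unlist(config$pixel_size_um),
    detector_shape = if (is.null(config$detector_shape)) c(1475L, 1679L) else unlist(config$detector_shape),
    beam_center = if (is.null(config$beam_center)) NULL else unlist(config$beam_center)
  )
}

#' Construct a detector image
#'
#' @param intensity numeric matrix of counts, dimensions equal to
#'   `geometry$detector_shape`.
#' @param geometry a [waxs_geometry].
#' @param mask optional logical matrix, `TRUE` = usable pixel. By default
#'   non-finite and negative pixels (Pilatus gap sentinels) are masked out.
#' @return An object of class `detector_image` with elements `intensity`,
#'   `mask` and `geometry`.
#' @export
detector_image <- function(intensity, geometry, mask = NULL) {
  stopifnot(inherits(geometry, "waxs_geometry"), is.matrix(intensity))
  if (!identical(dim(intensity), as.integer(geometry$detector_shape))) {
    stop(sprintf("image is %d x %d but geometry expects %d x %d",
                 nrow(intensity), ncol(intensity),
                 geometry$detector_shape[1L], geometry$detector_shape[2L]),
         call. = FALSE)
  }
  if (is.null(mask)) {
    mask <- is.finite(intensity) & intensity >= 0
  } else {
    stopifnot(is.logical(mask), identical(dim(mask), dim(intensity)))
    mask <- mask & is.finite(intensity) & intensity >= 0
  }
  n_bad <- sum(!mask)
  if (n_bad > 0L) {
    message(sprintf("masked out %d pixel(s) (non-finite or negative)", n_bad))
  }
  structure(list(intensity = intensity, mask = mask, geometry = geometry),
            class = "detector_image")
}

#' @export
print.detector_image <- function(x, ...) {
  cat(sprintf("Detector image %d x %d px, %d masked-in pixels, total counts %.6g\n",
              nrow(x$intensity), ncol(x$intensity), sum(x$mask),
              sum(x$intensity[x$mask])))
  invisible(x)
}

#' Read a single-frame grayscale TIFF detector image
#'
#' Reads 32-bit float TIFFs as written by photon-counting detectors.
#' Pixels that are non-finite or negative (detector gap sentinels) are
#' masked out, not clipped; the number of masked pixels is reported.
#'
#' @param path TIFF file path.
#' @param geometry a [waxs_geometry]; the image shape must match.
#' @return A [detector_image].
#' @export
read_detector_image <- function(path, geometry) {
  if (!file.exists(path)) stop("cannot read detector image: ", path, call. = FALSE)
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) {
    stop("expected a single-frame grayscale TIFF: ", path, call. = FALSE)
  }
  detector_image(matrix(as.numeric(img), nrow(img), ncol(img)), geometry)
}

#' Write a detector image as an uncompressed 32-bit float TIFF
#'
#' Detector counts routinely exceed 1 and gaps are marked with negative
#' sentinels, so images are stored in IEEE float32 sample format (one
#' strip, little-endian). Values representable in float32 (all integer
#' counts below 2^24, and -1) round-trip exactly through
#' [read_detector_image()]. Masked-out pixels are written as -1.
#'
#' @param image a [detector_image].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_detector_image <- function(image, path) {
  stopifnot(inherits(image, "detector_image"))
  m <- image$intensity
  m[!image$mask] <- -1
  write_float_tiff(m, path)
  invisible(path)
}

# Minimal baseline TIFF encoder: single strip, uncompressed, 32-bit IEEE
# float, little-endian. Needed because the installed TIFF writers clamp
# sample values to [0, 1]; reading back goes through tiff::readTIFF.
write_float_tiff <- function(m, path) {
  stopifnot(is.matrix(m), is.numeric(m))
  h <- nrow(m); w <- ncol(m)
  con <- file(path, "wb")
  on.exit(close(con))
  n_tags <- 8L
  ifd_offset <- 8L
  data_offset <- ifd_offset + 2L + n_tags * 12L + 4L
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_offset, con, size = 4, endian = "little")
  tag <- function(id, type, count, value) {
    writeBin(as.integer(id), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) {  # SHORT: value left-justified in 4 bytes
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  writeBin(n_tags, con, size = 2, endian = "little")
  tag(256L, 4L, 1L, w)                 # ImageWidth
  tag(257L, 4L, 1L, h)                 # ImageLength
  tag(258L, 3L, 1L, 32L)               # BitsPerSample
  tag(259L, 3L, 1L, 1L)                # Compression: none
  tag(262L, 3L, 1L, 1L)                # Photometric: BlackIsZero
  tag(273L, 4L, 1L, data_offset)       # StripOffsets
  tag(279L, 4L, 1L, w * h * 4L)        # StripByteCounts
  tag(339L, 3L, 1L, 3L)                # SampleFormat: IEEE float
  writeBin(0L, con, size = 4, endian = "little")  # next IFD
  # TIFF strips are row-major; R matrices are column-major
  writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
  invisible(path)
}
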