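#' Map detector pixels to momentum transfer q
#'
#' For a pixel at zero-based `(row, col)`, the in-plane radius is
#' `R = sqrt((drow * pixel_y)^2 + (dcol * pixel_x)^2)`, the scattering
#' angle `2theta = atan(R / camera_length)` and
#' `q = 4 pi sin(theta) / lambda`.
#'
#' @param row,col zero-based pixel indices (vectorised, recycled).
#' @param geometry a [waxs_geometry].
#' @return q in 1/Angstrom (>= 0).
#' @export
pixel_to_q <- function(row, col, geometry) {
  stopifnot(inherits(geometry, "waxs_geometry"))
  dy_mm <- (row - geometry$beam_center_y) * geometry$pixel_size_y_um * 1e-3
  dx_mm <- (col - geometry$beam_center_x) * geometry$pixel_size_x_um * 1e-3
  r_mm <- sqrt(dx_mm^2 + dy_mm^2)
  theta <- atan(r_mm / geometry$camera_length_mm) / 2
  4 * pi * sin(theta) / geometry$wavelength_A
}

#' Azimuthally integrate a detector image into a 1D q-profile
#'
#' Every masked-in pixel is assigned to the radial bin
#' `round(q / q_step) * q_step`; the bin intensity is the arithmetic
#' mean of its member pixels (so profiles from different solid-angle
#' coverages stay comparable), with `n_pixels` retained for variance
#' estimation. Empty bins are dropped. With the default
#' `q_step = 0.001` the q grid is the 3-decimal summary grid.
#'
#' @param image a [detector_image].
#' @param q_step radial bin width in 1/Angstrom.
#' @return A [qprofile]. Photon conservation holds exactly:
#'   `sum(intensity * n_pixels)` equals the total masked-in counts.
#' @export
integrate_azimuthal <- function(image, q_step = 0.001) {
  stopifnot(inherits(image, "detector_image"), q_step > 0)
  if (!any(image$mask)) stop("all pixels are masked out", call. = FALSE)
  g <- image$geometry
  shp <- g$detector_shape
  rows <- matrix(0:(shp[1L] - 1L), shp[1L], shp[2L])
  cols <- matrix(0:(shp[2L] - 1L), shp[1L], shp[2L], byrow = TRUE)
  q <- pixel_to_q(rows[image$mask], cols[image$mask], g)
  idx <- round(q / q_step)
  vals <- image$intensity[image$mask]
  sums <- rowsum(vals, idx)
  counts <- rowsum(rep(1L, length(vals)), idx)
  bins <- as.numeric(rownames(sums))
  ord <- order(bins)
  qprofile(bins[ord] * q_step, (sums / counts)[ord], counts[ord],
           provenance = sprintf("azimuthal integration, q_step = %g, %d pixels",
                                q_step, length(vals)))
}

#' Smooth a profile by a centered rolling mean
#'
#' Centered moving average with an odd window; at the profile edges the
#' window truncates to the available points (so a constant profile is
#' unchanged for any window). The q grid is untouched.
#'
#' @param profile a [qprofile].
#' @param window odd integer window length, `1 <= window <= nrow(profile)`.
#' @return A smoothed [qprofile].
#' @export
rolling_mean <- function(profile, window = 5L) {
  stopifnot(inherits(profile, "qprofile"))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("`window` must be an odd integer >= 1", call. = FALSE)
  }
  n <- nrow(profile)
  if (window > n) stop("`window` exceeds profile length", call. = FALSE)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, profile$intensity))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  out <- qprofile(profile$q, (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L),
                  profile$n_pixels, provenance = attr(profile, "provenance"))
  add_provenance(out, "rolling mean, window = %d", window)
}
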