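#' Lattice d-spacing from a peak position in q
#'
#' `d = 2 pi / q`. Combined with `q = 4 pi sin(theta) / lambda` this is
#' the Bragg relation `d = lambda / (2 sin theta)`.
#'
#' @param q_center peak center in 1/Angstrom, > 0 (vectorised).
#' @return d-spacing in Angstrom.
#' @export
d_spacing <- function(q_center) {
  if (any(q_center <= 0)) stop("q must be positive", call. = FALSE)
  2 * pi / q_center
}

#' Scherrer minimum crystal domain size
#'
#' `L = K * lambda / (beta * cos(theta))`, with `K` the crystal geometry
#' parameter (0.94 for the cellulose reflections treated here), `beta`
#' the peak full width at half maximum in 2-theta radians and `theta`
#' the Bragg angle. Because peak fitting happens in q space, the
#' equivalent q-space form `L = 2 pi K / beta_q` (with
#' `beta_q = beta * 2 pi cos(theta) / lambda` from
#' `q = 4 pi sin(theta) / lambda`) is exposed as
#' [scherrer_size_q()]; the two forms agree identically.
#'
#' No instrumental-broadening correction is applied, so `L` is a lower
#' bound on the coherent domain size (a "minimum" crystal size).
#'
#' @param beta FWHM of the reflection in 2-theta radians, > 0.
#' @param theta_bragg Bragg angle in radians, in `(0, pi/2)`.
#' @param wavelength_A X-ray wavelength (Angstrom).
#' @param K crystal geometry parameter (dimensionless).
#' @return domain size L in Angstrom.
#' @export
scherrer_size <- function(beta, theta_bragg, wavelength_A, K = 0.94) {
  stopifnot(K > 0, wavelength_A > 0)
  if (any(beta <= 0)) stop("beta must be positive (finite size)", call. = FALSE)
  if (any(theta_bragg <= 0 | theta_bragg >= pi / 2)) {
    stop("Bragg angle must lie in (0, pi/2)", call. = FALSE)
  }
  K * wavelength_A / (beta * cos(theta_bragg))
}

#' @rdname scherrer_size
#' @param beta_q FWHM of the reflection in q units (1/Angstrom), > 0.
#' @export
scherrer_size_q <- function(beta_q, K = 0.94) {
  stopifnot(K > 0)
  if (any(beta_q <= 0)) stop("beta_q must be positive", call. = FALSE)
  2 * pi * K / beta_q
}

#' Convert a q-space FWHM to a 2-theta FWHM
#'
#' First-order width conversion at the peak position:
#' `beta_2theta = beta_q * lambda / (2 pi cos(theta))` where
#' `sin(theta) = q lambda / (4 pi)`.
#'
#' @param beta_q FWHM in 1/Angstrom.
#' @param q_center peak center in 1/Angstrom.
#' @param wavelength_A wavelength (Angstrom).
#' @return list with `beta_2theta` (radians) and `theta_bragg` (radians).
#' @export
fwhm_q_to_2theta <- function(beta_q, q_center, wavelength_A) {
  s <- q_center * wavelength_A / (4 * pi)
  if (any(s <= 0 | s >= 1)) {
    stop("peak center outside the physical range (0, 4 pi / lambda)",
         call. = FALSE)
  }
  theta <- asin(s)
  list(beta_2theta = beta_q * wavelength_A / (2 * pi * cos(theta)),
       theta_bragg = theta)
}

find_peak_label <- function(fit, label) {
  labs <- vapply(fit$peaks, `[[`, "", "label")
  i <- which(labs == label)
  if (length(i) != 1L) {
    stop(sprintf("fit must contain exactly one peak labelled \"%s\" (found %d)",
                 label, length(i)), call. = FALSE)
  }
  fit$peaks[[i]]
}

#' Organized-water to cellulose (200) peak ratio
#'
#' The amount of diffraction-visible ("organized") water is quantified
#' relative to the cellulose (200) reflection. By default the ratio of
#' integrated peak areas (`weight * total_area`) is used, because
#' mixture weights are the natural output of the deconvolution; a
#' height-based variant (ratio of modelled peak apex intensities) is
#' available via `method = "height"`.
#'
#' @param fit a `pv_fit` containing peaks labelled `"water"` and `"200"`.
#' @param method `"area"` (default) or `"height"`.
#' @return dimensionless ratio, >= 0.
#' @export
organized_water_ratio <- function(fit, method = c("area", "height")) {
  stopifnot(inherits(fit, "pv_fit"))
  method <- match.arg(method)
  water <- find_peak_label(fit, "water")
  p200 <- find_peak_label(fit, "200")
  if (method == "area") {
    water$weight / p200$weight
  } else {
    (water$weight * pseudo_voigt_density(water$mu, water)) /
      (p200$weight * pseudo_voigt_density(p200$mu, p200))
  }
}

#' Assemble per-diffractogram crystal metrics from a fitted mixture
#'
#' From the fitted cellulose (200) peak: the d-spacing `2 pi / mu`, the
#' Bragg angle from `sin(theta) = q lambda / (4 pi)`, the FWHM
#' converted to 2-theta, and the Scherrer minimum domain size (computed
#' in both the 2-theta and q forms, which must agree to numerical
#' precision). If the fit carries a `"water"` peak the organized-water
#' area ratio is included, otherwise it is `NA`.
#'
#' @param fit a `pv_fit` with a peak labelled `"200"`.
#' @param geometry a [waxs_geometry] (only the wavelength is used), or a
#'   numeric wavelength in Angstrom.
#' @param K Scherrer crystal geometry parameter.
#' @param replicate_id free-text identifier copied into the output.
#' @return A one-row data frame of class `crystal_metrics` with columns
#'   `replicate_id`, `d200_A`, `L200_A`, `water_ratio`, `beta_q`,
#'   `theta_bragg_rad`.
#' @export
crystal_report <- function(fit, geometry, K = 0.94, replicate_id = "") {
  stopifnot(inherits(fit, "pv_fit"))
  lambda <- if (inherits(geometry, "waxs_geometry")) geometry$wavelength_A
            else as.numeric(geometry)
  p200 <- find_peak_label(fit, "200")
  conv <- fwhm_q_to_2theta(p200$fwhm, p200$mu, lambda)
  L_2theta <- scherrer_size(conv$beta_2theta, conv$theta_bragg, lambda, K)
  L_q <- scherrer_size_q(p200$fwhm, K)
  if (abs(L_2theta - L_q) > 1e-8 * L_q) {
    stop("internal inconsistency: 2-theta and q Scherrer forms disagree",
         call. = FALSE)
  }
  has_water <- any(vapply(fit$peaks, `[[`, "", "label") == "water")
  structure(data.frame(
    replicate_id = replicate_id,
    d200_A = d_spacing(p200$mu),
    L200_A = L_q,
    water_ratio = if (has_water) organized_water_ratio(fit) else NA_real_,
    beta_q = p200$fwhm,
    theta_bragg_rad = conv$theta_bragg
  ), class = c("crystal_metrics", "data.frame"))
}
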