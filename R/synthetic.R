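# Run code under a fixed RNG seed without disturbing the caller's
# random stream: every generator is a pure function of (truth, seed).
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Ground truth for a synthetic WAXS detector image
#'
#' Describes an isotropic diffraction pattern as pseudo-Voigt rings on
#' a smooth background. The default truth mimics a conifer wood
#' diffractogram: a combined cellulose (1-10)/(110) reflection near
#' q = 1.10, the cellulose (200) reflection near q = 1.60 (d about
#' 3.93 Angstrom) and a broad organized-water hump near q = 2.00, on an
#' affine background with a wide amorphous bump. Peak areas are in
#' expected counts per unit q along the radial profile; `exposure`
#' rescales everything (peak apex counts of about 900 give a counting
#' SNR of about 30).
#'
#' @param peaks data frame with columns `label`, `mu`, `fwhm`, `eta`,
#'   `area` (absolute areas > 0).
#' @param background list with `intercept`, `slope`, `hump_amp`,
#'   `hump_mu`, `hump_fwhm` describing `b(q) = intercept + slope q +
#'   hump_amp * G(q; hump_mu, hump_fwhm)` in counts.
#' @param exposure global scale multiplying the expected counts.
#' @param seed integer RNG seed recorded in the truth.
#' @return list of class `waxs_truth`.
#' @export
waxs_truth <- function(peaks = data.frame(
                         label = c("110/1-10", "200", "water"),
                         mu = c(1.10, 1.60, 2.00),
                         fwhm = c(0.20, 0.30, 0.35),
                         eta = c(0.3, 0.3, 0.5),
                         area = c(260, 270, 110)),
                       background = list(intercept = 40, slope = -8,
                                         hump_amp = 60, hump_mu = 1.4,
                                         hump_fwhm = 1.6),
                       exposure = 1,
                       seed = 1L) {
  stopifnot(all(c("label", "mu", "fwhm", "eta", "area") %in% names(peaks)),
            all(peaks$area > 0), all(peaks$fwhm > 0), exposure > 0)
  structure(list(peaks = peaks, background = background,
                 exposure = exposure, seed = as.integer(seed)),
            class = "waxs_truth")
}

# Expected (noise-free) radial intensity of a truth at q
waxs_model_intensity <- function(truth, q) {
  bg <- truth$background
  base <- bg$intercept + bg$slope * q +
    bg$hump_amp * gauss_density(q, bg$hump_mu, bg$hump_fwhm) * bg$hump_fwhm
  peaks <- Reduce(`+`, lapply(seq_len(nrow(truth$peaks)), function(k) {
    p <- truth$peaks[k, ]
    p$area * pseudo_voigt_density(q, mu = p$mu, fwhm = p$fwhm, eta = p$eta)
  }), accumulate = FALSE)
  truth$exposure * pmax(base + peaks, 0)
}

#' Generate a synthetic isotropic WAXS detector image
#'
#' The expected intensity at each pixel is the radial model of `truth`
#' evaluated at that pixel's q (so the pattern is perfectly isotropic
#' in azimuth); observed counts are Poisson draws under the truth's
#' seed. With `noise = FALSE` the expected intensities are returned
#' directly (zero-noise mode). The truth is attached to the image as
#' attribute `"truth"` and can be written as a JSON sidecar by
#' [write_waxs_truth()].
#'
#' @param truth a [waxs_truth].
#' @param geometry a [waxs_geometry].
#' @param noise draw Poisson counting noise? Default `TRUE`.
#' @return a [detector_image] with the truth attached.
#' @export
synth_waxs_image <- function(truth, geometry, noise = TRUE) {
  stopifnot(inherits(truth, "waxs_truth"), inherits(geometry, "waxs_geometry"))
  shp <- geometry$detector_shape
  rows <- matrix(0:(shp[1L] - 1L), shp[1L], shp[2L])
  cols <- matrix(0:(shp[2L] - 1L), shp[1L], shp[2L], byrow = TRUE)
  q <- pixel_to_q(rows, cols, geometry)
  lambda <- waxs_model_intensity(truth, q)
  counts <- if (noise) {
    with_seed(truth$seed,
              matrix(stats::rpois(length(lambda), lambda), shp[1L], shp[2L]))
  } else {
    matrix(lambda, shp[1L], shp[2L])
  }
  img <- detector_image(counts + 0.0, geometry)
  attr(img, "truth") <- truth
  img
}

#' Write the truth sidecar for a synthetic image or trace
#'
#' @param truth a [waxs_truth] or [dsc_truth].
#' @param path JSON path (conventionally `<image>.truth.json`).
#' @return `path`, invisibly.
#' @export
write_waxs_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Ground truth for a synthetic DSC thermoporosimetry trace
#'
#' Plants a known partition of the sample's water over pore-size bins,
#' bulk (free) water and non-freezing water. Defaults place a
#' 10 mg-scale saturated wood sample with water split over the sub-7 nm
#' and 7-17 nm nanopore bins plus bulk water.
#'
#' @param bins data frame with `d_lo_nm`, `d_hi_nm`, `mass_mg` (water
#'   mass melting in each pore bin).
#' @param bulk_water_mg free water melting at the bulk point (mg).
#' @param nonfreezing_water_mg bound water that never freezes (mg).
#' @param mass_dry_mg oven-dry solid mass (mg).
#' @param baseline_drift_mW_K instrument baseline slope versus
#'   temperature.
#' @param peak_width_s time-width (Gaussian sigma, s) of each melting
#'   endotherm.
#' @param noise_sd_mW additive Gaussian heat-flow noise.
#' @param seed integer RNG seed.
#' @return list of class `dsc_truth`. Total water is
#'   `sum(bins$mass_mg) + bulk_water_mg + nonfreezing_water_mg`.
#' @export
dsc_truth <- function(bins = data.frame(d_lo_nm = c(0, 7),
                                        d_hi_nm = c(7, 17),
                                        mass_mg = c(1.4, 2.1)),
                      bulk_water_mg = 3.5,
                      nonfreezing_water_mg = 0.7,
                      mass_dry_mg = 3.0,
                      baseline_drift_mW_K = 0.02,
                      peak_width_s = 25,
                      noise_sd_mW = 0.01,
                      seed = 1L) {
  stopifnot(all(bins$mass_mg >= 0), bulk_water_mg >= 0,
            nonfreezing_water_mg >= 0, mass_dry_mg > 0, peak_width_s > 0)
  structure(list(bins = bins, bulk_water_mg = bulk_water_mg,
                 nonfreezing_water_mg = nonfreezing_water_mg,
                 mass_dry_mg = mass_dry_mg,
                 baseline_drift_mW_K = baseline_drift_mW_K,
                 peak_width_s = peak_width_s, noise_sd_mW = noise_sd_mW,
                 seed = as.integer(seed)),
            class = "dsc_truth")
}

#' Generate a synthetic isothermal-step DSC trace
#'
#' Builds the temperature program (1 C/min ramps between ascending
#' isothermal holds), places one Gaussian-in-time melting endotherm per
#' pore bin in the hold at the first protocol step at or above the
#' bin's Gibbs-Thomson melting temperature (taken at the bin midpoint
#' diameter), with time-integrated area `mass * Hf`, plus a bulk
#' endotherm in the first hold at or above the bulk melting point. A
#' drifting baseline and additive Gaussian noise complete the trace.
#'
#' @param truth a [dsc_truth].
#' @param protocol_C ascending isotherm temperatures (C); the last must
#'   exceed the bulk melting point.
#' @param params a [gibbs_thomson_params].
#' @param hold_s hold duration per isotherm (s).
#' @param dt_s sampling interval (s).
#' @param start_C program start temperature (C).
#' @return a [dsc_trace] with the truth attached as attribute
#'   `"truth"`.
#' @export
synth_dsc_trace <- function(truth,
                            protocol_C = default_thermo_protocol(params),
                            params = gibbs_thomson_params(),
                            hold_s = 600, dt_s = 0.5, start_C = -30) {
  stopifnot(inherits(truth, "dsc_truth"))
  if (any(diff(protocol_C) <= 0)) {
    stop("protocol temperatures must be ascending", call. = FALSE)
  }
  protocol_K <- protocol_C + 273.15
  ramp_K_s <- 1 / 60   # 1 C/min
  # temperature program
  temps <- numeric(0); times <- numeric(0); t <- 0
  level_prev <- start_C
  hold_window <- matrix(NA_real_, length(protocol_C), 2L)
  for (i in seq_along(protocol_C)) {
    ramp_dur <- (protocol_C[i] - level_prev) / ramp_K_s
    if (ramp_dur > 0) {
      tt <- seq(dt_s, ramp_dur, by = dt_s)
      times <- c(times, t + tt)
      temps <- c(temps, level_prev + tt * ramp_K_s)
      t <- t + ramp_dur
    }
    tt <- seq(dt_s, hold_s, by = dt_s)
    times <- c(times, t + tt)
    temps <- c(temps, rep(protocol_C[i], length(tt)))
    hold_window[i, ] <- c(t, t + hold_s)
    t <- t + hold_s
    level_prev <- protocol_C[i]
  }
  # melting events: (hold index, mass)
  events <- list()
  if (nrow(truth$bins)) {
    for (k in seq_len(nrow(truth$bins))) {
      if (truth$bins$mass_mg[k] <= 0) next
      d_mid <- (truth$bins$d_lo_nm[k] + truth$bins$d_hi_nm[k]) / 2
      Tm <- gibbs_thomson_temperature(d_mid, params)
      hold <- which(protocol_K >= Tm)
      if (!length(hold)) {
        stop(sprintf("bin %g-%g nm melts at %.2f K, above the protocol range",
                     truth$bins$d_lo_nm[k], truth$bins$d_hi_nm[k], Tm),
             call. = FALSE)
      }
      events[[length(events) + 1L]] <- c(min(hold), truth$bins$mass_mg[k])
    }
  }
  if (truth$bulk_water_mg > 0) {
    hold <- which(protocol_K >= params$T0_K)
    if (!length(hold)) {
      stop("no protocol step at or above the bulk melting point", call. = FALSE)
    }
    events[[length(events) + 1L]] <- c(min(hold), truth$bulk_water_mg)
  }
  hf <- truth$baseline_drift_mW_K * (temps - 0)
  for (ev in events) {
    win <- hold_window[ev[1L], ]
    center <- mean(win)
    area_J <- ev[2L] / 1000 * params$Hf_J_g
    # mW curve with time integral area_J * 1000 mJ
    hf <- hf + area_J * 1000 *
      stats::dnorm(times, center, truth$peak_width_s)
  }
  if (truth$noise_sd_mW > 0) {
    hf <- hf + with_seed(truth$seed,
                         stats::rnorm(length(hf), 0, truth$noise_sd_mW))
  }
  total_water <- sum(truth$bins$mass_mg) + truth$bulk_water_mg +
    truth$nonfreezing_water_mg
  tr <- dsc_trace(times, temps, hf,
                  mass_wet_mg = truth$mass_dry_mg + total_water,
                  mass_dry_mg = truth$mass_dry_mg)
  attr(tr, "truth") <- truth
  tr
}

#' Generate a long-format table of seeded group samples
#'
#' Draws `n` observations per group from normal (or log-normal skewed)
#' distributions with the stated means and standard deviations, for
#' exercising the group-comparison layer against a known truth.
#'
#' @param effects data frame with columns `group`, `mean`, `sd`.
#' @param n observations per group (scalar or per-group vector, >= 2).
#' @param seed integer RNG seed.
#' @param dist `"normal"` or `"lognormal"` (skewed; `mean`/`sd` are the
#'   meanlog/sdlog parameters).
#' @return data frame `sample`, `group`, `value` with the truth
#'   attached as attribute `"truth"`.
#' @export
synth_group_samples <- function(effects, n, seed = 1L,
                                dist = c("normal", "lognormal")) {
  stopifnot(all(c("group", "mean", "sd") %in% names(effects)))
  dist <- match.arg(dist)
  n <- rep_len(as.integer(n), nrow(effects))
  if (any(n < 2L)) stop("need n >= 2 per group", call. = FALSE)
  tab <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(nrow(effects)), function(i) {
      v <- switch(dist,
        normal = stats::rnorm(n[i], effects$mean[i], effects$sd[i]),
        lognormal = stats::rlnorm(n[i], effects$mean[i], effects$sd[i]))
      data.frame(sample = sprintf("%s_%02d", effects$group[i], seq_len(n[i])),
                 group = effects$group[i], value = v)
    }))
  })
  attr(tab, "truth") <- list(effects = effects, n = n, seed = seed,
                             dist = dist)
  tab
}
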