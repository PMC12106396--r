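# Shared fixtures, all generated in code at test time.

# Small benchtop-scale geometry: square 201 x 201 detector whose corner
# reaches q ~ 2.9 1/A at 0.8266 A, so the full cellulose + water window
# [0.5, 2.5] is covered while images stay small.
test_geometry <- function(shape = c(201L, 201L),
                          beam_center = c((shape[2] - 1) / 2,
                                          (shape[1] - 1) / 2),
                          pixel_size_um = 172) {
  waxs_geometry(wavelength_A = 0.8266, camera_length_mm = 60,
                pixel_size_um = pixel_size_um, detector_shape = shape,
                beam_center = beam_center)
}

# Three-peak wood-like truth; d200 sets the cellulose (200) position,
# L200 its Scherrer width.
wood_truth <- function(d200 = 3.952, L200 = 20, water_area = 110,
                       eta200 = 0.3, seed = 1L, hump_amp = 60) {
  waxs_truth(
    peaks = data.frame(
      label = c("110/1-10", "200", "water"),
      mu = c(1.10, 2 * pi / d200, 2.00),
      fwhm = c(0.20, 2 * pi * 0.94 / L200, 0.35),
      eta = c(0.3, eta200, 0.5),
      area = c(260, 270, water_area)),
    background = list(intercept = 40, slope = -8, hump_amp = hump_amp,
                      hump_mu = 1.4, hump_fwhm = 1.6),
    seed = seed)
}

# Pseudo-Voigt density with both sub-components renormalised over
# [a, b], written out independently of the package internals.
tpv_density <- function(q, mu, fwhm, eta, a, b) {
  s <- fwhm / (2 * sqrt(2 * log(2)))
  g <- fwhm / 2
  gz <- stats::pnorm(b, mu, s) - stats::pnorm(a, mu, s)
  lz <- (atan((b - mu) / g) - atan((a - mu) / g)) / pi
  (1 - eta) * stats::dnorm(q, mu, s) / gz +
    eta * (g / pi) / ((q - mu)^2 + g^2) / lz
}

# Direct 3-peak profile fixture on the analysis grid (no image, no
# baseline): intensity = planted pseudo-Voigt mixture on the fitting
# window (sub-components renormalised over it, so mixing weights are
# exact window fractions), optionally with Poisson counting noise
# scaled so the apex sits near `peak_counts` expected counts
# (SNR ~ sqrt(peak_counts)).
pv_profile_fixture <- function(truth = data.frame(
                                 mu = c(1.10, 1.60, 2.00),
                                 fwhm = c(0.20, 0.12, 0.35),
                                 eta = c(0.3, 0.4, 0.5),
                                 w = c(0.4, 0.35, 0.25)),
                               peak_counts = 900, noise = FALSE,
                               seed = 42L) {
  q <- seq(0.5, 2.5, by = 0.001)
  mdl <- Reduce(`+`, lapply(seq_len(nrow(truth)), function(k) {
    truth$w[k] * tpv_density(q, truth$mu[k], truth$fwhm[k], truth$eta[k],
                             min(q), max(q))
  }))
  scale <- peak_counts / max(mdl)
  y <- if (noise) {
    withr::with_seed(seed, stats::rpois(length(q), mdl * scale))
  } else {
    mdl * scale
  }
  list(profile = qprofile(q, y), truth = truth, q = q, scale = scale)
}

# O(n^3) brute-force lower convex hull: the baseline at each x is the
# maximum over all supporting chords (lines through two data points
# with every point on or above them).
brute_force_lower_hull <- function(x, y) {
  n <- length(x)
  env <- rep(-Inf, n)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      slope <- (y[j] - y[i]) / (x[j] - x[i])
      line <- y[i] + slope * (x - x[i])
      if (all(y - line >= -1e-12 * (1 + abs(y)))) {
        env <- pmax(env, line)
      }
    }
  }
  env
}

extract_peak <- function(fit, label) {
  labs <- vapply(fit$peaks, `[[`, "", "label")
  fit$peaks[[which(labs == label)]]
}

peak_param <- function(fit, name) vapply(fit$peaks, `[[`, 0, name)
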