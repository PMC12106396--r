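test_that("pixel-to-q mapping reproduces direct trigonometry", {
  g <- waxs_geometry(wavelength_A = 0.8266, camera_length_mm = 693.9,
                     pixel_size_um = 172, detector_shape = c(501, 501),
                     beam_center = c(100, 100))
  # beam center maps to q = 0
  expect_equal(pixel_to_q(100, 100, g), 0)
  # 200 px off-center: R = 34.4 mm, 2theta = atan(0.049575)
  expect_equal(pixel_to_q(100, 300, g), 0.3765, tolerance = 2e-4)
  # small-angle limit: doubling the camera length halves q to 1st order
  g2 <- waxs_geometry(wavelength_A = 0.8266, camera_length_mm = 2 * 693.9,
                      pixel_size_um = 172, detector_shape = c(501, 501),
                      beam_center = c(100, 100))
  q1 <- pixel_to_q(100, 110, g)
  q2 <- pixel_to_q(100, 110, g2)
  expect_lt(abs(2 * q2 - q1) / q1, 1e-3)
})

test_that("azimuthal integration conserves photons and handles uniform images", {
  g <- test_geometry(shape = c(64L, 64L))
  uni <- detector_image(matrix(5, 64, 64), g)
  prof <- integrate_azimuthal(uni)
  expect_true(all(prof$intensity == 5))
  # photon conservation is an exact mean x count identity
  expect_identical(sum(prof$intensity * prof$n_pixels), sum(uni$intensity))
  img <- synth_waxs_image(wood_truth(seed = 2L), g)
  prof2 <- integrate_azimuthal(img)
  expect_equal(sum(prof2$intensity * prof2$n_pixels),
               sum(img$intensity[img$mask]), tolerance = 1e-12)
  expect_true(all(diff(prof2$q) > 0))
  expect_true(all(prof2$n_pixels >= 1))
})

test_that("integration is linear in the image and matches per-pixel enumeration", {
  g <- test_geometry(shape = c(8L, 8L), beam_center = c(3.2, 3.7))
  m <- withr::with_seed(4, matrix(rpois(64, 50) + 0.0, 8, 8))
  img <- detector_image(m, g)
  prof <- integrate_azimuthal(img, q_step = 0.01)
  # brute-force oracle: enumerate every pixel's bin and average by hand
  qpix <- outer(0:7, 0:7, function(r, c) pixel_to_q(r, c, g))
  bin <- round(qpix / 0.01)
  oracle <- vapply(sort(unique(as.vector(bin))), function(b) {
    mean(m[bin == b])
  }, numeric(1))
  expect_equal(prof$intensity, oracle, tolerance = 1e-12)
  # linearity: integrate(a * image) = a * integrate(image); with a
  # power-of-two factor the identity is even bitwise exact
  prof3 <- integrate_azimuthal(detector_image(4 * m, g), q_step = 0.01)
  expect_identical(prof3$intensity, 4 * prof$intensity)
  prof5 <- integrate_azimuthal(detector_image(3 * m, g), q_step = 0.01)
  expect_equal(prof5$intensity, 3 * prof$intensity, tolerance = 1e-14)
})

test_that("a planted isotropic ring lands in the right q bin", {
  g <- test_geometry()
  tr <- waxs_truth(peaks = data.frame(label = "ring", mu = 1.600,
                                      fwhm = 0.05, eta = 0, area = 500),
                   background = list(intercept = 0, slope = 0, hump_amp = 0,
                                     hump_mu = 1, hump_fwhm = 1),
                   seed = 1L)
  prof <- integrate_azimuthal(synth_waxs_image(tr, g, noise = FALSE))
  expect_lt(abs(prof$q[which.max(prof$intensity)] - 1.600), 0.0015)
})

test_that("rotating an isotropic image by 90 degrees leaves bin means within counting noise", {
  # rectangular pixels make this non-trivial: the rotated image only
  # reproduces each pixel's q when the row/col handling is consistent
  g <- test_geometry(shape = c(161L, 161L), beam_center = c(80, 80),
                     pixel_size_um = c(150, 200))
  gr <- test_geometry(shape = c(161L, 161L), beam_center = c(80, 80),
                      pixel_size_um = c(200, 150))
  img <- synth_waxs_image(wood_truth(seed = 5L), g)
  rot <- t(img$intensity)[, nrow(img$intensity):1]
  imgr <- detector_image(rot, gr)
  p1 <- integrate_azimuthal(img, q_step = 0.005)
  p2 <- integrate_azimuthal(imgr, q_step = 0.005)
  common <- intersect(round(p1$q, 3), round(p2$q, 3))
  common <- common[common > 0.3 & common < 2.3]
  i1 <- match(common, round(p1$q, 3))
  i2 <- match(common, round(p2$q, 3))
  keep <- p1$n_pixels[i1] >= 20 & p2$n_pixels[i2] >= 20
  sigma <- sqrt(p1$intensity[i1] / p1$n_pixels[i1] +
                p2$intensity[i2] / p2$n_pixels[i2])
  z <- abs(p1$intensity[i1] - p2$intensity[i2]) / sigma
  expect_true(all(z[keep] < 3))
})

test_that("rolling mean truncates its window at the edges", {
  prof <- qprofile(seq(1, 1.004, by = 0.001), c(1, 2, 3, 4, 5))
  expect_equal(rolling_mean(prof, 1)$intensity, prof$intensity)
  expect_equal(rolling_mean(prof, 3)$intensity, c(1.5, 2, 3, 4, 4.5))
  # constant profiles are fixed points for any window
  const <- qprofile(seq(1, 1.010, by = 0.001), rep(7, 11))
  for (w in c(1, 3, 5, 11)) {
    expect_equal(rolling_mean(const, w)$intensity, rep(7, 11))
  }
  expect_error(rolling_mean(prof, 2), "odd")
  expect_error(rolling_mean(prof, 7), "exceeds")
})
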