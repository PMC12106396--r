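test_that("pseudo-Voigt density has the textbook apex heights, symmetry and unit area", {
  # Gaussian limit: PV(mu) = 2 sqrt(ln 2 / pi) / fwhm
  expect_equal(pseudo_voigt_density(1.6, mu = 1.6, fwhm = 0.1, eta = 0),
               9.3944, tolerance = 1e-4)
  # Lorentzian limit: PV(mu) = 2 / (pi fwhm)
  expect_equal(pseudo_voigt_density(1.6, mu = 1.6, fwhm = 0.1, eta = 1),
               6.3662, tolerance = 1e-4)
  # symmetry about the center
  dx <- seq(0, 0.5, by = 0.01)
  for (eta in c(0, 0.37, 1)) {
    expect_equal(pseudo_voigt_density(1.6 + dx, mu = 1.6, fwhm = 0.12, eta = eta),
                 pseudo_voigt_density(1.6 - dx, mu = 1.6, fwhm = 0.12, eta = eta))
  }
  # unit area and half-maximum at mu +/- fwhm/2 for any mixing
  for (eta in c(0, 0.5, 1)) {
    area <- stats::integrate(pseudo_voigt_density, -Inf, Inf, mu = 0,
                             fwhm = 0.2, eta = eta)$value
    expect_equal(area, 1, tolerance = 1e-6)
    apex <- pseudo_voigt_density(0, mu = 0, fwhm = 0.2, eta = eta)
    expect_equal(pseudo_voigt_density(0.1, mu = 0, fwhm = 0.2, eta = eta),
                 apex / 2, tolerance = 1e-10)
  }
})

test_that("a single noiseless Gaussian is recovered with unit weight", {
  q <- seq(0.5, 2.5, by = 0.001)
  y <- 100 * pseudo_voigt_density(q, mu = 1.6, fwhm = 0.15, eta = 0)
  fit <- fit_pv_mixture(qprofile(q, y), init = list(pv_peak(1.5, 0.2, 0.5)))
  expect_equal(fit$peaks[[1]]$weight, 1)
  expect_lt(abs(fit$peaks[[1]]$mu - 1.6), 1e-3)
  expect_lt(fit$peaks[[1]]$eta, 0.05)
  expect_true(fit$converged)
})

test_that("EM log-likelihood is non-decreasing and the fit is deterministic", {
  fx <- pv_profile_fixture(noise = TRUE, seed = 7L)
  fit1 <- fit_pv_mixture(fx$profile, init = c(1.1, 1.6, 2.0), tol = 1e-7)
  expect_true(all(diff(fit1$loglik_trace) >= -1e-9))
  fit2 <- fit_pv_mixture(fx$profile, init = c(1.1, 1.6, 2.0), tol = 1e-7)
  expect_identical(peak_param(fit1, "mu"), peak_param(fit2, "mu"))
  expect_identical(peak_param(fit1, "fwhm"), peak_param(fit2, "fwhm"))
  expect_identical(fit1$loglik_trace, fit2$loglik_trace)
})

test_that("mixing weights stay normalised and the fit is scale invariant", {
  fx <- pv_profile_fixture(noise = TRUE, seed = 3L)
  fit <- fit_pv_mixture(fx$profile, init = c(1.1, 1.6, 2.0), tol = 1e-7)
  expect_equal(sum(peak_param(fit, "weight")), 1, tolerance = 1e-9)
  scaled <- qprofile(fx$profile$q, fx$profile$intensity * 37.5)
  fit_s <- fit_pv_mixture(scaled, init = c(1.1, 1.6, 2.0), tol = 1e-7)
  expect_equal(peak_param(fit_s, "mu"), peak_param(fit, "mu"), tolerance = 1e-6)
  expect_equal(peak_param(fit_s, "fwhm"), peak_param(fit, "fwhm"),
               tolerance = 1e-6)
  expect_equal(peak_param(fit_s, "eta"), peak_param(fit, "eta"),
               tolerance = 1e-5)
  expect_equal(peak_param(fit_s, "weight"), peak_param(fit, "weight"),
               tolerance = 1e-6)
  expect_equal(fit_s$total_area, 37.5 * fit$total_area, tolerance = 1e-12)
})

test_that("peak count is fixed: components are never pruned, and degeneracy warns", {
  q <- seq(0.5, 2.5, by = 0.002)
  y <- 500 * pseudo_voigt_density(q, mu = 1.5, fwhm = 0.2, eta = 0.3)
  expect_warning(
    fit <- fit_pv_mixture(qprofile(q, y),
                          init = list(pv_peak(1.5, 0.2, 0.3, 0.5),
                                      pv_peak(1.5, 0.2, 0.3, 0.5)),
                          tol = 1e-9),
    "degenerate")
  expect_length(fit$peaks, 2)
})

test_that("invalid inputs are rejected with informative errors", {
  q <- seq(0.5, 2.5, by = 0.01)
  expect_error(fit_pv_mixture(qprofile(q, rep(0, length(q))), init = 1.5),
               "zero total area")
  expect_error(fit_pv_mixture(qprofile(q, rep(-1, length(q))), init = 1.5),
               "non-negative")
  expect_error(fit_pv_mixture(qprofile(q, rep(1, length(q))), init = 3.5),
               "inside the fitted q range")
  expect_error(pv_peak(1.5, fwhm = -0.1), "fwhm")
  expect_error(pv_peak(1.5, 0.1, eta = 1.2), "eta")
})

test_that("non-convergence is reported, never silent", {
  fx <- pv_profile_fixture(noise = TRUE, seed = 5L)
  expect_warning(
    fit <- fit_pv_mixture(fx$profile, init = c(1.1, 1.6, 2.0), max_iter = 3L),
    "did not converge")
  expect_false(fit$converged)
  expect_equal(fit$n_iter, 3L)
})

test_that("fit results round-trip through JSON", {
  fx <- pv_profile_fixture()
  fit <- fit_pv_mixture(fx$profile, init = c(1.1, 1.6, 2.0), tol = 1e-6)
  path <- withr::local_tempfile(fileext = ".json")
  write_pv_fit(fit, path)
  back <- read_pv_fit(path)
  expect_equal(peak_param(back, "mu"), peak_param(fit, "mu"))
  expect_equal(peak_param(back, "fwhm"), peak_param(fit, "fwhm"))
  expect_equal(back$total_area, fit$total_area)
  expect_identical(vapply(back$peaks, `[[`, "", "label"),
                   vapply(fit$peaks, `[[`, "", "label"))
})
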