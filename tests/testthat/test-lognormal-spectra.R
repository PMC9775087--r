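ref_fit <- lognormal_fit(Im = 1000, nu_m = 28600, rho = 1.4, H = 5000)

test_that("log-normal band shape has the defining pointwise properties", {
  expect_equal(lognormal_eval(ref_fit, ref_fit$nu_m), ref_fit$Im)
  expect_identical(lognormal_eval(ref_fit, ref_fit$a), 0)
  expect_identical(lognormal_eval(ref_fit, ref_fit$a + 1), 0)
  # continuous and monotone decreasing between the maximum and the limit
  nu <- seq(ref_fit$nu_m, ref_fit$a - 1e-6, length.out = 500)
  expect_true(all(diff(lognormal_eval(ref_fit, nu)) < 0))
})

test_that("closed-form half-max positions match the root-finding oracle", {
  for (fit in list(ref_fit,
                   lognormal_fit(500, 29500, 1.2, 4200),
                   lognormal_fit(2000, 27500, 1.9, 6000))) {
    hm <- halfmax_oracle(fit)
    expect_equal(fit$nu_minus, unname(hm["nu_minus"]), tolerance = 1e-7)
    expect_equal(fit$nu_plus, unname(hm["nu_plus"]), tolerance = 1e-7)
    expect_equal(lognormal_eval(fit, fit$nu_plus), fit$Im / 2, tolerance = 1e-9)
    expect_equal(lognormal_eval(fit, fit$nu_minus), fit$Im / 2, tolerance = 1e-9)
    # asymmetry and bandwidth definitions are mutually consistent
    expect_equal((fit$nu_m - fit$nu_minus) / (fit$nu_plus - fit$nu_m),
                 fit$rho, tolerance = 1e-9)
    expect_equal(fit$nu_plus - fit$nu_minus, fit$H, tolerance = 1e-9)
  }
})

test_that("noiseless fits recover parameters within 1%", {
  grids <- list(seq(300, 500, 10), seq(305, 495, 10))
  params <- list(c(1000, 28600, 1.4, 5000),
                 c(750, 29850, 1.3, 4500),
                 c(1500, 28000, 1.6, 5600))
  for (g in grids) for (p in params) {
    truth <- lognormal_fit(p[1], p[2], p[3], p[4])
    sp <- emission_spectrum(g, lognormal_eval(truth, 1e7 / g))
    fit <- fit_lognormal(sp)
    expect_lt(abs(fit$Im - p[1]) / p[1], 0.01)
    expect_lt(abs(fit$nu_m - p[2]) / p[2], 0.01)
    expect_lt(abs(fit$rho - p[3]) / p[3], 0.01)
    expect_lt(abs(fit$H - p[4]) / p[4], 0.01)
  }
})

test_that("fitted emission maximum is robust to 1% noise", {
  truth <- lognormal_fit(1000, 28600, 1.4, 5000)
  g <- seq(300, 500, 10)
  clean <- lognormal_eval(truth, 1e7 / g)
  set.seed(11)
  nu_m_hat <- replicate(100, {
    sp <- emission_spectrum(g, clean * (1 + rnorm(length(g), 0, 0.01)))
    fit_lognormal(sp)$nu_m
  })
  expect_lt(abs(median(nu_m_hat) - 28600) / 28600, 0.005)
})

test_that("degenerate spectra are rejected", {
  expect_error(fit_lognormal(emission_spectrum(intensities = rep(0, 21))),
               "degenerate")
  expect_error(emission_spectrum(c(300, 300, 310), c(1, 2, 3)), "increasing")
  expect_error(emission_spectrum(intensities = c(rep(1, 20), NaN)), "finite")
})

test_that("heterogeneity points convert widths to the wavelength axis", {
  fit <- lognormal_fit(1000, 28600, 1.4, 5000)
  hp <- heterogeneity_points(list(fit, fit), c(1e-3, 1e-3))
  expect_equal(nrow(hp), 2)
  expect_equal(hp[1, ], hp[2, ], ignore_attr = TRUE)  # duplicates propagate
  expect_equal(hp$lambda_max[1], 1e7 / 28600)
  expect_equal(hp$peak_width[1], 1e7 / fit$nu_minus - 1e7 / fit$nu_plus)
  # near-symmetric band: maximum centred between the half-max wavelengths
  sym <- lognormal_fit(1000, 28600, 1.0001, 5000)
  hps <- heterogeneity_points(sym)
  mid <- (1e7 / sym$nu_minus + 1e7 / sym$nu_plus) / 2
  expect_lt(abs(hps$lambda_max - mid), 5)  # within grid-scale tolerance (nm)
})

test_that("spectral decomposition is exact on convex combinations", {
  g <- gen_titration_spectra(noise_sd = 0, seed = 1)
  wl <- g$free_ref$wavelengths
  expect_equal(decompose_spectrum(g$free_ref, g$free_ref, g$bound_ref), 0)
  expect_equal(decompose_spectrum(g$bound_ref, g$free_ref, g$bound_ref), 1)
  for (cb in c(0.08, 0.3, 0.77)) {
    mix <- emission_spectrum(wl, (1 - cb) * g$free_ref$intensities +
                               cb * g$bound_ref$intensities)
    got <- decompose_spectrum(mix, g$free_ref, g$bound_ref)
    expect_equal(got, cb, tolerance = 1e-6)
    expect_equal(got, decompose_oracle(mix$intensities, g$free_ref$intensities,
                                       g$bound_ref$intensities),
                 tolerance = 1e-4)
  }
  # output clamped even for spectra outside the simplex
  beyond <- emission_spectrum(wl, 1.4 * g$bound_ref$intensities -
                                0.4 * g$free_ref$intensities)
  expect_equal(decompose_spectrum(beyond, g$free_ref, g$bound_ref), 1)
})

test_that("decomposition rejects mismatched grids and identical references", {
  g <- gen_titration_spectra(noise_sd = 0, seed = 1)
  other <- emission_spectrum(seq(310, 510, 10), g$free_ref$intensities)
  expect_error(decompose_spectrum(other, g$free_ref, g$bound_ref), "grid")
  expect_error(decompose_spectrum(g$free_ref, g$free_ref, g$free_ref),
               "ill-posed")
})
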