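test_that("quadratic bound fraction matches hand computation and limits", {
  # independent evaluation of the closed form: P=1e-7, S=1e-6, Kd=1e-6
  expect_equal(bound_fraction_model(Kd = 1e-6, Bmax = 1, protein_conc = 1e-7,
                                    lipid_conc = 1e-6),
               0.4875, tolerance = 1e-4)
  expect_identical(bound_fraction_model(1e-6, 1 / 59, 1e-7, 0), 0)
  # stoichiometric limit: Kd -> 0 with sites in excess binds everything
  expect_equal(bound_fraction_model(1e-15, 1, 1e-7, 1e-6), 1, tolerance = 1e-6)
})

test_that("bound fraction is monotone and has the hyperbolic dilute limit", {
  L <- lipid_titration_grid()
  f1 <- bound_fraction_model(1e-6, 1 / 59, 1e-7, L)
  expect_true(all(diff(f1) > 0))                       # increasing in lipid
  f2 <- bound_fraction_model(5e-6, 1 / 59, 1e-7, L)
  expect_true(all(f2 < f1))                            # decreasing in Kd
  # P << Kd: quadratic model approaches S/(S+Kd)
  S <- L / 59
  hyper <- S / (S + 1e-5)
  quad <- bound_fraction_model(1e-5, 1 / 59, 1e-8, L)
  expect_lt(max(abs(quad - hyper) / hyper), 0.01)
})

test_that("the titration grid spans 1.25 uM to 10 mM in twofold ladders", {
  g <- lipid_titration_grid()
  expect_equal(length(g), 16)
  expect_equal(min(g), 1.25e-6)
  expect_equal(max(g), 1e-2)
  expect_equal(max(g) / min(g), 8000)
})

test_that("noiseless curves refit Kd within 1% across four decades", {
  L <- lipid_titration_grid()
  for (kd in c(1e-7, 1e-6, 1e-5, 1e-4, 1e-3)) {
    pts <- data.frame(lipid_conc = L,
                      bound_fraction = bound_fraction_model(kd, 1 / 59, 1e-7, L))
    fit <- fit_binding_curve(pts, protein_conc = 1e-7)
    expect_lt(abs(fit$Kd - kd) / kd, 0.01)
    expect_true(fit$converged)
  }
})

test_that("Kd estimates stay within 10% bias under 2% noise", {
  L <- lipid_titration_grid()
  truth <- bound_fraction_model(1.12e-6, 1 / 59, 1e-7, L)
  set.seed(21)
  kds <- replicate(40, {
    pts <- data.frame(lipid_conc = L,
                      bound_fraction = pmin(pmax(
                        truth * (1 + rnorm(length(L), 0, 0.02)), 0), 1))
    fit_binding_curve(pts, 1e-7)$Kd
  })
  expect_lt(abs(median(kds) - 1.12e-6) / 1.12e-6, 0.10)
})

test_that("non-saturating curves converge but are flagged", {
  L <- lipid_titration_grid()
  pts <- data.frame(lipid_conc = L,
                    bound_fraction = bound_fraction_model(1e-3, 1 / 59, 1e-7, L))
  expect_lt(max(pts$bound_fraction), 0.9)
  fit <- fit_binding_curve(pts, 1e-7)
  expect_true(fit$converged)
  expect_false(fit$saturating)
  expect_lt(abs(fit$Kd - 1e-3) / 1e-3, 0.05)
})

test_that("degenerate binding inputs error", {
  L <- lipid_titration_grid()
  expect_error(fit_binding_curve(
    data.frame(lipid_conc = L, bound_fraction = 0), 1e-7), "zero")
})

test_that("Bmax can be co-fitted when requested", {
  L <- lipid_titration_grid()
  pts <- data.frame(lipid_conc = L,
                    bound_fraction = bound_fraction_model(1.12e-6, 1 / 59, 1e-7, L))
  fit <- fit_binding_curve(pts, 1e-7, Bmax = "fit")
  expect_true(fit$Bmax_fitted)
  expect_lt(abs(fit$Kd - 1.12e-6) / 1.12e-6, 0.05)
  expect_lt(abs(1 / fit$Bmax - 59) / 59, 0.10)
})

test_that("lipids-per-site estimator reproduces its defining arithmetic", {
  prof <- residue_profile(1:9, rep(0.1525, 9), "intensity_ratio")
  expect_equal(estimate_lipids_per_site(prof, 2.5e-3, 50e-6), 59.0,
               tolerance = 1e-3)
  # full binding: ratios of zero
  full <- residue_profile(1:9, rep(0, 9), "intensity_ratio")
  expect_equal(estimate_lipids_per_site(full, 50e-6 * 50, 50e-6), 50)
  # no binding detected
  none <- residue_profile(1:9, rep(1, 9), "intensity_ratio")
  expect_error(estimate_lipids_per_site(none, 2.5e-3, 50e-6), "no binding")
  # missing residues tolerated down to 5 present
  gappy <- residue_profile(c(1:5, 10:12), c(rep(0.1525, 5), 0.9, 0.9, 0.9),
                           "intensity_ratio")
  expect_equal(estimate_lipids_per_site(gappy, 2.5e-3, 50e-6), 59.0,
               tolerance = 1e-3)
  sparse <- residue_profile(1:4, rep(0.2, 4), "intensity_ratio")
  expect_error(estimate_lipids_per_site(sparse, 2.5e-3, 50e-6), ">= 5")
})

test_that("scale invariance of lipids-per-site holds at fixed ratios", {
  prof <- residue_profile(1:9, rep(0.2, 9), "intensity_ratio")
  a <- estimate_lipids_per_site(prof, 2.5e-3, 50e-6)
  b <- estimate_lipids_per_site(prof, 2.5e-3 * 7, 50e-6 * 7)
  expect_equal(a, b)
})
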