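test_that("generators are deterministic functions of their seed", {
  a <- gen_titration_spectra(seed = 3)
  b <- gen_titration_spectra(seed = 3)
  expect_identical(a$spectra[[5]]$intensities, b$spectra[[5]]$intensities)
  expect_false(identical(a$spectra[[5]]$intensities,
                         gen_titration_spectra(seed = 4)$spectra[[5]]$intensities))
  d1 <- gen_dest_dataset(residues = 1:3, seed = 3)
  d2 <- gen_dest_dataset(residues = 1:3, seed = 3)
  expect_identical(d1$dest, d2$dest)
  e1 <- gen_exo_traces(seed = 3)
  e2 <- gen_exo_traces(seed = 3)
  expect_identical(e1$truth, e2$truth)
  i1 <- gen_droplet_image(seed = 3)
  expect_identical(i1$rhodamine, gen_droplet_image(seed = 3)$rhodamine)
})

test_that("noiseless titration spectra decompose to the generating fractions", {
  g <- gen_titration_spectra(noise_sd = 0, seed = 1)
  cb <- vapply(g$spectra, decompose_spectrum, 0,
               free_ref = g$free_ref, bound_ref = g$bound_ref)
  expect_equal(unname(cb), g$truth$bound_fraction, tolerance = 1e-6)
})

test_that("the full spectra-to-Kd pipeline round-trips the truth", {
  g <- gen_titration_spectra(Kd = 3.54e-6, noise_sd = 0, seed = 1)
  cb <- vapply(g$spectra, decompose_spectrum, 0,
               free_ref = g$free_ref, bound_ref = g$bound_ref)
  fit <- fit_binding_curve(
    data.frame(lipid_conc = g$truth$lipid_conc, bound_fraction = cb),
    protein_conc = 1e-7)
  expect_lt(abs(fit$Kd - 3.54e-6) / 3.54e-6, 0.01)
})

test_that("intensity-ratio profiles have the documented shapes", {
  wt <- gen_intensity_profile("WT_like")
  lbd <- wt$value[wt$residue <= 98 & !is.na(wt$value)]
  expect_true(all(diff(lbd) >= 0))                 # non-decreasing ramp
  expect_true(all(wt$value[wt$residue > 98 & !is.na(wt$value)] == 1))
  expect_true(all(is.na(wt$value[wt$residue %in% c(108, 117, 120, 128, 138)])))
  b34 <- gen_intensity_profile("break_at_34", break_step = 0.3)
  expect_gte(b34$value[b34$residue == 34] - b34$value[b34$residue == 33], 0.25)
  b65 <- gen_intensity_profile("break_at_65", break_step = 0.3)
  expect_gte(b65$value[b65$residue == 65] - b65$value[b65$residue == 64], 0.25)
  # N-terminal bound fraction f reproduces lipid/(f*protein) algebraically:
  # the median over residues 1-9 of the linear ramp sits at residue 5
  f <- 1 - (0.1525 + (0.95 - 0.1525) * 4 / 97)
  expect_equal(estimate_lipids_per_site(wt, 2.5e-3, 50e-6),
               2.5e-3 / (f * 50e-6), tolerance = 1e-9)
})

test_that("graded generator profiles survive the ratio computation", {
  prof <- gen_intensity_profile("WT_like", noise_sd = 0)
  without <- data.frame(residue = prof$residue, height = 1000)
  with_suv <- data.frame(residue = prof$residue, height = 1000 * prof$value)
  back <- compute_intensity_ratio(with_suv, without)
  expect_equal(back$value, prof$value, tolerance = 1e-12)
})

test_that("noiseless exocytosis traces return their true Exo exactly", {
  g <- gen_exo_traces(noise_sd = 0, seed = 2)
  exo <- vapply(g$traces, function(t) compute_exo(t)$exo, 0)
  expect_equal(unname(exo), g$truth$true_exo, tolerance = 1e-9)
})

test_that("generated condition groups recover their mean difference", {
  g <- gen_exo_traces(conditions = data.frame(
    condition = c("low", "high"), mean_exo = c(0.25, 0.45),
    sd_exo = c(0.08, 0.08), n_cells = c(40, 40)), seed = 9)
  exo <- vapply(g$traces, function(t) compute_exo(t)$exo, 0)
  cond <- vapply(g$traces, function(t) t$condition, "")
  cmp <- compare_conditions(exo[cond == "low"], exo[cond == "high"])
  expect_equal(cmp$difference, 0.2, tolerance = 0.08)
  expect_lt(cmp$p_value, 0.001)
})

test_that("C-terminal-tail style residues show flat narrow DEST profiles", {
  cfg <- dest_config(reference = "equilibrium")
  g <- gen_dest_dataset("two_state", residues = 99:101, config = cfg,
                        kon_app = 1e-9, noise_sd = 0, seed = 11)
  inner <- abs(g$dest$offset_hz) >= 15000
  expect_true(all(g$dest$ratio[inner] > 0.95))
  expect_lt(max(abs(g$delta_r2$delta_r2)), 1e-6)
})

test_that("droplet truth tables match what the image contains", {
  img <- gen_droplet_image(n_droplets = 10, noise_sd = 0, seed = 12)
  expect_equal(nrow(img$truth), 10)
  d <- droplet_partition(img$egfp, img$rhodamine, img$pixel_size_um)
  expect_equal(nrow(d), sum(img$truth$area_um2 > 0.2))
})
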