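test_that("CPMG schedule multiplies the 16.32 ms element", {
  d <- build_cpmg_schedule(18)
  expect_equal(length(d), 19)
  expect_equal(max(d), 0.29376)        # printed as "a maximum of 294 ms"
  expect_equal(min(d), 0)
  expect_equal(build_cpmg_schedule(0), 0)
  # scrambling is a seeded permutation of the unscrambled set
  s <- build_cpmg_schedule(18, seed = 4)
  expect_false(identical(s, d))
  expect_equal(sort(s), d)
  expect_equal(build_cpmg_schedule(18, seed = 4), s)
  expect_error(build_cpmg_schedule(19), "0..18")
})

test_that("single-exponential R2 fits recover clean decays", {
  d <- build_cpmg_schedule(18)
  f5 <- fit_r2_decay(d, 1000 * exp(-5 * d))
  expect_equal(f5$R2, 5, tolerance = 1e-6)
  f0 <- fit_r2_decay(d, rep(800, length(d)))
  expect_equal(f0$R2, 0, tolerance = 1e-8)
  expect_error(fit_r2_decay(c(0, 0.1), c(1, 0.5)), ">= 4")
  expect_error(fit_r2_decay(d, -1000 * exp(-5 * d)), "positive")
})

test_that("R2 estimates are accurate at 1% noise over the full schedule", {
  d <- build_cpmg_schedule(18)
  clean <- 1000 * exp(-5 * d)
  set.seed(31)
  r2s <- replicate(200, fit_r2_decay(d, clean * (1 + rnorm(length(d), 0, 0.01)),
                                     replicate_heights = clean[10] *
                                       (1 + rnorm(3, 0, 0.01)))$R2)
  expect_lt(abs(median(r2s) - 5) / 5, 0.02)
})

test_that("the propagator conserves magnetization without relaxation or field", {
  K <- synbind:::k_two_state(5, 20)
  p0 <- c(20, 5) / 25
  m <- synbind:::mcconnell_state_cpp(2 * pi * 5000, 0, 0.9, 0, c(0, 0), K, p0)
  expect_equal(m[3] + m[6], 1, tolerance = 1e-10)   # total z conserved
})

test_that("stationary free fraction follows the rate ratio", {
  for (rates in list(c(5, 20), c(0.5, 100), c(50, 50))) {
    K <- synbind:::k_two_state(rates[1], rates[2])
    p0 <- synbind:::stationary_populations(K)
    expect_equal(p0[1], rates[2] / sum(rates), tolerance = 1e-12)
    # equilibrium is a fixed point of the propagator without saturation
    m <- synbind:::mcconnell_state_cpp(0, 1e-12, 20, 1.5, c(4, 2000), K, p0)
    expect_equal(m[3], p0[1], tolerance = 1e-9)
    # and is reached from a fully free start (independent RK4 integration)
    z <- mcconnell_rk4(0, 1e-12, 10, 1.5, c(1, 5), K, p0, dt = 1e-3,
                       z0 = c(1, 0))
    expect_equal(z, p0[1], tolerance = 1e-6)
  }
})

test_that("DEST profiles are symmetric in the offset sign", {
  K <- synbind:::k_two_state(5, 20)
  p0 <- synbind:::stationary_populations(K)
  off <- 2 * pi * c(-30000, -7500, -1000, 1000, 7500, 30000)
  z <- synbind:::mcconnell_z_cpp(off, 2 * pi * 400, 0.9, 1.5, c(4, 2000),
                                 K, p0, 1L)
  expect_equal(z[1:3], rev(z[4:6]), tolerance = 1e-8)
})

test_that("matrix-exponential propagation matches an RK4 integrator", {
  # two-state and pseudo-two-state systems, several offsets, both powers
  cases <- list(
    list(K = synbind:::k_two_state(5, 20), r2 = c(4, 2000)),
    list(K = synbind:::k_pseudo(2.5, 2.5, 20), r2 = c(4, 300, 20000)))
  for (cs in cases) {
    p0 <- synbind:::stationary_populations(cs$K)
    for (off_hz in c(0, 7500, 30000)) for (bw in c(400, 175)) {
      zfast <- synbind:::mcconnell_z_cpp(2 * pi * off_hz, 2 * pi * bw, 0.9,
                                         1.5, cs$r2, cs$K, p0, 1L)
      zslow <- mcconnell_rk4(2 * pi * off_hz, 2 * pi * bw, 0.9, 1.5,
                             cs$r2, cs$K, p0, dt = 1e-5)
      expect_lt(abs(zfast - zslow), 1e-6)
    }
  }
})

test_that("no exchange leaves far-offset magnetization intact", {
  cfg <- dest_config(reference = "equilibrium")
  s <- simulate_dest(cfg, two_state_model(1e-9, 20, 2000), free_R2 = 10)
  prof <- s$profile
  extremes <- prof$ratio[abs(prof$offset_hz) == 30000]
  expect_true(all(extremes >= 0.98))
  expect_true(all(prof$ratio[prof$offset_hz == 0] < 0.1))  # direct saturation
  expect_lt(s$delta_r2, 1e-6)
})

test_that("stronger saturation fields deepen DEST dips everywhere", {
  cfg <- dest_config(bandwidths = c(400, 175), reference = "equilibrium")
  s <- simulate_dest(cfg, two_state_model(5, 20, 2000), free_R2 = 4)$profile
  strong <- s$ratio[s$bandwidth_hz == 400]
  weak <- s$ratio[s$bandwidth_hz == 175]
  # strict away from resonance; on-resonance both are saturated to ~0 and
  # coherent nutation leaves sub-1e-2 residuals of either sign
  off <- s$offset_hz[s$bandwidth_hz == 400]
  expect_true(all(strong[abs(off) > 1000] <= weak[abs(off) > 1000] + 1e-9))
  expect_true(all(strong <= weak + 5e-3))
})

test_that("pseudo-two-state simulation nests the two-state limits", {
  cfg <- dest_config()
  # pure direct contact (k1 = 0): identical to two-state at R2_direct
  a <- simulate_dest(cfg, pseudo_two_state_model(0, 5, 20, 300, 2000), 4)
  b <- simulate_dest(cfg, two_state_model(5, 20, 2000), 4)
  expect_equal(a$profile$ratio, b$profile$ratio, tolerance = 1e-8)
  expect_equal(a$delta_r2, b$delta_r2, tolerance = 1e-8)
  # pure tethered (k2 = 0): identical to two-state at R2_tethered
  c1 <- simulate_dest(cfg, pseudo_two_state_model(5, 0, 20, 300, 20000), 4)
  c2 <- simulate_dest(cfg, two_state_model(5, 20, 300), 4)
  expect_equal(c1$profile$ratio, c2$profile$ratio, tolerance = 1e-8)
})

test_that("predicted relaxation enhancement approaches lifetime broadening", {
  # slow exchange into a rapidly relaxing bound state: delta-R2 ~ kon
  m <- two_state_model(5, 20, 2e4)
  expect_equal(delta_r2_model(m, 4), 5, tolerance = 0.01)
  expect_equal(delta_r2_model(two_state_model(0, 20, 2000), 4), 0,
               tolerance = 1e-10)
})

test_that("two-state null data yield a near-zero on-rate", {
  cfg <- dest_config()
  g <- gen_dest_dataset("two_state", residues = 1:4, config = cfg,
                        kon_app = 1e-9, noise_sd = 0, seed = 5)
  f <- fit_two_state(g$dest, g$delta_r2, g$free_r2, cfg, n_starts = 2)
  expect_lt(f$kon_app, 0.1)
})

test_that("pseudo-first-order check reads slope structure correctly", {
  res <- 1:12
  mk <- function(lipid, protein, dr2)
    data.frame(lipid_conc = lipid, protein_conc = protein, residue = res,
               delta_r2 = dr2 + 0.05 * sin(res))
  # delta-R2 proportional to lipid, flat in protein
  ok <- rbind(mk(1e-3, 1e-4, 2), mk(2e-3, 1e-4, 4), mk(4e-3, 1e-4, 8),
              mk(1e-3, 5e-5, 2), mk(1e-3, 2e-4, 2))
  expect_equal(pseudo_first_order_check(ok, seed = 2)$verdict,
               "pseudo-first-order consistent")
  # delta-R2 proportional to protein instead
  bad <- rbind(mk(1e-3, 5e-5, 1), mk(1e-3, 1e-4, 2), mk(1e-3, 2e-4, 4),
               mk(2e-3, 1e-4, 2), mk(4e-3, 1e-4, 2))
  expect_match(pseudo_first_order_check(bad, seed = 2)$verdict, "violation")
  expect_error(pseudo_first_order_check(mk(1e-3, 1e-4, 2)), ">= 2")
})

test_that("doubling the lipid scale doubles generated enhancements", {
  cfg <- dest_config()
  g1 <- gen_dest_dataset("two_state", residues = 1:5, config = cfg,
                         noise_sd = 0, seed = 6, lipid_scale = 1)
  g2 <- gen_dest_dataset("two_state", residues = 1:5, config = cfg,
                         noise_sd = 0, seed = 6, lipid_scale = 2)
  ratio <- mean(g2$delta_r2$delta_r2) / mean(g1$delta_r2$delta_r2)
  expect_equal(ratio, 2, tolerance = 0.02)
})
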