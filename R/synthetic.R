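#' Synthetic-data generators
#'
#' Every generator is a deterministic function of its seed and returns its
#' ground truth alongside the data, so each pipeline stage is testable
#' without measured inputs. Generators target the statistical structure
#' each analysis assumes (mixture spectra, exchange-broadened DEST
#' profiles, plateau traces, disk-shaped droplets); they do not model
#' physical noise sources such as shot noise or lineshapes.
#'
#' @name synthetic
NULL

# proline positions of human alpha-synuclein, used (as configuration, not
# hard-coded biology) to emulate residues missing from NH-detected spectra
asyn_prolines <- function() c(108L, 117L, 120L, 128L, 138L)

rel_noise <- function(x, sd_rel) if (sd_rel > 0) x * (1 + rnorm(length(x), 0, sd_rel)) else x

#' Generate a lipid-titration series of mixture emission spectra
#'
#' For each lipid concentration, the bound fraction follows
#' [bound_fraction_model()] and the spectrum is the corresponding convex
#' mixture of a free and a bound log-normal reference, plus optional
#' relative Gaussian noise (default 1%, a plausible bench magnitude).
#'
#' @param Kd,Bmax,protein_conc Binding truth (defaults: 1.12e-6 M, 1/59
#'   sites per lipid, 0.1 uM protein).
#' @param lipid_grid Lipid concentrations, M (default
#'   [lipid_titration_grid()]).
#' @param free_params,bound_params Log-normal parameters
#'   `list(Im, nu_m, rho, H)` of the free (red-shifted, ~348 nm) and bound
#'   (blue-shifted, ~335 nm) reference states.
#' @param wavelengths Emission grid, nm.
#' @param noise_sd Relative Gaussian noise on intensities (0 = noiseless).
#' @param seed Seed (mandatory for noisy output).
#' @param label Variant label.
#' @return List with `spectra` (list of [emission_spectrum()], one per
#'   lipid concentration), `free_ref`, `bound_ref`, and `truth`
#'   (data.frame `lipid_conc`, `bound_fraction`).
#' @export
gen_titration_spectra <- function(Kd = 1.12e-6, Bmax = 1 / 59,
                                  protein_conc = 1e-7,
                                  lipid_grid = lipid_titration_grid(),
                                  free_params = list(Im = 1000, nu_m = 28740, rho = 1.4, H = 5200),
                                  bound_params = list(Im = 1250, nu_m = 29850, rho = 1.35, H = 4800),
                                  wavelengths = seq(300, 500, by = 10),
                                  noise_sd = 0.01, seed = 1, label = "WT") {
  free_fit <- do.call(lognormal_fit, free_params)
  bound_fit <- do.call(lognormal_fit, bound_params)
  nu <- wavelength_to_wavenumber(wavelengths)
  free_I <- lognormal_eval(free_fit, nu)
  bound_I <- lognormal_eval(bound_fit, nu)
  fb <- bound_fraction_model(Kd, Bmax, protein_conc, lipid_grid)
  spectra <- with_seed(seed, lapply(seq_along(lipid_grid), function(i) {
    I <- (1 - fb[i]) * free_I + fb[i] * bound_I
    emission_spectrum(wavelengths, rel_noise(I, noise_sd),
                      lipid_conc = lipid_grid[i],
                      protein_conc = protein_conc, label = label)
  }))
  list(spectra = spectra,
       free_ref = emission_spectrum(wavelengths, free_I, 0, protein_conc, label),
       bound_ref = emission_spectrum(wavelengths, bound_I, max(lipid_grid),
                                     protein_conc, label),
       truth = data.frame(lipid_conc = lipid_grid, bound_fraction = fb))
}

#' Generate a residue-resolved DEST + R2 dataset from a known truth
#'
#' Simulates both-bandwidth DEST profiles and free/with-vesicle R2
#' profiles for a stretch of lipid-binding-domain residues under a
#' two-state or pseudo-two-state exchange truth, then applies relative
#' Gaussian noise (default 2%). For the pseudo-two-state truth, `K3`
#' ramps linearly along the sequence (direct-contact binding growing
#' toward helix-2) while the total apparent on-rate is held at
#' `kon_total * lipid_scale`; the two-state truth uses a single global
#' `kon_app * lipid_scale`. `lipid_scale` emulates proportionality of the
#' pseudo-first-order on-rate to lipid concentration.
#'
#' @param model_type `"two_state"` or `"pseudo_two_state"`.
#' @param residues Residue numbers (default 1:20).
#' @param config A [dest_config()].
#' @param kon_app,koff,R2_bound Two-state truth (defaults 5, 20, 2000 /s).
#' @param kon_total Pseudo-two-state total on-rate `k1+k2` (default 5 /s).
#' @param K3_range Linear K3 ramp endpoints along `residues`
#'   (default c(0.2, 2)); a vector of `length(residues)` is used as the
#'   per-residue K3 profile directly.
#' @param R2_tethered,R2_direct Bound-mode R2 truths (defaults 300,
#'   20000 /s).
#' @param free_r2_range Per-residue free R2 drawn uniformly in this range
#'   (default 3-6 /s).
#' @param lipid_scale Multiplier on the on-rates (default 1).
#' @param noise_sd Relative Gaussian noise (0 = noiseless).
#' @param seed Seed.
#' @return List with `dest` (data.frame `residue`, `offset_hz`,
#'   `bandwidth_hz`, `ratio`), `delta_r2`, `free_r2`, `r2_with_vesicles`,
#'   and `truth` (per-residue model parameters).
#' @export
gen_dest_dataset <- function(model_type = c("pseudo_two_state", "two_state"),
                             residues = 1:20, config = dest_config(),
                             kon_app = 5, koff = 20, R2_bound = 2000,
                             kon_total = 5, K3_range = c(0.2, 2),
                             R2_tethered = 300, R2_direct = 20000,
                             free_r2_range = c(3, 6),
                             lipid_scale = 1, noise_sd = 0.02, seed = 1) {
  model_type <- match.arg(model_type)
  n <- length(residues)
  with_seed(seed, {
    fr2 <- runif(n, free_r2_range[1], free_r2_range[2])
    K3 <- if (length(K3_range) == n) K3_range else
      seq(K3_range[1], K3_range[2], length.out = n)
    models <- lapply(seq_len(n), function(i) {
      if (model_type == "two_state")
        two_state_model(kon_app * lipid_scale, koff, R2_bound)
      else {
        kt <- kon_total * lipid_scale
        pseudo_two_state_model(k1_app = kt / (1 + K3[i]),
                               k2_app = kt * K3[i] / (1 + K3[i]),
                               koff = koff, R2_tethered = R2_tethered,
                               R2_direct = R2_direct)
      }
    })
    dest <- list(); dr2 <- numeric(n)
    for (i in seq_len(n)) {
      sim <- simulate_dest(config, models[[i]], fr2[i])
      p <- sim$profile
      p$residue <- residues[i]
      p$ratio <- rel_noise(p$ratio, noise_sd)
      dest[[i]] <- p[, c("residue", "offset_hz", "bandwidth_hz", "ratio")]
      dr2[i] <- sim$delta_r2
    }
    dr2_noisy <- rel_noise(dr2, noise_sd)
    truth <- data.frame(residue = residues, free_r2 = fr2, delta_r2 = dr2)
    if (model_type == "pseudo_two_state") {
      truth$K3 <- K3
      truth$k1_app <- vapply(models, `[[`, 0, "k1_app")
      truth$k2_app <- vapply(models, `[[`, 0, "k2_app")
    } else {
      truth$kon_app <- kon_app * lipid_scale
    }
    list(dest = do.call(rbind, dest),
         delta_r2 = data.frame(residue = residues, delta_r2 = dr2_noisy),
         free_r2 = data.frame(residue = residues, r2 = fr2),
         r2_with_vesicles = data.frame(residue = residues, r2 = fr2 + dr2_noisy),
         truth = truth,
         params = list(model_type = model_type, koff = koff,
                       R2_bound = R2_bound, R2_tethered = R2_tethered,
                       R2_direct = R2_direct, lipid_scale = lipid_scale))
  })
}

#' Generate an N-to-C graded intensity-ratio profile
#'
#' Emulates vesicle-binding intensity-ratio profiles: maximal bound
#' fraction (lowest ratio) at the very N-terminus, a monotone ramp toward
#' the end of the lipid-binding domain (residue 98) and no binding
#' (ratio 1) in the C-terminal tail. `break_at_34` / `break_at_65` add a
#' step discontinuity of height `break_step` at the named residue,
#' emulating 4G- and V70P-style truncated binding modes. Proline
#' positions are `NA`.
#'
#' @param variant_style `"WT_like"`, `"break_at_34"` or `"break_at_65"`.
#' @param n_residues Sequence length (default 140).
#' @param nterm_ratio Intensity ratio at residue 1 (default 0.1525).
#' @param cterm_ratio Ramp endpoint at residue 98 (default 0.95).
#' @param break_step Step height for the break styles (default 0.3).
#' @param noise_sd Relative Gaussian noise (default 0).
#' @param seed Seed.
#' @param prolines Residues reported as missing (default the human
#'   alpha-synuclein prolines).
#' @return A [residue_profile()] of kind `intensity_ratio`.
#' @export
gen_intensity_profile <- function(variant_style = c("WT_like", "break_at_34", "break_at_65"),
                                  n_residues = 140, nterm_ratio = 0.1525,
                                  cterm_ratio = 0.95, break_step = 0.3,
                                  noise_sd = 0, seed = 1,
                                  prolines = asyn_prolines()) {
  variant_style <- match.arg(variant_style)
  res <- seq_len(n_residues)
  lbd <- pmin(res, 98)
  ratio <- nterm_ratio + (cterm_ratio - nterm_ratio) * (lbd - 1) / 97
  ratio[res > 98] <- 1
  brk <- switch(variant_style, WT_like = NA, break_at_34 = 34, break_at_65 = 65)
  if (!is.na(brk)) {
    idx <- res >= brk & res <= 98
    ratio[idx] <- pmin(ratio[idx] + break_step, 1)
  }
  ratio <- with_seed(seed, rel_noise(ratio, noise_sd))
  ratio <- pmin(pmax(ratio, 0), 1.2)
  ratio[res %in% prolines] <- NA
  residue_profile(res, ratio, "intensity_ratio")
}

#' Generate per-cell pHluorin exocytosis traces
#'
#' Piecewise-plateau traces following the assay timeline: a 20 s baseline
#' (frames at `dt` spacing), a stimulated rise to a peak plateau whose
#' height encodes the per-cell true Exo, and a terminal NH4Cl plateau
#' revealing the total pool. Per-cell Exo values are drawn as
#' `rnorm(mean_exo, sd_exo)` (clamped to 0.01..0.99) and trace-level
#' relative noise is added (default 5%).
#'
#' @param conditions data.frame with columns `condition`, `mean_exo`,
#'   `sd_exo`, `n_cells`.
#' @param dt Frame interval, s (default 2).
#' @param n_frames Total frames (default 220).
#' @param stim_frame,nh4cl_frame Event frames (defaults 10 and 200).
#' @param f_basal,f_total Basal and NH4Cl-plateau fluorescence levels
#'   (defaults 100 and 400 a.u.).
#' @param noise_sd Relative Gaussian trace noise (default 0.05).
#' @param seed Seed.
#' @return List with `traces` (list of [exo_trace()]) and `truth`
#'   (data.frame `cell_id`, `condition`, `true_exo`).
#' @export
gen_exo_traces <- function(conditions = data.frame(condition = c("low", "high"),
                                                   mean_exo = c(0.25, 0.45),
                                                   sd_exo = c(0.08, 0.08),
                                                   n_cells = c(30, 30)),
                           dt = 2, n_frames = 220, stim_frame = 10,
                           nh4cl_frame = 200, f_basal = 100, f_total = 400,
                           noise_sd = 0.05, seed = 1) {
  with_seed(seed, {
    traces <- list(); truth <- list(); k <- 0
    for (ci in seq_len(nrow(conditions))) {
      for (cell in seq_len(conditions$n_cells[ci])) {
        k <- k + 1
        exo_true <- min(max(rnorm(1, conditions$mean_exo[ci],
                                  conditions$sd_exo[ci]), 0.01), 0.99)
        f_peak <- f_basal + exo_true * (f_total - f_basal)
        f <- rep(f_basal, n_frames)
        rise <- stim_frame + 1:15
        f[rise] <- f_basal + (f_peak - f_basal) * seq_along(rise) / length(rise)
        f[(max(rise) + 1):(nh4cl_frame - 1)] <- f_peak
        f[nh4cl_frame:n_frames] <- f_total
        f <- rel_noise(f, noise_sd)
        id <- sprintf("%s_%03d", conditions$condition[ci], cell)
        traces[[k]] <- exo_trace(time = (seq_len(n_frames) - 1) * dt,
                                 fluorescence = f, stim_frame = stim_frame,
                                 peak_frame = max(rise) + 5,
                                 nh4cl_frame = nh4cl_frame + 5,
                                 cell_id = id,
                                 condition = conditions$condition[ci])
        truth[[k]] <- data.frame(cell_id = id,
                                 condition = conditions$condition[ci],
                                 true_exo = exo_true)
      }
    }
    list(traces = traces, truth = do.call(rbind, truth))
  })
}

#' Generate a two-channel synapsin/SUV droplet image
#'
#' Disk-shaped droplets on both channels: the eGFP channel carries the
#' segmentation signal, the rhodamine channel is `pc` times the outside
#' level inside each droplet. Optional saturated droplets (rhodamine
#' pinned at `sat_level`) emulate detector saturation. Gaussian noise is
#' absolute, scaled to the outside rhodamine level.
#'
#' @param n_droplets Number of droplets (default 12).
#' @param size_px Image edge length, px (default 256).
#' @param pixel_size_um Pixel size, microns (default 0.1).
#' @param radius_um_range Droplet radius range, microns (default 0.4-1.1).
#' @param pc True partition coefficient (default 10).
#' @param egfp_in,egfp_bg eGFP levels inside/outside droplets.
#' @param rho_out Outside rhodamine level (default 20).
#' @param n_saturated Droplets rendered saturated (default 0).
#' @param sat_level Saturation level (default 4095, 12-bit).
#' @param noise_sd Gaussian noise sd relative to `rho_out` (default 0.02).
#' @param seed Seed.
#' @return List with `egfp`, `rhodamine` (matrices), `pixel_size_um`,
#'   `sat_level`, and `truth` (data.frame of centres, radii and per-droplet
#'   true pc; saturated droplets marked).
#' @export
gen_droplet_image <- function(n_droplets = 12, size_px = 256,
                              pixel_size_um = 0.1,
                              radius_um_range = c(0.4, 1.1), pc = 10,
                              egfp_in = 200, egfp_bg = 10, rho_out = 20,
                              n_saturated = 0, sat_level = 4095,
                              noise_sd = 0.02, seed = 1) {
  with_seed(seed, {
    xg <- matrix(rep(seq_len(size_px), size_px), size_px)
    yg <- t(xg)
    egfp <- matrix(egfp_bg, size_px, size_px)
    rho <- matrix(rho_out, size_px, size_px)
    placed <- data.frame()
    margin <- ceiling(max(radius_um_range) / pixel_size_um) + 4
    tries <- 0
    while (nrow(placed) < n_droplets && tries < 2000) {
      tries <- tries + 1
      r_um <- runif(1, radius_um_range[1], radius_um_range[2])
      r_px <- r_um / pixel_size_um
      cx <- runif(1, margin, size_px - margin)
      cy <- runif(1, margin, size_px - margin)
      if (nrow(placed) > 0 &&
          any(sqrt((placed$cx - cx)^2 + (placed$cy - cy)^2) <
              (placed$r_px + r_px + 6))) next
      sat <- nrow(placed) < n_saturated
      disk <- (xg - cx)^2 + (yg - cy)^2 <= r_px^2
      egfp[disk] <- egfp_in
      rho[disk] <- if (sat) sat_level else pc * rho_out
      placed <- rbind(placed, data.frame(
        cx = cx, cy = cy, r_px = r_px, radius_um = r_um,
        area_um2 = pi * r_um^2, pc = pc, saturated = sat))
    }
    if (noise_sd > 0) {
      egfp <- egfp + rnorm(length(egfp), 0, noise_sd * rho_out)
      rho <- pmin(rho + rnorm(length(rho), 0, noise_sd * rho_out), sat_level)
    }
    list(egfp = egfp, rhodamine = rho, pixel_size_um = pixel_size_um,
         sat_level = sat_level, truth = placed)
  })
}
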