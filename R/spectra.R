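#' Emission spectrum container
#'
#' One tryptophan fluorescence titration point: a wavelength grid with
#' baseline-subtracted intensities at a given total lipid and protein
#' concentration. All spectral arithmetic in the package is carried out on
#' the wavenumber axis, `nu = 1e7 / lambda(nm)` in cm^-1; this container
#' keeps the raw wavelength grid.
#'
#' @param wavelengths Wavelength grid in nm, strictly increasing
#'   (default 300-500 nm in 10 nm steps).
#' @param intensities Baseline-subtracted fluorescence, arbitrary units.
#' @param lipid_conc Total lipid concentration, molar (>= 0).
#' @param protein_conc Protein concentration, molar (> 0).
#' @param label Variant identifier (e.g. `"WT"`, `"A30P"`).
#' @return An object of class `emission_spectrum`.
#' @export
emission_spectrum <- function(wavelengths = seq(300, 500, by = 10),
                              intensities,
                              lipid_conc = 0,
                              protein_conc = 1e-7,
                              label = "WT") {
  wavelengths <- as.numeric(wavelengths)
  intensities <- as.numeric(intensities)
  if (length(wavelengths) != length(intensities))
    stopf("wavelengths and intensities differ in length")
  if (any(diff(wavelengths) <= 0))
    stopf("wavelengths must be strictly increasing")
  if (!all(is.finite(intensities)))
    stopf("intensities must be finite")
  if (lipid_conc < 0) stopf("lipid_conc must be >= 0")
  if (protein_conc <= 0) stopf("protein_conc must be > 0")
  structure(
    list(wavelengths = wavelengths, intensities = intensities,
         lipid_conc = lipid_conc, protein_conc = protein_conc, label = label),
    class = "emission_spectrum")
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf("<emission_spectrum> %s: %d points %g-%g nm, lipid %.3g M, protein %.3g M\n",
              x$label, length(x$wavelengths), min(x$wavelengths),
              max(x$wavelengths), x$lipid_conc, x$protein_conc))
  invisible(x)
}

wavelength_to_wavenumber <- function(lambda_nm) 1e7 / lambda_nm
wavenumber_to_wavelength <- function(nu_cm) 1e7 / nu_cm

#' Log-normal band-shape parameter set
#'
#' The biparametric log-normal model for a single-fluorophore emission band
#' on the wavenumber axis:
#' \deqn{I(\nu) = I_m \exp\left[-\frac{\ln 2}{\ln^2\rho}
#'   \ln^2\frac{a-\nu}{a-\nu_m}\right], \quad \nu < a; \qquad I(\nu \ge a) = 0}
#' with band asymmetry \eqn{\rho = (\nu_m-\nu_-)/(\nu_+-\nu_m) > 1}
#' (\eqn{\nu_+}/\eqn{\nu_-} the high/low-wavenumber half-maximum positions),
#' bandwidth \eqn{H = \nu_+-\nu_-}, and limiting point
#' \eqn{a = \nu_m + H\rho/(\rho^2-1)} on the high-wavenumber side.
#'
#' @param Im Peak intensity, a.u.
#' @param nu_m Wavenumber of the fluorescence maximum, cm^-1.
#' @param rho Band asymmetry (> 1).
#' @param H Bandwidth `nu_plus - nu_minus`, cm^-1 (> 0).
#' @param residual_rms Root-mean-square fit residual, a.u. (0 for a
#'   constructed parameter set).
#' @param converged Logical convergence flag.
#' @return An object of class `lognormal_fit` carrying the derived
#'   quantities `a`, `nu_plus`, `nu_minus` and `lambda_max` (nm).
#' @export
lognormal_fit <- function(Im, nu_m, rho, H, residual_rms = 0, converged = TRUE) {
  if (rho <= 1) stopf("rho must be > 1")
  if (H <= 0) stopf("H must be > 0")
  if (Im <= 0) stopf("Im must be > 0")
  a <- nu_m + H * rho / (rho^2 - 1)
  structure(
    list(Im = Im, nu_m = nu_m, rho = rho, H = H, a = a,
         nu_plus = nu_m + H / (1 + rho),
         nu_minus = nu_m - H * rho / (1 + rho),
         lambda_max = wavenumber_to_wavelength(nu_m),
         residual_rms = residual_rms, converged = converged),
    class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf(
    "<lognormal_fit> Im=%.4g  nu_m=%.1f cm-1 (lambda_max=%.1f nm)  rho=%.3f  H=%.1f cm-1  rms=%.3g%s\n",
    x$Im, x$nu_m, x$lambda_max, x$rho, x$H, x$residual_rms,
    if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Evaluate the log-normal band shape
#'
#' @param fit A [lognormal_fit()] object.
#' @param nu Wavenumbers (cm^-1), any length.
#' @return Intensities; exactly 0 where `nu >= a`.
#' @export
lognormal_eval <- function(fit, nu) {
  out <- numeric(length(nu))
  below <- nu < fit$a
  r <- (fit$a - nu[below]) / (fit$a - fit$nu_m)
  out[below] <- fit$Im * exp(-(log(2) / log(fit$rho)^2) * log(r)^2)
  out
}

lognormal_core <- function(nu, Im, nu_m, rho, H) {
  a <- nu_m + H * rho / (rho^2 - 1)
  out <- numeric(length(nu))
  below <- nu < a
  out[below] <- Im * exp(-(log(2) / log(rho)^2) *
                           log((a - nu[below]) / (a - nu_m))^2)
  out
}

#' Fit an emission spectrum with the log-normal model
#'
#' Least-squares estimation of `(Im, nu_m, rho, H)` on the wavenumber axis;
#' the limiting point `a` is recomputed from the fitted parameters.
#' Initialisation takes `nu_m` at the grid argmax, `Im` at the maximum
#' intensity, `rho = 1.3`, and `H` from a crude half-maximum scan; `rho`
#' is bounded to (1, 3].
#'
#' @param spectrum An [emission_spectrum()] with at least 5 points of
#'   positive intensity.
#' @param control Passed to [minpack.lm::nls.lm.control()].
#' @return A [lognormal_fit()].
#' @export
fit_lognormal <- function(spectrum, control = minpack.lm::nls.lm.control(maxiter = 200)) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  nu <- wavelength_to_wavenumber(spectrum$wavelengths)
  y <- spectrum$intensities
  o <- order(nu)
  nu <- nu[o]; y <- y[o]
  if (sum(y > 0) < 5)
    stopf("degenerate spectrum: need >= 5 points with positive intensity")

  imax <- which.max(y)
  Im0 <- y[imax]; num0 <- nu[imax]
  # crude half-max scan for a starting bandwidth
  half <- y >= Im0 / 2
  H0 <- diff(range(nu[half]))
  if (!is.finite(H0) || H0 <= 0) H0 <- diff(range(nu)) / 4

  fit <- minpack.lm::nlsLM(
    y ~ lognormal_core(nu, Im, nu_m, rho, H),
    start = list(Im = Im0, nu_m = num0, rho = 1.3, H = H0),
    lower = c(Im = Im0 * 1e-3, nu_m = min(nu), rho = 1 + 1e-4, H = H0 * 1e-2),
    upper = c(Im = Im0 * 10, nu_m = max(nu), rho = 3, H = diff(range(nu)) * 2),
    control = control)

  cf <- coef(fit)
  conv <- fit$convInfo$isConv %||% TRUE
  if (!conv) warnf("log-normal fit did not converge")
  lognormal_fit(cf[["Im"]], cf[["nu_m"]], cf[["rho"]], cf[["H"]],
                residual_rms = sqrt(mean(residuals(fit)^2)),
                converged = conv)
}

#' Emission-maximum vs peak-width heterogeneity points
#'
#' Converts each fit's half-maximum positions back to the wavelength axis
#' and returns `(lambda_max, FWHM)` pairs used to assess the environmental
#' heterogeneity of the emitting tryptophan species. A homogeneous
#' population falls on an empirical straight reference line (determined
#' with free tryptophan in solvents of graded hydrophobicity); that line is
#' supplied by the caller as configuration, never synthesised here.
#'
#' @param fits List of [lognormal_fit()] objects.
#' @param concentrations Lipid concentrations (molar), recycled to
#'   `length(fits)`.
#' @return A data.frame with columns `lambda_max` (nm), `peak_width`
#'   (FWHM on the wavelength axis, nm) and `lipid_conc` (M).
#' @export
heterogeneity_points <- function(fits, concentrations = NA_real_) {
  if (inherits(fits, "lognormal_fit")) fits <- list(fits)
  stopifnot(all(vapply(fits, inherits, TRUE, "lognormal_fit")))
  concentrations <- rep_len(as.numeric(concentrations), length(fits))
  data.frame(
    lambda_max = vapply(fits, function(f) f$lambda_max, 0),
    peak_width = vapply(fits, function(f)
      wavenumber_to_wavelength(f$nu_minus) - wavenumber_to_wavelength(f$nu_plus), 0),
    lipid_conc = concentrations)
}

#' Decompose a titration spectrum into free and bound fractions
#'
#' Solves the simplex-constrained least-squares problem
#' `min || s - (c_f * free + c_b * bound) ||^2` with `c_f, c_b >= 0`,
#' `c_f + c_b = 1`, for spectra measured at matched protein concentration.
#' Under the closed-simplex constraint the problem is one-dimensional and
#' the constrained optimum is the projection of the unconstrained optimum
#' onto [0, 1], so the returned bound fraction is clamped by construction.
#'
#' @param spectrum,free_ref,bound_ref [emission_spectrum()] objects on an
#'   identical wavelength grid; `free_ref` is the lipid-free spectrum and
#'   `bound_ref` the fully bound (highest lipid) spectrum. For variants
#'   that never saturate, pass a substitute bound reference (e.g. the WT
#'   spectrum at the highest lipid concentration).
#' @return The bound fraction `c_b` in [0, 1].
#' @export
decompose_spectrum <- function(spectrum, free_ref, bound_ref) {
  for (s in list(spectrum, free_ref, bound_ref))
    stopifnot(inherits(s, "emission_spectrum"))
  if (!isTRUE(all.equal(spectrum$wavelengths, free_ref$wavelengths)) ||
      !isTRUE(all.equal(spectrum$wavelengths, bound_ref$wavelengths)))
    stopf("wavelength grid mismatch between spectrum and references")
  d <- bound_ref$intensities - free_ref$intensities
  dd <- sum(d * d)
  if (dd <= .Machine$double.eps * sum(bound_ref$intensities^2))
    stopf("free and bound references are identical: decomposition ill-posed")
  cb <- sum((spectrum$intensities - free_ref$intensities) * d) / dd
  min(max(cb, 0), 1)
}
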