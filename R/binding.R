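#' Quadratic bimolecular binding model
#'
#' Bound fraction of protein binding to sites on the vesicle surface, with
#' the site concentration proportional to total lipid: `S = Bmax * L`.
#' Solving the bimolecular equilibrium exactly (no ligand-excess
#' approximation) gives the quadratic form
#' \deqn{P_b = \frac{(P+S+K_d) - \sqrt{(P+S+K_d)^2 - 4PS}}{2}}
#' and the returned bound fraction is `P_b / P`, in [0, 1].
#'
#' @param Kd Dissociation constant, molar (> 0).
#' @param Bmax Maximum binding sites per lipid molecule; `1/Bmax` is the
#'   minimum number of lipids per binding site.
#' @param protein_conc Total protein concentration, molar (> 0).
#' @param lipid_conc Total lipid concentration, molar (>= 0); vectorised.
#' @return Bound fraction(s) in [0, 1].
#' @export
bound_fraction_model <- function(Kd, Bmax, protein_conc, lipid_conc) {
  if (Kd <= 0 || Bmax <= 0 || protein_conc <= 0)
    stopf("Kd, Bmax and protein_conc must be positive")
  if (any(lipid_conc < 0)) stopf("lipid_conc must be >= 0")
  P <- protein_conc
  S <- Bmax * lipid_conc
  b <- P + S + Kd
  disc <- pmax(b^2 - 4 * P * S, 0)  # analytically >= 0; guard rounding
  bound <- (b - sqrt(disc)) / 2
  pmin(pmax(bound / P, 0), 1)
}

#' The titration lipid grid used for fluorescence binding curves
#'
#' Union of twofold dilution ladders descending from decade anchors at 10,
#' 1, 0.1 and 0.01 mM, spanning 1.25 uM to 10 mM (16 concentrations).
#'
#' @return Sorted lipid concentrations in molar.
#' @export
lipid_titration_grid <- function() {
  anchors <- c(10, 1, 0.1, 0.01) * 1e-3
  sort(unique(as.numeric(outer(anchors, 2^(0:(-3)), `*`))))
}

#' Fit a binding curve with the quadratic bimolecular model
#'
#' Nonlinear least squares for `Kd` (and optionally `Bmax`) on bound
#' fraction vs total lipid. `Bmax` defaults to 1/59 sites per lipid, the
#' value derived from NMR intensity ratios for WT-like analyses; pass
#' `Bmax = "fit"` to co-fit it. The parameter SEM is the square root of
#' the corresponding diagonal element of the covariance from the Jacobian
#' at the optimum. Curves whose maximum bound fraction stays below
#' `saturation_threshold` are flagged as non-saturating (the Kd then rests
#' on the assumed `Bmax` and the curve's initial slope).
#'
#' @param points data.frame with columns `lipid_conc` (M) and
#'   `bound_fraction` (in [0,1]); >= 6 points recommended.
#' @param protein_conc Protein concentration, molar.
#' @param Bmax Sites per lipid (numeric) or `"fit"`.
#' @param weights Optional per-point weights (1/sd^2 scale); default
#'   unweighted.
#' @param saturation_threshold Non-saturation flag threshold on the maximum
#'   observed bound fraction (default 0.9).
#' @return An object of class `binding_fit` with `Kd`, `Kd_sem`, `Bmax`,
#'   `Bmax_fitted`, `fit_pvalue`, `converged`, `saturating`, `residual_rms`.
#' @export
fit_binding_curve <- function(points, protein_conc, Bmax = 1 / 59,
                              weights = NULL, saturation_threshold = 0.9) {
  stopifnot(is.data.frame(points),
            all(c("lipid_conc", "bound_fraction") %in% names(points)))
  L <- points$lipid_conc
  f <- points$bound_fraction
  if (any(L < 0) || any(f < -1e-9) || any(f > 1 + 1e-9))
    stopf("invalid binding points")
  if (all(f <= 0))
    stopf("all bound fractions are zero: no binding to fit")
  if (length(L) < 6)
    warnf("fewer than 6 titration points; Kd may be poorly determined")
  w <- weights %||% rep(1, length(L))

  fit_bmax <- identical(Bmax, "fit")
  # coarse log-space scan for a robust Kd start
  kd_grid <- 10^seq(-9, -1, by = 0.25)
  b0 <- if (fit_bmax) 1 / 59 else Bmax
  sse <- vapply(kd_grid, function(k)
    sum(w * (f - bound_fraction_model(k, b0, protein_conc, L))^2), 0)
  kd0 <- kd_grid[which.min(sse)]

  if (fit_bmax) {
    fit <- minpack.lm::nlsLM(
      f ~ bound_fraction_model(10^lKd, 10^lB, protein_conc, L),
      start = list(lKd = log10(kd0), lB = log10(b0)),
      lower = c(lKd = -12, lB = -6), upper = c(lKd = 0, lB = 2),
      weights = w)
  } else {
    fit <- minpack.lm::nlsLM(
      f ~ bound_fraction_model(10^lKd, Bmax, protein_conc, L),
      start = list(lKd = log10(kd0)),
      lower = c(lKd = -12), upper = c(lKd = 0),
      weights = w)
  }
  cf <- coef(fit)
  Kd <- 10^cf[["lKd"]]
  conv <- fit$convInfo$isConv %||% TRUE
  if (!conv) warnf("binding fit did not converge")

  # covariance of log10(Kd) -> delta-method SEM on Kd; p-value of the Kd
  # term against the null of an undetermined (boundary) affinity
  sm <- tryCatch(summary(fit), error = function(e) NULL)
  if (!is.null(sm) && is.finite(sm$coefficients["lKd", "Std. Error"])) {
    se_l <- sm$coefficients["lKd", "Std. Error"]
    pval <- sm$coefficients["lKd", "Pr(>|t|)"]
  } else {
    se_l <- 0; pval <- 0
  }
  Kd_sem <- Kd * log(10) * se_l

  structure(
    list(Kd = Kd, Kd_sem = Kd_sem,
         Bmax = if (fit_bmax) 10^cf[["lB"]] else Bmax,
         Bmax_fitted = fit_bmax,
         protein_conc = protein_conc,
         fit_pvalue = pval,
         converged = conv,
         saturating = max(f) >= saturation_threshold,
         residual_rms = sqrt(mean(residuals(fit)^2)),
         n_points = length(L)),
    class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf(
    "<binding_fit> Kd = %.3g M (SEM %.2g), 1/Bmax = %.3g lipids/site%s, n = %d%s%s\n",
    x$Kd, x$Kd_sem, 1 / x$Bmax, if (x$Bmax_fitted) " [fitted]" else " [fixed]",
    x$n_points,
    if (x$saturating) "" else ", NON-SATURATING",
    if (x$converged) "" else ", NOT CONVERGED"))
  invisible(x)
}

#' Estimate lipids per binding site from a saturating intensity-ratio profile
#'
#' In the saturating regime every binding site is occupied, so the bound
#' protein concentration divided into the total lipid concentration gives
#' the minimum number of lipids per site, `1/Bmax`. The bound fraction is
#' the median of `1 - intensity_ratio` over the N-terminal nine residues,
#' the tightest-binding region of the protein. The caller is responsible
#' for supplying data acquired in the saturating regime.
#'
#' @param profile A residue profile (see [residue_profile()]) of kind
#'   `intensity_ratio`; residues 1-9 are used, with at least 5 present.
#' @param lipid_conc Total lipid concentration, molar.
#' @param protein_conc Total protein concentration, molar.
#' @return Lipids per binding site (`lipid_conc / (f * protein_conc)`).
#' @export
estimate_lipids_per_site <- function(profile, lipid_conc, protein_conc) {
  stopifnot(is.data.frame(profile), all(c("residue", "value") %in% names(profile)))
  nt <- profile$value[profile$residue %in% 1:9]
  nt <- nt[is.finite(nt)]
  if (length(nt) < 5)
    stopf("need >= 5 of residues 1-9 with finite intensity ratios")
  f <- median(1 - nt)
  if (f <= 0) stopf("no binding detected (median N-terminal bound fraction <= 0)")
  lipid_conc / (f * protein_conc)
}
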