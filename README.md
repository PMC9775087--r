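# synbind

Quantitative analysis of alpha-synuclein membrane binding and its
consequences for vesicle release. Alpha-synuclein is an intrinsically
disordered presynaptic protein whose lipid-binding domain (residues 1–94)
folds into membrane-bound helices; how tightly it binds small unilamellar
vesicles (SUVs), and in which conformational mode, shapes both inhibition
and potentiation of stimulated exocytosis. `synbind` implements the
quantitative pipeline such studies rely on, for spectroscopists and cell
biologists who have the measurements (emission spectra, NMR peak tables,
per-cell fluorescence traces, two-channel droplet images) and need the
derived quantities: dissociation constants, exchange rates, exocytosis
fractions and condensate partition coefficients.

## What it computes

**Tryptophan emission spectra.** Single-fluorophore emission bands are
fit on the wavenumber axis with the biparametric log-normal model

    I(v) = Im * exp( -(ln 2 / ln^2 rho) * ln^2( (a - v) / (a - v_m) ) ),  v < a

with peak intensity `Im` at wavenumber `v_m`, band asymmetry
`rho = (v_m - v_-)/(v_+ - v_m) > 1`, bandwidth `H = v_+ - v_-` and
limiting point `a = v_m + H*rho/(rho^2 - 1)`. Emission-maximum vs
peak-width plots probe the heterogeneity of the emitting species, and
titration spectra are decomposed into free/bound fractions by
simplex-constrained least squares against lipid-free and fully bound
reference spectra.

**Binding isotherms.** Bound fractions vs total lipid `L` are fit with
the quadratic bimolecular model between protein `P` and binding sites
`S = Bmax * L`,

    bound = ( (P + S + Kd) - sqrt( (P + S + Kd)^2 - 4 P S ) ) / (2 P),

with `1/Bmax` — the minimum number of lipids per binding site — fixed
from NMR intensity ratios in the saturating regime (median bound fraction
of residues 1–9), or co-fitted on request.

**Exchange kinetics (DEST / R2).** Dark-state exchange saturation
transfer profiles and transverse relaxation enhancements are simulated
and fit under the homogeneous McConnell equations for a spin exchanging
between a visible free state and NMR-dark bound states, propagating
(x, y, z) magnetization per state plus a homogeneous constant through a
matrix exponential over the 900 ms saturation pulse at each offset and
bandwidth. Two models are supported: a global two-state fit
(`kon_app`, `koff`, `R2_bound`) and the pseudo-two-state fit in which
each residue is either in direct contact with the vesicle surface or
tethered to it, with residue-wise `K3(i) = k2_app(i)/k1_app(i)`
quantifying the balance. CPMG R2 decays and a pseudo-first-order
consistency check (enhancements scale with lipid, not protein,
concentration) round out the module.

**Cell and condensate assays.** pHluorin exocytosis fractions
`Exo = (F_stim - F_basal)/(F_total - F_basal)` from 5-frame window means;
1.5×IQR outlier filtering and expression-level comparisons with the
printed significance categories; recycling-endosome peripheral fractions
in an 800 nm membrane shell; and synapsin-condensate droplet segmentation
(Gaussian blur, rolling-ball-equivalent background subtraction, Li
thresholding, area filter) with per-droplet SUV partition coefficients.

**Synthetic data.** Every pipeline stage has a seeded generator with
machine-readable ground truth (`gen_titration_spectra`,
`gen_dest_dataset`, `gen_intensity_profile`, `gen_exo_traces`,
`gen_droplet_image`), so the full analysis is testable end to end without
any measured input.

## Worked example

Simulate a fluorescence titration at the study design (0.1 uM protein,
1.25 uM–10 mM lipid in twofold steps, 59 lipids per site, 1% noise),
decompose each spectrum and refit the dissociation constant:

```r
library(synbind)
sim <- gen_titration_spectra(Kd = 1.12e-6, noise_sd = 0.01, seed = 7)
bound <- vapply(sim$spectra, decompose_spectrum, 0,
                free_ref = sim$free_ref, bound_ref = sim$bound_ref)
fit <- fit_binding_curve(data.frame(lipid_conc = sim$truth$lipid_conc,
                                    bound_fraction = bound),
                         protein_conc = 1e-7)
fit
#> <binding_fit> Kd = 1.14e-06 M (SEM 2.2e-08), 1/Bmax = 59 lipids/site [fixed], n = 16
```

The generating `Kd` of 1.12e-6 M is recovered within 2% under 1% spectral
noise. The fully bound spectrum refits its log-normal parameters
(`lambda_max` 335.1 nm here), and the saturating-regime site count
reproduces its defining arithmetic:

```r
fit_lognormal(sim$spectra[[16]])
#> <lognormal_fit> Im=1235  nu_m=29839.0 cm-1 (lambda_max=335.1 nm)  rho=1.349  H=4837.8 cm-1  rms=4.2

prof <- residue_profile(1:9, rep(0.1525, 9), "intensity_ratio")
estimate_lipids_per_site(prof, lipid_conc = 2.5e-3, protein_conc = 50e-6)
#> [1] 58.99705
```

See `vignettes/synuclein-membrane-analysis.Rmd` for the models,
assumptions and numerical choices.

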