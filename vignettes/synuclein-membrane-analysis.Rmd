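---
title: "Models and methods: membrane binding, exchange kinetics and vesicle-release assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: membrane binding, exchange kinetics and vesicle-release assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synbind)
```

`synbind` analyses alpha-synuclein membrane binding at three scales:
spectroscopic titrations that yield equilibrium affinity, NMR exchange
experiments that resolve the kinetics and per-residue binding modes, and
cellular/condensate assays that quantify the functional consequences.
This vignette documents the models, their assumptions, the tunable
parameters, and the numerical and design choices a maintainer should
know about. Every statement of performance here is one the test suite
computes itself.

## Log-normal spectral model

Tryptophan emission bands of a single fluorophore are empirically
log-normal on the frequency axis. We parameterise the band by peak
intensity $I_m$ (a.u.), the wavenumber of the maximum $\nu_m$
(cm$^{-1}$), the band asymmetry $\rho > 1$ and the bandwidth $H$
(cm$^{-1}$), with the limiting point
$a = \nu_m + H\rho/(\rho^2 - 1)$ on the high-wavenumber side, above
which the intensity is identically zero:

$$I(\nu) = I_m \exp\!\left[-\frac{\ln 2}{\ln^2 \rho}\,
  \ln^2\!\frac{a - \nu}{a - \nu_m}\right], \quad \nu < a.$$

All arithmetic is done on the wavenumber axis ($\nu = 10^7/\lambda$ with
$\lambda$ in nm), reporting back in nm. One convention deserves
emphasis, because typeset renderings of the asymmetry definition are
ambiguous about which half-maximum is "left": we fix
$\rho = (\nu_m - \nu_-)/(\nu_+ - \nu_m)$ with $\nu_+$ the
high-wavenumber (blue-side) half-maximum position. This makes $\rho > 1$
and $a > \nu_m$ for red-skewed emission, keeps $a$ finite and positive,
and reproduces $I(\nu_\pm) = I_m/2$ exactly (verified against a
root-finding oracle in the tests). With the opposite convention the
limiting point falls on the wrong side of the band.

Fitting uses bounded Levenberg–Marquardt with $\nu_m$ started at the
grid argmax, $I_m$ at the maximum intensity, $\rho = 1.3$ and $H$ from a
crude half-maximum scan; $\rho$ is constrained to $(1, 3]$. On the 10 nm
acquisition grid (300–500 nm, 21 points) this recovers noiseless
parameters to well under 1% and the emission maximum to 0.5% under 1%
noise.

**Spectral decomposition.** Titration spectra are modelled as convex
combinations of a lipid-free reference and a fully bound reference at
matched protein concentration. We impose the closed simplex
$c_f + c_b = 1$, $c_b \ge 0$ — not merely nonnegativity — because
matched protein concentrations justify it and it prevents
intensity-scale drift from masquerading as binding. Under that
constraint the quadratic program collapses to one dimension and the
optimum is the projection of the unconstrained least-squares solution
onto $[0, 1]$; we use this closed form (it is the exact QP solution, and
the tests confirm it against a grid search). For variants that never
reach saturation, the bound reference is substituted by configuration
(e.g. the WT spectrum at 10 mM lipid), mirroring the experimental
practice.

## Quadratic binding model

Binding sites on the vesicle surface are proportional to total lipid,
$S = B_{max} L$, and the protein–site equilibrium is solved exactly
(quadratic in the bound concentration) rather than assuming ligand
excess — essential because the titration deliberately spans
protein-comparable site concentrations. The default
$1/B_{max} = 59$ lipids per binding site comes from the NMR
intensity-ratio estimate in the saturating regime: with every site
occupied, total lipid divided by bound protein (median bound fraction of
the N-terminal nine residues times total protein) counts the lipids per
site. That estimator is only meaningful in saturation; the function
documents, and the tests exercise, its invariance to joint rescaling of
lipid and protein only when the ratios are held fixed.

`fit_binding_curve` optimises $\log_{10} K_d$ (affinities span four
decades across variants) with a coarse log-grid start, reports the SEM
by the delta method from the Jacobian covariance at the optimum, and
flags curves whose maximum bound fraction stays below 0.9 as
non-saturating — for those, the estimate leans on the assumed $B_{max}$
and the initial slope, which is exactly the situation of the
weakest-binding double mutant. The titration grid reconstructs the
experimental design as the union of twofold dilution ladders from decade
anchors (10, 1, 0.1, 0.01 mM), spanning 1.25 µM–10 mM in 16 points; the
fit accepts any grid.

## DEST and relaxation: the exchange models

The saturation-transfer experiment is modelled with the homogeneous
McConnell equations: each exchanging state carries $(M_x, M_y, M_z)$,
all states share the free-state resonance (the bound state is broadened,
not shifted), a continuous-wave field of amplitude $\omega_1$ acts for
0.9 s at offset $\Delta\omega$, and longitudinal relaxation returns
$M_z$ to the stationary populations through a homogeneous constant row.
The full evolution matrix ($3n + 1$ dimensional for $n$ states) is
exponentiated once per offset (RcppArmadillo); an independent
fixed-step RK4 integrator lives in the test suite and agrees with the
propagator to $10^{-6}$, and the exact $\pm$offset symmetry of the
profiles is both tested and exploited (only nonnegative offsets are
propagated).

Choices the experiment leaves open, and what we adopted:

* **Saturation amplitude**: $\omega_1/2\pi$ equals the nominal bandwidth
  (400/175 Hz or 500/200 Hz pairs), as implied by pulse-length
  calibration under an ideal linear amplifier.
* **Normalisation reference**: the mean of the two extreme-offset points
  (±30 kHz), configurable to an explicit no-saturation (equilibrium)
  reference; the source analysis does not name its reference experiment.
* **$R_1$**: a single longitudinal rate of 1.5 s$^{-1}$ shared by all
  states; DEST at these powers is $R_2$-dominated, so this choice is
  uncritical, and it is configurable.
* **Offset grid**: 17 points across ±30 kHz by default. The acquisition
  range is stated by the experiment; the sampling density is ours, chosen
  at the sparse end of common DEST practice — much sparser grids leave
  the per-residue pseudo-two-state parameters underdetermined.
* **Observed $\Delta R_2$**: predicted from the slowest-decaying
  transverse eigenmode of $K - \mathrm{diag}(R_2)$, i.e. lifetime
  broadening including partial averaging, which reduces to
  $k_{on}^{app}$ in the slow-exchange limit.

**Two-state fit.** Global $(k_{on}^{app}, k_{off}, R_{2,bound})$ over
log-transformed rates, multi-start local least squares (seeded), bounds
$k_{on}^{app} \in [10^{-3}, 10^3]$, $k_{off} \in [10^{-1}, 10^4]$,
bound-state $R_2 \in [10, 10^5]$ s$^{-1}$. The joint objective weights
DEST ratio residuals by an assumed 0.02 ratio error and $\Delta R_2$
residuals by 5% of the mean observed enhancement, so a fit is judged in
large part by its ability to reproduce the relaxation enhancements —
which is also how model adequacy is assessed.

**Pseudo-two-state fit.** Bound conformations split per residue into a
direct-contact mode (very large, globally shared $R_2$) and a tethered
mode (moderate, residue-specific $R_2$), with apparent on-rates
$k_2^{app}(i)$ and $k_1^{app}(i)$, a global off-rate
$k_{off} = k_{-1} = k_{-2}$, and the derived mode balance
$K_3(i) = k_2^{app}(i)/k_1^{app}(i)$. The optimiser alternates block
coordinate descent: exact per-residue fits (three canonical starts —
tethered-dominant, direct-dominant, balanced — plus the warm start, with
periodic jittered re-seeding) against a cheap global update at fixed
residue parameters, after a coarse log-grid initialisation of
$(k_{off}, R_{2,direct})$. Each block step decreases the joint
objective, which keeps the nested problem stable at a fraction of the
cost of profiling the globals. Direct interconversion between bound
modes ($k_3$, $k_{-3}$) can be added to the global block behind a flag
and is kept only if it lowers the objective; it matters only when faster
than $k_{off}$. Residues whose rates pin to the box bounds are flagged
non-identifiable rather than silently reported.

At the simulation sizes used in the tests (10–20 residues, two
bandwidths, 17 offsets) the two-state fit recovers noiseless truths
within 10%, the pseudo-two-state fit recovers a $K_3$ ramp from 0.2 to 2
within 25% per residue at 2% noise, and a strongly bimodal
pseudo-two-state truth leaves the two-state fit with at least twice the
$\Delta R_2$ residual sum — the model-discrimination logic used to
prefer one model per variant. The C-terminal tail (residues beyond 98)
is never fit as exchanging.

**CPMG.** Relaxation delays are multiples of the 16.32 ms
delay–pulse–delay element (0–18 elements, 293.76 ms maximum), scrambled
under a seed; decays are fit as single exponentials with the triplicate
mid-range point supplying the noise scale for the standard error. The
pseudo-first-order check regresses per-condition mean $\Delta R_2$
against lipid (at the modal protein concentration) and against protein
(at the modal lipid), with residue-bootstrap confidence intervals; the
verdict requires a lipid slope whose CI excludes zero and a protein
effect that is either CI-consistent with zero or below 20% relative.

## Cell assays

**Exocytosis.** $Exo = (F_{stim} - F_{basal})/(F_{total} - F_{basal})$,
each $F$ the mean of a 5-frame window: the five frames ending at the
stimulation frame, the five starting at the post-stimulation peak, and
the five starting at the NH$_4$Cl plateau frame. The peak frame was
chosen manually in the source workflow; we auto-detect it as the argmax
of a 5-frame running mean between stimulation and NH$_4$Cl (stopping the
search five frames short so the stimulated window and the smoothing
support stay clear of the NH$_4$Cl response), overridable per cell. As a
ratio of differences the measure is invariant to gain and offset; a
near-zero denominator is flagged undefined, and values outside $[0,1]$
are flagged, never clipped.

**Outlier rule and comparisons.** The 1.5×IQR rule uses linear
interpolation between order statistics (R's type-7 quantile), fixed and
documented because conventions differ and the rule's outcome can depend
on them. Expression-level comparisons report the mean difference
(high − low) as the potentiation measure with a Welch t-test and the
printed category thresholds (*** < 0.001 < * < 0.05 < NS); every
comparison is also reported without outlier removal.

**Recycling-endosome shell.** The peripheral fraction is the percentage
of in-mask fluorescence within an inner band of the cell boundary of the
requested physical thickness (800 nm default), computed by binary
erosion with a disc; shell thicknesses below one pixel are refused
rather than silently rounded up.

**Droplet partitioning.** The eGFP (synapsin) channel is blurred
(Gaussian, 2 px), background-subtracted by grayscale opening with a flat
40 px disc (the morphological equivalent of the rolling ball at this
geometry — the ball is chosen larger than any droplet, so only its
footprint matters), thresholded with Li's minimum-cross-entropy
iteration, and labelled 8-connected. Per droplet, the partition
coefficient is mean rhodamine inside over mean rhodamine outside
(inverted threshold). Two documented extensions, both on by default and
both disableable for literal replication: a 2 px guard band around
droplets is excluded from "outside", and an inner margin of
$\lceil\sigma_{blur}\rceil + 1$ px is excluded from "inside". The margin
exists because a minimum-cross-entropy threshold on a sparse-foreground
image sits low, so the mask includes the blur skirt whose pixels carry
outside-level tracer signal; without the margin the measured coefficient
is biased low by roughly half at the study geometry. Areas are always
measured on the unshrunken mask, and the 0.2 µm² area filter is an exact
cut on that area. Saturated-droplet removal is automated (any droplet
containing a rhodamine pixel at or above the stated level is dropped) in
place of the manual curation of the source workflow. Group comparisons
log-transform, IQR-filter, check near-normality (Shapiro–Wilk) and
t-test, again reported with and without outlier removal.

Two numerical notes. Li's update takes logarithms of the class means,
which degenerates when an idealised background is exactly zero after
perfect background subtraction; class means are floored at $10^{-3}$ of
the dynamic range. And EBImage's grayscale morphology operates on
$[0,1]$-scaled data, so the opening rescales around it.

## The synthetic generators

Each generator emulates the statistical structure its consumer assumes,
under the study's design conditions, and returns its ground truth:

* `gen_titration_spectra`: free/bound log-normal references (defaults:
  red-shifted free state near 348 nm, blue-shifted bound state near
  335 nm) mixed according to the quadratic model on the 16-point lipid
  grid at 0.1 µM protein; 1% relative noise by default.
* `gen_dest_dataset`: both-bandwidth DEST profiles and $\Delta R_2$ from
  a two-state or pseudo-two-state truth ($K_3$ ramping 0.2→2 by default,
  or any per-residue profile), per-residue free $R_2$ drawn in
  3–6 s$^{-1}$; 2% noise default; a lipid-scale multiplier on the
  on-rates emulates pseudo-first-order proportionality.
* `gen_intensity_profile`: N-to-C graded intensity ratios (tightest
  binding at the N-terminus) with optional step breaks at residue 34 or
  65 emulating truncated binding modes; prolines reported missing.
* `gen_exo_traces`: plateau traces on the assay timeline (2 s frames,
  baseline, stimulated rise, NH$_4$Cl plateau), per-cell true Exo drawn
  per condition; 5% trace noise default.
* `gen_droplet_image`: non-overlapping disks on both channels with a
  known partition coefficient, optional saturated droplets, noise scaled
  to the outside tracer level.

Noise defaults (1–2% for spectra and NMR ratios, 5% for cell traces) are
plausible bench magnitudes chosen once; the experiments report none.
What the generators deliberately do not model: shot noise, spectrometer
lineshapes, optical PSFs on the tracer channel, scattering or
inner-filter effects, cell-to-cell baseline drift. Passing tests
therefore demonstrate correctness of the estimators under the stated
statistical structure — not robustness to every artefact of real data.

## Problem sizes and limitations

The test suite runs the exchange fits at 8–20 residues with 17 offsets
and two bandwidths, Monte-Carlo loops at 40–200 replicates, and droplet
fields of 12–30 droplets at 256–384 px — sizes at which the full suite
completes in a few minutes while still exercising every recovery claim
above. Known limitations: the exchange models share a single $R_1$ and
ignore cross-relaxation and multi-spin effects; the DEST normalisation
convention is ours, not the source's (unstated); the pseudo-two-state
per-residue parameters are only identifiable with adequate offset
sampling and both bandwidths; `Kd` from non-saturating curves inherits
the assumed $B_{max}$; and the droplet pipeline assumes registered
channels and segmentation-quality contrast on the synapsin channel.
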