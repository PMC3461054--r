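---
title: "Stability analysis of weak coiled-coil heterodimers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability analysis of weak coiled-coil heterodimers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coilstab)
```

This vignette is the package's account of the science it implements:
the models, their assumptions, the numerical choices, and what the
synthetic-data tests do and do not demonstrate about real data. The
running system is the stalk heterodimer of the kinesin-II motor
(KLP64D/KLP68D in *Drosophila*), a weak coiled coil whose published
stability parameters anchor the package's defaults and checks, but
every operation is generic.

## The two-state thermal-unfolding model

A thermal melt followed by CD at 222 nm reports the helical content of
the sample as a function of temperature. We assume an apparent
two-state equilibrium between folded (N) and unfolded (U) states of
the heterodimer treated as a single cooperative unit — no intermediate
states, no explicit dissociation-coupled dimer model, and reversibility
over the scan. The observable is modelled as a population-weighted
mixture of two linear baselines:

$$Y_0(T) = (1 - f_U)\,(y_N + m_N T) + f_U\,(y_U + m_U T)$$

The unfolded fraction, apparent equilibrium constant and free energy
follow as $f_U = (Y_0 - b_N)/(b_U - b_N)$, $K = f_U/(1-f_U)$ and
$\Delta G = -RT\ln K$ with $R = 8.314\times10^{-3}$ kJ mol$^{-1}$
K$^{-1}$. The stability curve is the Gibbs–Helmholtz form with a
temperature-independent heat-capacity change,

$$\Delta G(T) = \Delta H_m\!\left(1-\frac{T}{T_m}\right) +
  \Delta C_p\!\left[(T - T_m) - T\ln\frac{T}{T_m}\right],$$

whose stationary point is the temperature of maximum conformational
stability $T_s = T_m \exp(-\Delta H_m/(\Delta C_p T_m))$. We verified
that this form, with $\Delta C_p$ solved from the stationarity
condition at the reported $T_s$, reproduces the reported
$\Delta G(295\,\mathrm{K})$ for both stalk-heterodimer constructs to
within the rounding of the printed inputs (0.89 vs 0.90 and 1.20 vs
1.19 kJ/mol) — which is why `meltfit()` adopts it.

### Defaults and tunable parameters

* **Transition window** for the stability-curve extraction:
  288–334 K. Melts are accepted in °C or K; everything internal is K.
* **Baseline windows**: the lowest 10 K of the data for the native
  line, the highest 15 K for the unfolded line, both configurable.
* **Clipping**: $f_U$ is clipped to $[\varepsilon, 1-\varepsilon]$
  with $\varepsilon = 10^{-4}$ before the logit; clipped points are
  excluded from the stability fit, since their $\Delta G$ reflects
  baseline noise, not the transition.
* **Reference temperature** for the reported free energy: 295 K.
* **Weights** (staged fit): the $\Delta G$ points are weighted by
  $(f_U(1-f_U))^2$, the inverse-variance weight obtained by
  propagating constant noise on the observable through the logit —
  points near the window edges otherwise dominate the fit with
  enormously inflated variance.

## Estimator design: staged versus global fitting

`meltfit(method = "staged")` is the literal textbook chain: windowed
OLS baselines, $f_U$, $\Delta G$, then a Levenberg–Marquardt fit of
the Gibbs–Helmholtz curve with deterministic starts ($T_{m,0}$ at the
interpolated zero crossing, $\Delta H_{m,0}$ from the central van't
Hoff slope, $\Delta C_{p,0} = 0.5$ kJ/mol/K).

The staged chain presumes the baseline windows contain pure native or
pure unfolded protein. For a *marginally stable* dimer this fails on
the native side: with the default parameters the population is already
~6% unfolded at 278 K and climbing, so the "native" window is
contaminated and the windowed native line absorbs the transition
onset. `meltfit(method = "global")` — the default — therefore uses the
staged estimates only as starting values and refits all seven
parameters (two baselines plus thermodynamics) jointly to the raw
observable. On noise-free two-state data the global fit is exact to
numerical precision, because the generating model is in the model
class.

### Identifiability, and the constraints the global fit imposes

With realistic noise the unconstrained 7-parameter problem is not
identifiable for marginally stable proteins: a degenerate valley
exists in which a steep pseudo-baseline plus a very broad transition
(small $\Delta H_m$, large $\Delta C_p$) fits the data slightly
*better* than the truth basin. Two a-priori restrictions remove it:

1. **Baseline slope bounds.** CD melt baselines drift gently; both
   slopes are bounded at 1% of the transition amplitude per Kelvin.
2. **Admissibility of optima.** Multistart candidates are rejected if
   their baselines cross inside the data range (the degenerate
   geometry) or if their fitted transition is not bracketed by the
   data ($f_U > 0.4$ at the coldest point or $< 0.6$ at the hottest):
   a two-state baseline analysis is only meaningful when the data
   bracket the transition.

Even so, the native baseline of a marginal dimer is weakly determined
— at the coldest accessible temperature the transition term still
dominates the curve slope severalfold — and that uncertainty
propagates: on synthetic melts with noise at 2% of the transition
amplitude, seed-averaged recovery errors are about 1 K in $T_m$ and
5% in $\Delta H_m$, and $\Delta C_p$ scatters strongly between seeds
(sometimes collapsing to its boundary at zero, where $T_s$ is
undefined and reported as absent). $T_s$ amplifies $\Delta C_p$ error
exponentially and is the least reliable derived quantity; its wide
per-fit standard errors are reported rather than hidden. Users with
stable proteins (clean native plateaus) will see none of this; users
with marginal ones should treat $T_s$ and $\Delta C_p$ from a single
melt as order-of-magnitude estimates, as one would from any
single-curve analysis.

## CD spectrum indices

Raw millidegree ellipticity is normalised to mean residue molar
ellipticity $[\Theta] = \theta / (10\,C\,l\,N)$ (deg cm$^2$
dmol$^{-1}$), with molar concentration, path length in cm and residue
count; for an intact dimer, $N$ is per complex and is deliberately an
explicit user input — helix fractions depend on it and tags/constructs
change it. Values at exactly 208 and 222 nm are linearly interpolated
on the acquisition grid (negligible error at sub-nm pitch).

The $[\Theta]_{222}/[\Theta]_{208}$ ratio is classified against the
empirical anchors 0.83 (isolated helix) and 1.03 (two-stranded coiled
coil) with a dead-band: ≥ 0.98 is coiled-coil-like, ≤ 0.88 is
helix-like, between is intermediate. The anchors and band are
configurable; the dead-band acknowledges that the distinction is
qualitative near the midpoint.

Helix content is estimated two ways: the chain-length formula
$[\Theta]_{222} = -40000\,(1 - 4.6/n)$ for a fully helical chain of
$n$ residues (observed/predicted, clipped to [0, 1]), and non-negative
least squares against a reference basis. The shipped basis
(`cd_basis_spectra()`) is *synthetic*: analytic band shapes carrying
the canonical features (helix: +192 nm band, 208/222 nm double
minima). It is adequate for mixture round-trips and rough estimates;
for publication-grade deconvolution supply an instrument-calibrated
basis. The NNLS solver is a small Lawson–Hanson implementation;
coefficients are normalised to sum to one and the helix coefficient is
the reported fraction. Note the two estimators can legitimately
disagree on real spectra — they answer subtly different questions —
and both are reported.

## Heptad register and atypicality

Coiled-coil sequences repeat with period seven (a–g), hydrophobic at
`a`/`d`. `assign_register()` applies user-specified coil blocks and
phases deterministically; `score_register()` is an explicitly simple
hydropathy scanner (windowed Kyte–Doolittle contrast between implied
a/d positions and the rest, best of the 7 phase offsets per window,
deterministic lowest-offset tie-break flagged low-confidence). It is a
stand-in for dedicated predictors such as MultiCoil or PSIPRED — which
are out of scope — and its reports say so; on designed
heptad-periodic sequences it is essentially exact, which is what the
generator-based tests exercise.

Atypicality counts residues from a configurable charged set (default
D/E/K/R; histidine excluded at physiological pH) occupying `a`/`d`
positions — the substitutions that weaken the hydrophobic seam of weak
coiled coils. Coordinates are 1-based, inclusive, in full-protein
numbering throughout; `segment_scheme()` and the shipped
KLP64D/KLP68D schemes slice stalk fragments without losing the
numbering. Segment boundaries that were never published are left to
user configuration rather than guessed.

## Ensemble metrics

Multi-model PDB files are parsed with bio3d behind `read_ensemble()`
(waters and, by default, HETATM records excluded; per-model atom-count
consistency checked first). All coordinates are Å internally; report
units follow trajectory conventions (nm) where that is how such tables
are usually read.

* **Superposition** is the closed-form SVD (Kabsch) solution
  constrained to proper rotations; it is cross-checked in the tests
  against a brute-force rotational search and against bio3d's
  implementation.
* **RMSF** superposes all frames to the ensemble mean (one mean
  refinement pass) and reports per-atom fluctuation. For a planted
  isotropic per-residue displacement $\sigma_i$ the expectation is
  $\sigma_i\sqrt{3}$; recovery on 100-residue, 500-frame synthetic
  ensembles is within a few percent, with a known alignment-noise
  floor at the low-$\sigma$ end.
* **SASA** is Shrake–Rupley with Bondi radii, probe 1.4 Å and 960
  sphere points by default (quadrature error well under 1% against
  analytic one- and two-sphere areas); unknown elements get 1.5 Å with
  a warning. The hydrophobic/hydrophilic partition is residue-level
  (A/V/L/I/M/F/W/P/G hydrophobic by default) and sums exactly to the
  total by construction.
* **Salt bridges** pair acidic side-chain oxygens (Asp OD1/OD2, Glu
  OE1/OE2, C-terminal OXT) with basic nitrogens (Lys NZ, Arg
  NH1/NH2/NE, N-terminal backbone N) at a 4.0 Å cutoff, deduplicated
  to one bridge per residue pair; **hydrophobic contacts** use minimum
  side-chain heavy-atom distance at 5.0 Å, interchain by default.
  Published trajectory tables rarely state their counting criteria, so
  absolute counts are convention-dependent; the cutoffs are recorded
  in every report and are configurable.
* **Helicity** is assigned from Cα geometry alone (P-SEA-style bands:
  $d_{i,i+3} \in [4.7, 5.7]$ Å and $d_{i,i+4} \in [5.8, 6.7]$ Å over
  4-residue runs), not hydrogen-bond DSSP, so ensembles without
  hydrogens or carbonyl oxygens — including Cα-only models — can be
  scored. Ideal-helix constructions score 100%, extended chains 0%.

## What the generators emulate — and what they do not

The generators produce exactly the structures the operators assume:
two-state melts with linear baselines and homoscedastic Gaussian
noise; spectra that are exact basis mixtures; heptad sequences with a
single clean phase; ensembles that are a base structure plus isotropic
Gaussian displacements and optional rigid motions. Passing the
round-trip tests therefore shows the *inverse* operations are correct
and calibrated, not that real data obey the models: real melts have
scan-rate and reversibility artefacts and heteroscedastic noise; real
spectra have instrument baselines and non-ideal reference sets; real
dynamics are anisotropic and correlated along the chain. The default
melt grid is 278–363 K at 0.5 K pitch — coarser than typical
instrument acquisition but dense enough that fit quality is limited by
noise, not pitch. Test problem sizes (20-seed melt panels, 100-seed
register panels, 500-frame/100-residue ensembles, ≤ 8-atom
superposition toys against brute force) were chosen so the whole suite
runs in seconds while keeping sampling error well inside the asserted
tolerances.

## Known limitations

* Single-wavelength analysis only; no global multi-wavelength fit.
* No chemical-denaturation (m-value), kinetic, three-state or
  dissociation-coupled dimer models.
* The shipped CD basis is generic and synthetic, not an
  instrument-calibrated reference set.
* The register scanner is not a coiled-coil predictor; it assumes the
  sequence is coiled-coil-like and finds the best phase.
* $\Delta C_p$ and $T_s$ from one melt of a marginally stable protein
  are weakly identified (see the estimator section); the package
  reports uncertainties rather than suppressing the problem.
* Trajectory formats beyond multi-model PDB (XTC/DCD) are not read.
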