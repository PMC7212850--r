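---
title: "Absorbed-photon dosimetry for photodynamic therapy: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absorbed-photon dosimetry for photodynamic therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdtdose)
```

## The dose model

Photodynamic therapy kills tissue when the photosensitizer it contains
absorbs enough photons to generate a cytotoxic dose of reactive oxygen. Two
photosensitizers with different activation wavelengths, extinction
coefficients and tissue uptake can only be compared on the **absorbed photon
density**,

$$N_{abs} = \frac{H}{h c / \lambda}\; \mu_{a,ps},
\qquad \mu_{a,ps} = \ln(10)\,\varepsilon(\lambda)\, C,$$

photons absorbed by the drug per cm³ of tissue: radiant exposure $H$
(J·cm⁻²) divided by the photon energy gives the areal photon density, and
the Beer–Lambert absorption coefficient of the drug at its local molar
concentration $C$ converts it to a volumetric count. Physical constants are
the CODATA/SI exact values. Two unit conventions deserve a note:

* **The $\ln(10)$ factor.** Extinction coefficients are tabulated on the
  decadic convention, while radiative transport uses natural-log attenuation;
  `ps_absorption_coefficient()` applies the $\ln(10)$ conversion by default.
  Published absorbed-photon doses do not always state which convention they
  used, and both choices invert published photon-unit LD50s to concentrations
  inside the respective assay ranges, so the factor is an explicit switch
  (`use_ln10`) everywhere it enters — never a silent assumption. All shipped
  defaults use the $\ln(10)$ convention.
* **Power modes.** A flat-field well irradiator is specified by irradiance
  (W·cm⁻²), an interstitial emitter by power (W). Operations refuse the
  wrong mode instead of converting, because the two differ by a geometry
  factor that should never be guessed.

A small worked check: 20 J·cm⁻² at 530 nm is
`r format(radiant_exposure_to_photon_density(20, 530), digits = 4)` hv·cm⁻²;
the printed value in the source study is 5.334×10¹⁹, within 0.05% —
differences at that level trace to rounded constants, which is why the
package's conversion tests use a 0.5% band rather than exact equality.

## Dose–response and LD50 in photon units

`fit_dose_response()` fits percent kill against $\log_{10}$ concentration
with a four-parameter logistic,

$$k(\log c) = b + \frac{t - b}{1 + 10^{\,s\,(\log c_{50} - \log c)}},$$

by Levenberg–Marquardt least squares (`minpack.lm::nlsLM`). Design choices:

* **Free asymptotes.** Assay floors and ceilings drift (metabolic-dye
  baselines, incomplete kill controls), so $b$ and $t$ are estimated, not
  pinned at 0/100; the LD50 is the concentration at the midpoint of the
  *fitted* asymptotes, the convention of the common plotting packages.
* **Normalization.** Each plate is anchored to its own solvent (0% kill) and
  cell-death (100% kill) controls and clipped to [0, 100]. Clipping cannot
  reorder noise-free means (tested). Zero-concentration wells take part in
  normalization but not in the log-dose fit.
* **Precursor stoichiometry.** Pro-drug agents are corrected by a fixed
  precursor ratio (8 ALA consumed per protoporphyrin IX, assuming complete
  conversion) before any photon-unit conversion. No uptake or conversion
  kinetics are modelled — the ratio is a stoichiometric constant, which is
  also the main caveat on the resulting LD50s.
* **Uncertainty.** The fit is parameterized in $\log_{10}c_{50}$; the LD50
  standard deviation on the concentration scale follows by the delta method
  ($\mathrm{sd}(c_{50}) = \ln(10)\,c_{50}\,\mathrm{sd}(\log_{10}c_{50})$),
  and carries through linearly to photon units. A parametric bootstrap is
  available via `simulate()` + refitting.

Published studies sometimes print the photon-unit LD50 without the
underlying concentration. `implied_ld50_concentration()` inverts the chain;
the package's synthetic plate truths are defined this way, so the generator,
the fitter and the conversion close a loop that is tested to 10⁻⁹ relative.

## Light transport

Interstitial delivery uses an isotropic point emitter. Two transport models:

* **Diffusion closed form** (infinite homogeneous medium):
  $\phi(r) = P e^{-\mu_{eff} r} / (4\pi D r)$ with
  $D = 1/3(\mu_a + \mu_s')$ and
  $\mu_{eff} = \sqrt{3\mu_a(\mu_a + \mu_s')}$. This is the default for
  threshold work: fast, smooth, and accurate a few transport mean free
  paths from the source in high-albedo brain tissue.
* **Voxel Monte Carlo** (`mc_fluence()`, compiled): photon packets with step
  length $-\ln\xi/\mu_t$, absorption deposition $w\,\mu_a/\mu_t$ per
  interaction, Henyey–Greenstein scattering sampled at
  $\mu_s = \mu_s'/(1-g)$, Russian roulette below weight 10⁻⁴ with survival
  probability 0.1 (the survivor's weight gain is debited against the
  terminated bucket, so absorbed + escaped + roulette-net equals the
  launched weight to floating-point accuracy — asserted at 10⁻⁶ in every
  run). Homogeneous phantoms take analytic steps without voxel marching;
  heterogeneous ones march voxel to voxel consuming dimensionless optical
  path, which the tests cross-check against the fast path on a two-label
  phantom with identical optics. The RNG is a counter-seeded
  xorshift128+, so a seed gives a bit-identical field on any platform and
  never touches R's RNG state.

The benchmark configuration (µa = 0.02, µs′ = 16.62 cm⁻¹, g = 0, albedo
0.999) uses isotropic scattering at the reduced coefficient — the similarity
relation under which diffusion is parameterized — on a 51³ grid of 1 mm
voxels with ~1.5 cm of margin beyond the outermost compared radius, keeping
the absorbing-boundary bias at r = 1 cm near 1%. The default phantom voxel
(0.1 cm here, 0.02 cm in `phantom()` examples mirroring resampled MRI) and
packet budgets trade runtime against shot noise; the standard error scales
as $1/\sqrt{\text{packets}}$ (tested across four budgets). Refractive-index
boundaries are matched (no Fresnel reflection); the clinical 0.85 mm
cylindrical diffuser is idealized as a point, which overestimates fluence
within roughly one diffuser length of the source — both are acceptable for
radial-dose questions at millimetre scales and are the stated scope.

**Optics table.** The per-tissue optical properties of the source study live
in its supplement and are not available; `default_tissue_optics()` therefore
ships literature-typical placeholders chosen to be *consistent with the
published penetration distances* (gray matter at 808 nm: 1/µ_eff = 1.0 cm;
white 808: 0.54 cm; gray 635: 0.83 cm; white 635: 0.36 cm). They are labelled
placeholders in the documentation and should be replaced by measured values
for any real analysis.

## Photodynamic threshold at the necrosis boundary

Tissue necroses where the absorbed photon density exceeds a threshold
$T$. Given an observed boundary radius (from post-treatment T2 enhancement),
the forward model evaluated at that radius *is* the threshold estimate;
`threshold_at_boundary()` does this per animal and aggregates as unweighted
mean ± sample sd (the source report gives mean ± value without stating
weights; unweighted is the neutral reading). When the entire tumor necroses
the boundary only bounds the threshold from above, so the maximum
enhancement distance — the "upper boundary" reading — is the default, with
minimum distances retained in the observation type.

`predict_necrosis_radius()` inverts the monotone profile by bracketed root
finding. The tolerance is 10⁻¹⁰ cm — far below the 1 µm measurement scale —
so the forward/inverse round trip closes to 10⁻⁹ relative and the inverse is
exact on its range (property-tested). A threshold above the near-source
density returns radius 0: "no necrosis" is a result, not an error.

Tissue drug concentrations convert from µg/g to molar assuming density
1 g/mL (documented constant; the study is silent). The synthetic threshold
scenario uses the published tumor threshold 8.86×10¹⁸ hv·cm⁻³ as generating
truth and a placeholder tissue concentration of 3.9×10⁻⁸ M chosen so the
forward boundary sits near 5 mm — the anatomical scale of a 3 mm tumor plus
margin. The published in vivo thresholds themselves are **not**
reproducible here (they require the supplementary concentrations and
optics); what the tests assert instead is the round trip, cohort recovery
(6 animals, 5% radius jitter, cohort mean within one sd of truth in ≥90% of
seeds) and the qualitative ordering that lower normal-brain uptake implies a
lower normal-brain threshold.

**Selectivity.** The rule of thumb that every factor of 3 in SUR buys one
effective penetration depth follows from matching the fluence decay
$e^{-r/\delta}$ against the uptake ratio: depths $= \log_3(\mathrm{SUR})$,
distance $=$ depths $/\mu_{eff}$. SUR 20 gives 2.73 depths; SUR 10.6 gives
2.15 — the published roundings are "close to 2.8" and "just over 2".

## Biodistribution

ICP-MS reports ruthenium ppb (µg/L) in a 2 mL acid digest; mass of drug is
ppb × volume × MW(TLD1433)/AM(Ru) with MW = 1007 g/mol and the standard
atomic weight 101.07. The readout quantifies the ¹⁰¹Ru isotope, so an
isotope-specific mass (100.906) is available as a switch — a 0.16% effect.
SUR is the ratio of group mean concentrations; it cancels molecular weight
and density, hence is identical in µg/g and molar units (tested to 10⁻¹²)
and invariant to rescaling every ppb. Degenerate groups follow the data
rather than crashing: an all-zero reference group is the biologically real
"complete absence of uptake" case and returns an `absent` sentinel; n = 1
groups are flagged `low_n`. Ratio uncertainty is a first-order delta-method
SE, with the per-animal spread preserved in the output tables.

## Survival

`km_estimate()` and `logrank_test()` are written from the defining formulas
(product limit with Greenwood variance; observed-minus-expected with
hypergeometric variance and a χ²₁ reference), with the survival package used
only as an independent oracle in the tests. Conventions:

* deaths precede censorings at tied times (standard risk-set convention);
* the median is the first time with $S(t) \le 0.5$, with a 10⁻⁹ relative
  tolerance so a product of risk-set fractions that lands on 0.5 up to
  floating-point rounding counts as reached — this is how half-integer
  medians arise with even n and no censoring;
* a comparison with zero hypergeometric variance is degenerate: identically
  null data returns statistic 0, p = 1, anything else an undefined sentinel;
* multiple comparisons are reported unadjusted by default (matching the
  source study's reporting), with Holm available.

## What the synthetic generators emulate — and what they don't

Each generator is a pure function of (config, seed) and regenerates
bit-identically; written scenarios carry a manifest with the seed and a
config hash.

* **Plates** (`gen_plate`): true 4PL kill curves over the assay ranges
  (Rutherrin 0–500 nM, ALA 0–6000 µM), true LD50s defined by inverting the
  published photon-unit LD50s, Hill slope 1.5, 6 replicates, Gaussian
  viability noise (sd 0.05) clipped at zero, solvent and 4%-methanol-style
  kill controls at levels 1.0 and 0.02. Not emulated: edge effects,
  photobleaching during exposure, drug toxicity without light.
* **Uptake** (`gen_uptake`): lognormal per-tissue concentrations (15% CV)
  with tumor medians set to SUR × reference; SUR 20 at 4 h and 24 h, 12 at
  48 h (the study reports ≈20 early and >10 at 48 h); doses 5 and
  10 mg/kg; 3 animals per cell; optional zeroed reference draws to exercise
  the absence sentinel. Equal log-sd across tissues makes the ratio of means
  equal the ratio of medians, so the configured SUR is the estimand. Not
  emulated: clearance kinetics within a timepoint, inter-animal correlation
  across tissues.
* **Boundaries** (`gen_boundaries`): forward model radius for the generating
  threshold, multiplicative Gaussian radius jitter (5%), n = 6.
* **Survival** (`gen_survival`): Weibull event times with per-arm medians
  4.5 / 8.5 / 12.5 days and common shape 3 (CV ≈ 0.36), n = 8 per arm, no
  censoring by default. **Why Weibull, not exponential:** with all 16 events
  observed, the log-rank z for a median ratio of 12.5/4.5 under exponential
  arms is about $\log(2.78)\sqrt{16/4} \approx 2.0$, i.e. power ≈ 0.5 — an
  exponential cohort of this size simply cannot reproduce the decisive
  separation the source comparison shows, and tumor-driven deaths in a
  syngeneic model cluster far more tightly than an exponential's CV of 1.
  Shape 3 matches both the observed separability and biological
  plausibility; `shape = 1` recovers the exponential family when wanted.

Passing tests on these generators show the *estimators* are correct and
well-calibrated under the stated noise families; they do not validate the
noise families against real assay, ICP-MS or survival data.

## Simulation sizes and numerical settings

The test suite and acceptance script use: 200 seeds for LD50 recovery
(median relative error < 10%), 200 seeds for threshold-cohort coverage,
500 seeds for SUR recovery, 2000 null simulations for log-rank calibration
and 500 for power, and 10⁶ packets for the Monte Carlo–diffusion comparison.
The null calibration uses 20 subjects per arm: the χ²₁ reference is
asymptotic, and at n = 8 the log-rank test is known to be mildly
anti-conservative (~0.07), so calibration is assessed at a size where the
approximation is meant to hold while power is assessed at the study's own
n = 8. These sizes are the package's choices balancing Monte Carlo error
against runtime.

## Known limitations

* Optics defaults are placeholders (see above); any absolute in vivo
  threshold or selectivity distance inherits their uncertainty.
* The point-source idealization and matched boundaries bias fluence within
  ~1 diffuser length of the source and near tissue interfaces.
* LD50s in photon units assume complete precursor conversion and no
  photobleaching; the stoichiometric correction is an upper bound on active
  photosensitizer.
* SUR inference treats group means as the estimand; with n = 3 and lognormal
  spread the delta-method CI is approximate (the recovery tests quantify
  this).
* No Cox regression, covariates, or competing risks; no MRI segmentation —
  boundary distances are inputs.
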