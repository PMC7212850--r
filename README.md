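# pdtdose

Absorbed-photon dosimetry for photodynamic therapy (PDT).

## The problem

Comparing two photosensitizers — here Rutherrin (the ruthenium complex
TLD1433 formulated with apo-transferrin, activated at 530/808 nm) against
ALA-induced protoporphyrin IX (635 nm) in a rat RG-2 glioma model — is
meaningless in J·cm⁻² or in drug concentration alone: the agents absorb at
different wavelengths, with different extinction coefficients, and
accumulate differently in tissue. The common currency is the **absorbed
photon density**, the number of photons absorbed by the photosensitizer per
cm³ of tissue:

```
N_abs [hv·cm⁻³] = ( H / (h·c/λ) ) · ln(10) · ε(λ) · C
```

where `H` is the radiant exposure (J·cm⁻²), `h·c/λ` the photon energy,
`ε` the decadic molar extinction coefficient (M⁻¹·cm⁻¹) and `C` the local
molar photosensitizer concentration. Everything in this package feeds that
quantity:

* **photonic conversions** — exposure ↔ photon density, exposure times,
  Beer–Lambert absorption (`ln(10)` convention switchable);
* **dose–response** — 4-parameter logistic fits of plate kill data with the
  LD50 expressed both in concentration and in hv·cm⁻³, including
  precursor stoichiometry (8 ALA per PpIX);
* **light transport** — the diffusion closed form
  `φ(r) = P·exp(−µ_eff·r)/(4πDr)` around an interstitial isotropic emitter
  and a seeded voxel Monte Carlo simulator (Henyey–Greenstein scattering,
  Russian roulette, full energy accounting), plus dose–volume histograms;
* **threshold model** — the photodynamic threshold implied by an observed
  necrosis boundary radius, its inverse (predicted treatable radius), and
  the log₃ rule converting a specific uptake ratio into effective
  penetration depths of selectivity;
* **biodistribution** — ICP-MS ruthenium ppb → TLD1433 tissue
  concentrations → specific uptake ratios (SUR), with the degenerate
  "no uptake in reference tissue" case handled explicitly;
* **survival** — Kaplan–Meier and the Mantel–Cox log-rank test implemented
  from first principles;
* **synthetic data** — seeded generators for every input table, so the whole
  chain runs end to end without animal data.

## Worked example

```r
library(pdtdose)
ps  <- default_photosensitizers()
src <- default_light_sources()

# photon bookkeeping of the 530 nm well-irradiator schedule
cat(sprintf("photons at 20 J/cm2, 530 nm: %.4g hv/cm2\n",
            radiant_exposure_to_photon_density(20, 530)))

# fit a synthetic Rutherrin plate and express LD50 in absorbed photons
sc  <- scenario_config(seed = 1)
fit <- fit_dose_response(gen_plate(sc, "rutherrin"),
                         ps = ps$rutherrin, source = src$well_530)
print(fit)

# selectivity a SUR of 20 buys in gray matter at 808 nm
sel <- selectivity_depths(20, default_tissue_optics()$gray_808)
cat(sprintf("SUR 20: %.2f penetration depths = %.1f mm\n",
            sel$depths, sel$distance_cm * 10))
```

prints

```
photons at 20 J/cm2, 530 nm: 5.336e+19 hv/cm2
Four-parameter logistic dose-response fit
  LD50: 2.003e-08 M (sd 1.4e-09 M)
  Hill slope: 1.42   asymptotes: -3.42 / 97.3 % kill
  LD50 in absorbed photons: 2.074e+16 hv cm^-3 (sd 1.5e+15)
SUR 20: 2.73 penetration depths = 27.3 mm
```

Reading: 20 J·cm⁻² of 530 nm light is 5.34×10¹⁹ photons per cm²; a noisy
synthetic plate (6 replicates, 5% viability noise) fits to an LD50 of
~20 nM which, under that light schedule, corresponds to ~2×10¹⁶ absorbed
photons per cm³ — three orders of magnitude below the ALA/PpIX requirement,
which is the headline comparison. A tumor-to-brain uptake ratio of 20 buys
2.73 effective penetration depths (27 mm at 808 nm in gray matter) of
treatment selectivity.

`run_comparison(scenario_config(seed = 1))` runs the whole chain — both
plate fits, SUR tables, threshold estimate, selectivity, Kaplan–Meier
medians and pairwise log-rank — and prints one consolidated report;
`write_report()` saves it as CSVs plus a text summary.

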