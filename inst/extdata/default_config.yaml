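# Photosensitizer, light-source and tissue-optics definitions for the
# Rutherrin vs ALA-induced PpIX rat glioma comparison. Units are declared in
# the field names. Tissue optical properties are literature-typical
# PLACEHOLDERS chosen to be consistent with the published effective
# penetration distances, not measured values.
photosensitizers:
  - name: rutherrin
    epsilon_M_cm: 8427.4
    wavelength_nm: 530
    molecular_weight_g_mol: 1007
    precursor_ratio: 1
  - name: ala_ppix
    epsilon_M_cm: 5121
    wavelength_nm: 635
    molecular_weight_g_mol: 562.66
    precursor_ratio: 8
light_sources:
  - name: well_530
    geometry: flat_field
    wavelength_nm: 530
    irradiance_W_cm2: 0.360
    duration_s: 55.555555555555557
  - name: well_635
    geometry: flat_field
    wavelength_nm: 635
    irradiance_W_cm2: 0.075
    duration_s: 133.33333333333334
  - name: interstitial_808
    geometry: isotropic_point
    wavelength_nm: 808
    power_W: 0.2
    duration_s: 3000
  - name: interstitial_635
    geometry: isotropic_point
    wavelength_nm: 635
    power_W: 0.018
    duration_s: 1333
tissue_optics:
  - label: tumor_808
    mu_a_cm: 0.03
    mu_s_prime_cm: 15.0
    g: 0.9
  - label: gray_808
    mu_a_cm: 0.02
    mu_s_prime_cm: 16.62
    g: 0.9
  - label: white_808
    mu_a_cm: 0.07
    mu_s_prime_cm: 16.6
    g: 0.9
  - label: gray_635
    mu_a_cm: 0.024
    mu_s_prime_cm: 20.0
    g: 0.9
  - label: white_635
    mu_a_cm: 0.064
    mu_s_prime_cm: 40.0
    g: 0.9
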