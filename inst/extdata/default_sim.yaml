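# Default synthetic-vineyard configuration.
#
# Trait means/total SDs and hierarchical variance proportions are seeded from
# published descriptive statistics for 178 field-grown grapevine leaves across
# 12 cultivars (7 varieties).  For traits summarized there by median and CV,
# mean is seeded with the median and total_sd with CV * median / 100.
# Proportions omitted below (including the residual) default to zero, with the
# residual taking the shortfall from 1; printed proportions below 0.001 are
# treated as 0.
#
# Units: E mmol H2O m-2 s-1; Amax umol CO2 m-2 s-1; gs mol m-2 s-1;
# N, C % dry mass; d13C permil; Psi_pd MPa; WUE_intr umol CO2 mol-1 H2O;
# WUE_inst umol CO2 mmol-1 H2O; Area cm2; LDMC mg g-1; LMA g m-2.

traits:
  E:
    mean: 3.24
    total_sd: 1.13
    proportions: {origin: 0.42, cultivar: 0.38, row: 0.08}
  Amax:
    mean: 21.83
    total_sd: 3.35
    proportions: {origin: 0.27, row: 0.19}
  gs:
    mean: 0.26
    total_sd: 0.08
    proportions: {cultivar: 0.54, row: 0.15}
  "N":   # quoted: bare N is a YAML 1.1 boolean
    mean: 2.75
    total_sd: 0.35
    proportions: {red_white: 0.12, row: 0.05}
  C:
    mean: 45.81
    total_sd: 0.78
    proportions: {origin: 0.08, cultivar: 0.32}
  d13C:
    mean: -27.88
    total_sd: 1.22
    proportions: {row: 0.08}
  Psi_pd:
    mean: -5.88
    total_sd: 1.47
    proportions: {red_white: 0.18, cultivar: 0.21, row: 0.07}
  WUE_intr:
    mean: 85.51
    total_sd: 25.07
    proportions: {cultivar: 0.52, row: 0.15}
  WUE_inst:
    mean: 6.70
    total_sd: 2.28
    proportions: {origin: 0.59, cultivar: 0.29, row: 0.04}
  Area:
    mean: 150.74
    total_sd: 34.30
    proportions: {origin: 0.15, cultivar: 0.09}
  LDMC:
    mean: 255.69
    total_sd: 21.98
    proportions: {red_white: 0.09, cultivar: 0.05}
  LMA:
    mean: 70.51
    total_sd: 6.75
    proportions: {cultivar: 0.04}

# Forward-model absorption features: Gaussian optical-depth bumps whose depth
# is strength * z(trait).  Placement follows where each trait plausibly
# expresses optically (red edge for photosynthesis/chlorophyll-linked traits,
# 1450/1940 nm water bands for water status, SWIR for dry matter).  d13C has
# no link on purpose: an isotopic signature has no direct optical expression,
# so the retrieval protocol should fail honestly on it.
links:
  - {trait_id: E,        center_wavelength: 1940, width: 70, strength: 0.060}
  - {trait_id: Amax,     center_wavelength: 690,  width: 25, strength: 0.050}
  - {trait_id: gs,       center_wavelength: 1450, width: 60, strength: 0.050}
  - {trait_id: "N",      center_wavelength: 710,  width: 35, strength: 0.060}
  - {trait_id: C,        center_wavelength: 2100, width: 60, strength: 0.040}
  - {trait_id: Psi_pd,   center_wavelength: 1450, width: 90, strength: 0.035}
  - {trait_id: WUE_intr, center_wavelength: 1660, width: 60, strength: 0.025}
  - {trait_id: WUE_inst, center_wavelength: 720,  width: 30, strength: 0.035}
  - {trait_id: Area,     center_wavelength: 550,  width: 45, strength: 0.035}
  - {trait_id: LDMC,     center_wavelength: 2300, width: 80, strength: 0.050}
  - {trait_id: LMA,      center_wavelength: 1720, width: 60, strength: 0.045}
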