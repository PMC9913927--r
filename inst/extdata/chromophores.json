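{
  "note": "Synthetic parametric reconstructions of the standard compiled chromophore spectra (not measured data); bands anchored to published peak wavelengths 542/576 (oxy), 556/756 (deoxy), 975 nm (water); melanosome: 20*(lambda/500)^-3.48 mm^-1.",
  "hemoglobin_conversion": {
    "total_hemoglobin_g_per_L": 150,
    "molar_mass_g_per_mol": 64500,
    "formula": "mua_mm-1 = ln(10) * molar_extinction * (C_gL/M_gmol) / 10"
  },
  "units": {
    "hemoglobin": "cm^-1 M^-1 (molar extinction)",
    "water": "mm^-1",
    "melanosome": "mm^-1"
  },
  "wavelength_range_nm": [450, 1040],
  "step_nm": 1
}
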