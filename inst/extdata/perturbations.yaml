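# Parametric transfer-function catalog for the cataloged instrumental
# perturbations.  Loss perturbations use the core-area ratio of the
# inserted fiber; curving uses a flat near-unity transmittance; sticker
# curves are qualitative smooth band-passes (visible transmission band set
# by the color plus partial NIR recovery), an approximation of measured
# sticker transfer curves.
loss:
  inserted_core_um: 105
curve:
  transmittance: 0.98
sticker:
  floor: 0.25
  band_amplitude: 0.55
  nir_amplitude: 0.55
  nir_center_nm: 760
  nir_width_nm: 50
  colors:
    B: {center_nm: 470, width_nm: 60}
    G: {center_nm: 530, width_nm: 55}
    P: {center_nm: 650, width_nm: 120}
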