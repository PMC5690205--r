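# Example simulation scenario: sinusoidal surrogate motion of +/-10 mm with
# a 6 s cycle, evaluated at a slice 200 mm from the central piece.
waveform:
  kind: sine
  amplitude_mm: 10
  period_s: 6
  tc_s: 0
  baseline_mm: 0
geometry:
  z0_mm: 580
  zp_mm: 180
  bar_length_mm: 470
acquisition:
  n_slabs: 1
  slices_per_slab: 1
  noise_sd_hu: 20
  seed: 1
slice_zs: [380]
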