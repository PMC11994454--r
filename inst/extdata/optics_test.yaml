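# reduced test-scale instrument: 5 x 5 views, geometry chosen so the fine
# grid resolves the diffraction limit; used by the test suite
na: 1.4
mag_objective: 63
mag_relay: 1.0
wavelength_nm: 525
refr_index: 1.515
mla_pitch_um: 16.25
mla_focal_um: 365
pixel_size_um: 6.5
n_views: 5
scan:
  s: 3
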