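# inverted system: 63x/1.4 oil objective, 100-um MLA imaged onto the camera
# at 0.845 so one lens covers exactly 13 x 13 pixels of 6.5 um
na: 1.4
mag_objective: 63
mag_relay: 1.0
wavelength_nm: 525
refr_index: 1.515
mla_pitch_um: 100
mla_focal_um: 2100
pixel_size_um: 6.5
n_views: 13
scan:
  s: 3
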