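# upright system: 25x/1.05 water objective with 1.64 relay (M = 41),
# 136.5-um MLA at 1:1 onto 6.5-um pixels -> 21 x 21 views
na: 1.05
mag_objective: 25
mag_relay: 1.64
wavelength_nm: 525
refr_index: 1.33
mla_pitch_um: 136.5
mla_focal_um: 2800
pixel_size_um: 6.5
n_views: 21
scan:
  s: 3
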