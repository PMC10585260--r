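# Blackberry RDR settings, 2021-style campaign: color-checker ruler edge
# (50 mm shown here) as size reference; measure reference_px on one
# sample image of the batch.
max_dim: 1500
normalize: yes
sharpen_amount: 1.0
denoise_radius: 1.0
lab_scale: cielab
background:
- space: lab
  channel: a
  min: -8.5
features:
  RDR:
  - space: lab
    channel: a
    min: 8.58
despeckle_radius: 2.0
feature_despeckle_radius: 1.0
min_object_area: 50.0
calibration:
  reference_length_mm: 50.0
  reference_px: 320.0
traits:
- length
- width
- area
- feature_pct
- color_profile
length_mode: bbox
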