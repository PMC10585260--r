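# Blackberry RDR settings, 2019-style campaign: US quarter (24.26 mm
# diameter) as size reference. reference_px must be measured on one
# sample image of the batch; the value below matches a quarter spanning
# 180 px in the original image.
max_dim: 1500
normalize: yes
sharpen_amount: 1.0
denoise_radius: 1.0
lab_scale: cielab
background:
- space: lab
  channel: a
  min: -10.0
features:
  RDR:
  - space: lab
    channel: a
    min: 7.51
despeckle_radius: 2.0
feature_despeckle_radius: 1.0
min_object_area: 50.0
calibration:
  reference_length_mm: 24.26
  reference_px: 180.0
traits:
- length
- width
- area
- feature_pct
- color_profile
length_mode: bbox
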