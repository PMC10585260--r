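# fruitpix

Batch image-based fruit phenotyping by color thresholding.

`fruitpix` measures fruit size and color-defined surface features from
staged photographs — the motivating application is **red drupelet
reversion (RDR)** in blackberry, a postharvest disorder in which black
drupelets turn red after handling and cold storage. Breeding programs
score RDR and fruit size on hundreds of samples per season; `fruitpix`
turns a directory of photographs (fruit on a uniform contrasting
background, with a size reference of known length in frame) into a tidy
CSV of calibrated per-fruit and per-image trait values, plus a settings
sidecar that makes every run exactly reproducible.

## The method

Each photograph passes through a fixed pipeline:

1. **Preprocess** — downsize so the maximum dimension is at most 1500 px,
   stretch pixel values to span the full RGB range (joint across
   channels, so hue is preserved), median-denoise and unsharp-sharpen.
2. **Segment fruit** — classify pixels by *conjunctive per-channel
   intervals* in RGB, HSB and CIELAB. A pixel is fruit iff it satisfies
   every configured interval; unset channels are full range (FR). On a
   green board, a single CIELAB cutoff such as `a* > −10` suffices,
   because the green–red opponent axis a\* cleanly separates board
   (a\* ≈ −33) from fruit (a\* > 0). Small debris (dust, juice specks) is
   removed by **despeckling**: morphological opening — erosion then
   dilation with a disc of radius *r* — deletes any pixel group that
   cannot survive the erosion.
3. **Detect features** — the same machinery with a second threshold set
   (e.g. `a* > 16` for reverted-red pixels), intersected with the fruit
   mask. The feature quantity is a pixel fraction,

   RDR% = 100 · |feature pixels| / |fruit pixels|,

   reported per image and per fruit.
4. **Label and measure** — individual fruit are 8-connected components
   (area-filtered). Length is the vertical pixel extent of a fruit
   (uppermost to lowest detected pixel — so staging orientation
   matters), width the horizontal extent; a size reference of known
   physical length calibrates mm/px. Optionally, feature regions get a
   **color profile**: the nearest named chart colors for their minimum,
   median and maximum colors (Euclidean distance in CIELAB against a
   bundled, synthetic approximation of the RHS chart).

All colorimetry is sRGB → linear → XYZ → CIELAB under D65/2°, computed in
floating point; a compatibility mapping to ImageJ's 0–255 Lab scale lets
you port thresholds chosen there (`lab_scale: imagej`).

Because validation against real photographs requires the original image
sets, the package ships a **synthetic scene generator** with exact
pixel-level ground truth: green board, berries as ellipses carrying
hex-packed reverted drupelet discs at a requested pixel fraction, debris
specks, and a reference bar of known mm length. Every guarantee the
package makes is tested against these scenes.

## Worked example

```r
library(fruitpix)

# a synthetic scene: 3 berries, 15% reverted pixels, anti-aliased,
# with a 50 mm reference bar spanning 120 px
spec <- scene_spec(reverted_fraction = 0.15, n_specks = 4,
                   anti_alias = TRUE, seed = 11)
sc  <- render_scene(spec)
cfg <- scene_analysis_config(spec)   # thresholds calibrated to the palette
res <- process_image(sc$image, cfg, image_id = "demo")
res[, c("image_id", "object_label", "n_pixels", "length_mm",
        "width_mm", "RDR_pct", "color_median_name", "status")]
```

```
  image_id object_label n_pixels length_mm width_mm RDR_pct color_median_name status
1     demo            1     5196     41.67     27.5   14.76          Red 53-A     ok
2     demo            2     5008     40.00     27.5   15.38          Red 53-A     ok
3     demo            3     5628     39.17     32.5   15.28          Red 53-A     ok
4     demo           NA    15832        NA       NA   15.14          Red 53-A     ok
```

Rows 1–3 are the three detected fruit: pixel counts, calibrated sizes
(e.g. 41.67 mm long from a 100-row extent at 50 mm/120 px), per-fruit
reverted fractions, and the chart name nearest to the median feature
color. The last row is the per-image summary: 15 832 fruit pixels of
which 15.14% are reverted — against a generated truth of 15.06%.

For real photographs, write a YAML config (see
`inst/extdata/configs/blackberry_rdr_2019.yaml` for a complete campaign
configuration) and run the batch from R:

```r
cfg <- load_config("blackberry_rdr_2019.yaml")
process_batch("photos/", cfg, "results.csv")   # + settings.json sidecar
```

or from the shell via the bundled CLI (`inst/cli/fruitpix`):

```sh
fruitpix analyze  --config cfg.yaml --input photos/ --output results.csv
fruitpix preview  --config cfg.yaml --image sample.jpg --out-dir preview/
fruitpix simulate --n-scenes 20 --f 0.15 --seed 7 --out scenes/
```

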