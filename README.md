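# gliaband

Quantifying the foreign-body response around chronically implanted neural
microelectrodes from stained histological sections.

When a probe is explanted after weeks in cortex, the section shows a track
void surrounded by a glial scar (GFAP-positive reactive astrocytes) and a
halo of neuronal loss (NeuN-stained nuclei). `gliaband` turns a manually
outlined track polygon — each edge labelled with the implant surface that
faced it (`nanoSi`, `flatSi`, `microSi`, `micro-polymer`) — into a
reproducible, banded quantification of both effects, and compares the four
surface types statistically at every distance.

## The method

1. **Banding.** The track outline is rasterized; a Euclidean distance
   transform assigns every tissue pixel its distance to the track. Pixels
   are binned into half-open 50 µm bands `[k·50, (k+1)·50)` out to 500 µm
   and labelled with the nearest polygon edge's surface. An optional
   cortical-layer mask restricts analysis to one layer.
2. **Profiles.** Per (band, face): mean stain intensity (GFAP) and neuron
   density in neurons/mm² from nucleus annotations (NeuN), each normalized
   to the face's own 400–500 µm background zone, treated as unaffected
   tissue. Manual nucleus counts are the primary input; a scale-space
   blob detector (`detect_nuclei`) is available for clean material.
3. **Statistics.** At each band, a tie-corrected Kruskal–Wallis test over
   the four surface groups; where significant (α = 0.05), Dunn's post-hoc
   test with Bonferroni adjustment over the 6 pairs,
   `p_adj = min(1, 6·p_raw)`. Testing is per distance band, with no
   across-band correction by default.
4. **Surface morphology.** Area-ratio roughness of AFM height maps
   (triangulated 3-D area / projected area), pillar density per µm² by
   spot counting, and tilt-corrected pillar heights from annotated SEM
   cross-sections.

A synthetic-section generator with analytic ground truth
(`generate_section`, `generate_height_map`) validates the whole chain: a
GFAP field `background·(1 + A_f·e^{−d/τ})`, an inhomogeneous-Poisson
nucleus process `baseline·(1 − B_f·g(d))`, and height maps with known area
ratios.

## Worked example

```r
library(gliaband)

# one synthetic section per seed; defaults mirror the study conditions
# (180 x 380 um track, 50 um bands to 500 um)
secs <- lapply(1:6, function(s)
  generate_section(image_spec = list(pixel_size_um = 4, margin_um = 520),
                   seed = s))
res <- run_pipeline(secs, run_config())
res$comparisons$intensity
```

```
<gb_band_comparison> kind=intensity, alpha=0.05
 band band_lo_um band_hi_um         H         p_kw
    0          0         50 21.600000 7.900462e-05
    1         50        100 20.686667 1.222871e-04
    2        100        150 16.126667 1.068151e-03
    3        150        200 14.540000 2.255095e-03
    4        200        250 14.606667 2.185584e-03
    5        250        300 13.286667 4.055955e-03
    6        300        350 13.660000 3.406453e-03
    7        350        400 11.726667 8.380618e-03
    8        400        450  5.646667 1.301248e-01
    9        450        500  5.686667 1.278905e-01
significant post-hoc pairs: 17
```

The generator's default gives the nanostructured face a ~15 % weaker scar
amplitude, so the per-band Kruskal–Wallis is significant wherever the
scar is measurable and fades by the outermost bands; the post-hoc pairs
identify nanoSi against the other three surfaces. With all amplitudes
equal the same pipeline reports no significant bands (see the tests).

`res$profiles` holds the per-section (band, face) table — raw mean
intensity, pixel counts, areas in mm², nucleus counts, and normalized
values; `res$aggregates` the pooled per-(band, group) samples and
mean/SD/n summaries.

## Command line

A thin CLI wraps the exported functions:

```sh
Rscript inst/cli/gliaband.R simulate --config cfg.yaml --seed 1 --out data/
Rscript inst/cli/gliaband.R run --manifest manifest.yaml --out results/
Rscript inst/cli/gliaband.R surface roughness --in heights.txt --step-nm 20
```
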