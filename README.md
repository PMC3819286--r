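# nucleodemark

Demarcation and quantification of **nucleoli** in multi-channel
fluorescence microscopy images — for cell biologists who need per-nucleolus
intensity measurements (marker proteins, nascent-RNA labels such as EU)
that keep working when stress or drugs reorganize the nucleolus.

## What it does

Nucleoli can be demarcated from a **positive marker** concentrated in them
(e.g. nucleolin: nucleoli are brighter than the nucleoplasm) or from a
**negative marker** excluded from them (e.g. CAS or HuR: nucleoli are dark
holes). Both cases reduce to grayscale top-hat transforms with a disk/ball
structuring element *B*:

* light holes: `I − (I ∘ B)` (white top-hat, source minus opening)
* dark holes: `(I • B) − I` (black top-hat, closing minus source)

The response is median-filtered, and within each DAPI-segmented nucleus the
candidates are accepted by **size constraints and intensity above local
background**, yielding labelled nucleolar segments (2D or 3D z-stacks).
When two negative markers each miss some nucleoli (as after DRB), their
images are **pixel-wise added** before dark-hole detection, which rescues
the missed nucleoli. Channel intensities are then measured on the original
images over each segment, quality-controlled automatically, normalized per
replicate to the control, and compared with replicate-level Welch t-tests
(`*` p < 0.05, `**` p < 0.01).

A bundled synthetic scene generator plants nuclei, nucleoli, per-channel
intensities and per-pixel ground truth, and emulates five experimental
phenotypes (control, heat shock, DEM oxidant, actinomycin D, DRB), so the
whole pipeline is validated end to end without real data.

## Worked example

```r
library(nucleodemark)

spec  <- scene_spec(condition = "control", noise_sigma = 100, seed = 1)
sc    <- render_scene(spec)
holes <- detect_light_holes(sc$channels$nucleolin, structuring_radius = 2)
segs  <- score_nucleoli(median_denoise(holes, 1),
                        segment_nuclei(sc$channels$DAPI))
segs
#> <segment_labels> 9 segments in 4 nuclei (unknown mode)
evaluate_segmentation(segs, sc$truth)
#> <segmentation_metrics> recall 1.000, precision 1.000, mean IoU 0.985 (9 true / 9 predicted)
```

All nine planted nucleoli are recovered, each with near-perfect overlap.
A full experiment — control vs. DRB, three replicates, demarcation from the
added CAS+HuR image, measurement of nucleolin and EU:

```r
cfg <- pipeline_config(conditions = c("control", "DRB"), marker_mode = "add",
                       scene = scene_spec(noise_sigma = 100, seed = 1),
                       base_seed = 7)
res <- run_pipeline(cfg)
res$comparison[res$comparison$channel %in% c("nucleolin", "EU"),
               c("condition", "channel", "normalized_mean", "sem", "p",
                 "annotation")]
#> # A tibble: 4 × 6
#>   condition channel   normalized_mean      sem            p annotation
#>   <chr>     <chr>               <dbl>    <dbl>        <dbl> <chr>
#> 1 control   nucleolin           1     4.53e-17 NA           ""
#> 2 DRB       nucleolin           0.400 5.38e- 4  0.000000804 "**"
#> 3 control   EU                  1     0        NA           ""
#> 4 DRB       EU                  0.600 4.63e- 4  0.00000134  "**"
```

The DRB phenotype planted by the generator — nucleolin redistributed out of
nucleoli (nucleolar level drops to the nucleoplasm level, 0.4× the control
nucleolar signal) and nucleolar RNA synthesis reduced to 0.6 — is recovered
exactly, with the expected significance stars. `plot_comparison(res$comparison)`
draws the usual mean + SEM bar chart with stars.

A command-line interface wrapping the same functions is installed at
`inst/cli/nucleodemark` (subcommands `simulate`, `holes`, `combine`,
`segment`, `measure`, `compare`, `run`, `evaluate`).

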