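---
title: "Demarcating and quantifying nucleoli with positive and negative markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demarcating and quantifying nucleoli with positive and negative markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleodemark)
```

## The problem

The nucleolus is the nuclear subcompartment where ribosomes are made, and it
reorganizes dramatically under stress and chemotherapeutic treatment: heat
shock relocates resident proteins, oxidants shift protein composition, and
transcription inhibitors such as actinomycin D and DRB fragment the
compartment outright. Quantitative immunofluorescence of nucleolar proteins
or of nascent RNA (EU incorporation) therefore needs a way to *demarcate*
nucleoli reliably across all of these conditions before anything can be
measured in them.

Two marker strategies exist:

* **positive markers** — proteins concentrated in nucleoli (e.g. nucleolin):
  nucleoli are brighter than the surrounding nucleoplasm ("light holes");
* **negative markers** — nucleoplasmic proteins excluded from nucleoli
  (e.g. CAS, HuR): nucleoli appear as "dark holes".

Neither is universal. Heat shock drives CAS and HuR *into* nucleoli,
destroying the dark holes while nucleolin still works; DRB redistributes
nucleolin throughout the nucleoplasm while CAS and HuR still work, though
each misses some nucleoli; actinomycin D relocates nucleolin so thoroughly
that it becomes a *negative* marker (dark holes). When two negative markers
each miss a different subset of nucleoli, summing their images deepens every
hole relative to noise, and the combined image recovers nucleoli each single
marker missed.

This package implements that whole demarcation-and-quantification chain as
testable primitives, together with a synthetic scene generator that plants
ground truth, so every claim above is a reproducible property rather than a
visual impression.

## The demarcation chain

For a marker image $I$ and a structuring element $B$ (disk in 2D, ball in
3D, radius in µm):

1. **Hole detection.** Light holes are the white top-hat
   $I - (I \circ B)$ (source minus its grayscale opening); dark holes are
   the black top-hat $(I \bullet B) - I$ (closing minus source). Blobs
   smaller than $B$ deviating from local background yield a positive
   response; flat regions yield zero; adding a constant to $I$ changes
   nothing. The two are duals: dark holes of $I$ equal light holes of the
   inverted image. The contracts are stated as formulas and checked against
   a brute-force per-pixel oracle, so the implementation (compiled
   neighborhood kernels with symmetric-reflection borders) is replaceable
   without changing behavior.
2. **Median denoising.** A per-pixel median over a $(2r+1)^d$ neighborhood
   (default $r = 1$, i.e. 3×3) suppresses isolated response spikes.
3. **Nucleus segmentation.** The DAPI-like channel is thresholded (Otsu, or
   a fixed user threshold in the ImageJ-style mode), holes are filled,
   small objects removed, components labelled; border-touching nuclei are
   flagged.
4. **Segment scoring.** Within each nucleus the median-filtered response is
   thresholded (Otsu restricted to intranuclear pixels), and each connected
   candidate is accepted iff its size lies in `[min_size, max_size]`
   (defaults 0.5–80 µm², typical HeLa nucleolar sizes) *and* its mean
   response exceeds that of a surrounding 1 µm intranuclear annulus
   (other candidates excluded) by at least
   `min_intensity_above_background`.
5. **Measurement.** Channel intensities (markers, EU, …) are measured on
   the *original* images over exactly the accepted segment pixels — never
   on filter responses.
6. **QC, normalization, statistics.** Automated QC replaces visual
   inspection (border nuclei, size bounds, contrast floor, per-nucleus
   count cap). Nucleolar means are normalized per replicate and channel to
   the control's mean-of-nucleolar-means; conditions are compared by a
   two-sided Welch t-test on replicate means with `*` (p < 0.05) and `**`
   (p < 0.01) annotation.

```{r example, eval = FALSE}
spec <- scene_spec(condition = "control", noise_sigma = 100, seed = 1)
sc   <- render_scene(spec)
holes <- detect_light_holes(sc$channels$nucleolin, structuring_radius = 2)
segs  <- score_nucleoli(median_denoise(holes, 1),
                        segment_nuclei(sc$channels$DAPI))
evaluate_segmentation(segs, sc$truth)
```

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| structuring radius | 1.25 × max nucleolus radius (2 µm) | µm | must cover the largest hole; 25% headroom keeps partially merged holes detectable |
| median radius | 1 (3×3) | px | smallest neighborhood that kills single-pixel spikes without eroding 2-px-radius remnants |
| size constraints | 0.5–80 | µm² (µm³ in 3D) | typical HeLa nucleolar cross-sections; both bounds configurable |
| intensity above background | 100 | grey levels | on the order of the camera noise floor, so candidates whose contrast is within noise are rejected |
| background annulus | 1 | µm | intranuclear ring wide enough to average nucleoplasm, narrow enough to stay local |
| connectivity | 8 (2D) / 26 (3D) | — | diagonal-connected blobs are one nucleolus |
| nucleus min size | 30 | µm²/µm³ | rejects debris while keeping small nuclei |

Numerical choices: intensities are rendered in floating point, then
quantized (rounded, clipped) to the declared 8/16-bit range, matching camera
behavior; all neighborhood operators reflect at borders; per-nucleus Otsu is
computed over 256 histogram bins on the observed intranuclear response
range; a constant response within a nucleus yields no candidates rather than
an arbitrary split. Greedy evaluation matching breaks ties by larger IoU,
then lower predicted label.

## The synthetic benchmark

Real micrographs carry no per-pixel truth, so validation uses a parametric
scene generator (`scene_spec()`, `render_scene()`): elliptical (2D) or
flattened-ellipsoidal (3D) nuclei with random orientation, each containing
1–6 disjoint circular/spherical nucleoli; per-channel intensities planted as
background → nucleoplasm level → contrast-scaled nucleolar level; additive
Gaussian noise (optionally signal-scaled) and integer quantization. The same
spec and seed render bit-identical scenes. Contrast is parametrized so that
a positive value is the nucleolus:nucleoplasm enrichment ratio and a
negative value the fractional depletion (−0.8 plants nucleoli at 0.2× the
nucleoplasm), with defaults — nucleolin 2.5×, CAS/HuR −0.8, EU 3× on a
2000-grey-level nucleoplasm over a 200-grey-level background — chosen as
typical confocal values for strongly partitioned markers.

The five emulated treatment phenotypes live in one editable table
(`condition_table()`); each is a numeric encoding of a qualitative
observation, since no quantitative contrasts are published for them:

* **heat** scales negative-marker contrast by 0.05 (CAS/HuR enter
  nucleoli — an essentially complete collapse of the dark holes, which is a
  free parameter of the generator, not an inferred value);
* **DEM** scales overall levels by 1.2 and leaves contrasts intact;
* **actinomycin D** flips the positive marker's enrichment $r$ to the
  depletion $1/r - 1$ (nucleolin forms dark holes) and drops the EU effect
  to 0.2;
* **DRB** flattens the positive marker's contrast, fragments each nucleolus
  into two remnants at 0.7× radius, halves negative-marker depth, and makes
  each negative marker "miss" a disjoint random subset of nucleoli
  (probability 0.2 each, contrast attenuated ×0.05) — the construction that
  lets the add-combination recover what single markers lose.

What the generator does **not** emulate: optical PSF blur, photobleaching,
chromatic aberration, chromatin texture, irregular nuclear shapes, or
touching nucleoli. Passing tests therefore demonstrate the correctness of
the operators and the protocol logic under idealized geometry, not
performance on degraded real acquisitions; on real data the thresholds and
size constraints are the knobs to revisit.

## Design choices where the design was open

* **Hole filters as top-hats.** The original "detect holes" operators come
  from proprietary software; grayscale top-hats are the canonical
  small-blob-versus-background residues with exactly the described
  behavior, and stating them as formulas makes the choice testable.
* **Per-nucleus thresholding.** Candidates are seeded per nucleus (Otsu on
  intranuclear response), not globally, so a dim nucleus cannot be drowned
  out by a bright neighbor. A fixed global threshold mode exists for
  ImageJ-style workflows.
* **Add before detection.** The two negative-marker images are summed at
  widened precision and linearly rescaled *before* dark-hole detection,
  matching the published order of operations. Note the combined image's
  relative hole depth is a weighted average of the inputs' depths — it is
  bounded below by the weaker input and rises above the missing marker's
  depth at planted misses, which is what rescues detection; it cannot
  exceed the deeper input at a nucleolus both markers demarcate well.
* **Replicates as statistical units.** Averaging nucleoli within an
  experiment before testing avoids pseudoreplication; a per-nucleolus mode
  exists for comparison. Welch's test is the default (a pooled option
  matches the classical Student test); testing is two-sided; no
  multiple-testing correction by default (a Holm option exists), matching
  per-comparison star annotation.
* **Border nuclei** are flagged at segmentation and excluded at QC rather
  than deleted, so the exclusion is auditable.
* **Scene container.** Scenes are written as plain multi-page TIFF
  (channels as planes, z-major within channel) with a YAML metadata sidecar
  and CSV planted-means table; the contract is bit-exact round-tripping.

## Problem sizes used in the checks

The bundled suites run at desk scale: 50 noise-free and 50 SNR-5 control
fields (40 µm, 3 nuclei each) for recovery and marker-equivalence checks,
25 DRB fields (56 µm, 6 nuclei) for the add-combination comparison, 15 heat
fields for the failure-mode ordering, three replicates of paired
control/treated fields per planted effect size, 1000 simulated null
experiments for t-test calibration, and one 72×72×24 stack at 0.3 µm
z-spacing for the spherical-volume check. All quantities reported by
`scripts/acceptance.R` are recomputed from these runs at execution time.

## Known limitations

* Touching nucleoli are not split (no watershed); they count as one
  segment.
* The 3D path assumes complete nuclei along z; nuclei are never cut by the
  first/last slice in generated stacks.
* Global-field segment scoring (as opposed to per-nucleus) is not
  implemented.
* OME-XML metadata is not embedded in written TIFFs; geometry travels in
  the YAML sidecar.
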