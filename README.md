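# focalindex

Quantitative CT scoring of lung-injury focality for ARDS morphology.

Acute respiratory distress syndrome (ARDS) presents along a morphological
spectrum from *diffuse* (patchy, uniformly distributed loss of aeration) to
*focal* (dorsal/caudal consolidation with ventral sparing), and the two
sub-phenotypes respond differently to ventilator strategy. Visual
classification of thoracic CT into these categories is subjective and
error-prone. This package implements an objective alternative: the **focal
index**, a continuous score of regional heterogeneity computed from the
Hounsfield-unit (HU) distributions of two anatomically extreme lung regions,
together with the full regional quantitative-CT pipeline it sits in. It is
aimed at researchers analysing HU-calibrated thoracic CT (NIfTI or DICOM) and
at methodologists who want a fully synthetic, ground-truthed test bed for
regional aeration analysis.

## The method

For one scan the pipeline:

1. reads and canonicalizes the volume (cranial→caudal, ventral→dorsal,
   left→right; supine gravitational axis), applying an external lung mask or a
   semiautomatic threshold/connected-component segmentation;
2. clips in-mask HU to the analysable lung range [−1000, +100];
3. selects 18 axial slices evenly covering the lung's craniocaudal extent and
   splits them into apical / mediastinal / diaphragmatic thirds; each slice's
   lung extent is further cut into ventral / medial / dorsal thirds along the
   gravitational axis, giving **nine 3-D regions of interest**;
4. computes each region's HU distribution profile on a fixed grid of 220 bins
   of 5 HU, as percent of regional voxels, plus its aeration compartments
   (hyperaerated [−1000, −800), non-aerated [−100, +100]);
5. estimates per-slice and whole-lung gas volume (ml) and lung weight (g) from
   the standard linear HU decomposition (gas fraction = −HU/1000; tissue
   density = (HU + 1000)/1000 g/ml), interpolating between analysed slices;
6. scores focality from the ventral-apical (VA) and dorsal-diaphragmatic (DD)
   profiles:

   FI = 100 · ∫ |f_VA(x) − f_DD(x)| dx = 100 · Σ_b |p_VA(b) − p_DD(b)|,

   where f are the HU density curves (unit area) and p the per-bin probability
   masses. FI equals **200 × the total-variation distance** between the two
   regional HU distributions: 0 = complete overlap (homogeneous aeration),
   200 = disjoint support (maximal focality).

Cohort-level tools reproduce the statistical battery used to characterise the
score: Pearson correlations with Fisher-z 95% intervals, Cohen's kappa with an
asymptotic interval for rater agreement, and an OLS sensitivity regression of
the focal index on ventilator settings (PEEP, respiratory rate, Vt/PBW).

A seeded phantom generator builds synthetic thoracic CTs — two lung ellipsoids
in a soft-tissue body — whose regional HU laws blend a homogeneous aerated
lung (φ = 0) into full ventral-aerated / dorsal-consolidated separation
(φ = 1), with the exact focal index of the generating laws known analytically.

## Worked example

```r
library(focalindex)

ph  <- generate_phantom(phantom_config(phi = 0.8, scale = 0.12), seed = 7)
ph
#> <ct_phantom> phi = 0.80, analytic focal index 160.00, 20108 lung voxels

rep <- run_scan(ph$volume, ph$mask)
rep
#> <scan_report 'phantom_seed7'>
#>   focal index 159.55 (overlap 20.22%)
#>   gas 62.4 ml, weight 55.9 g
#>   0 warnings, config 3c94043d
```

The phantom was built with focality φ = 0.8, whose generating laws have an
exact focal index of 160.00; the pipeline measures 159.55 from the sampled
voxels, i.e. 20.22% of the two regions' probability mass overlaps. Gas volume
and weight are the interpolated whole-lung totals for this (small, `scale =
0.12`) phantom. `autoplot(focal_index(rep$profiles))` draws the two regional
curves with their non-overlapping area; `plot_hu_profiles(rep$profiles)` shows
all nine regions.

A command-line wrapper over the same functions ships in
`inst/cli/focalindex.R`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/focalindex.R", package="focalindex"))') \
  score --ct scan.nii.gz --mask mask.nii.gz --out report.json
```

with subcommands `score`, `segment`, `phantom` and `cohort` (exit codes:
0 ok, 2 input error, 3 stage failure).

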