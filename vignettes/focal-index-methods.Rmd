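---
title: "Regional quantitative CT and the focal index: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional quantitative CT and the focal index: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focalindex)
```

## The problem and the score

Lung injury in ARDS ranges from diffuse, patchy aeration loss to focal
dorsal-caudal consolidation with ventral sparing. Because CT attenuation of
lung tissue is essentially a linear gauge of aeration — −1000 HU is pure gas,
0 HU water, and +100 HU is taken as the dense end of non-aerated parenchyma —
regional HU histograms carry the morphological signal: in a focal lung, the
ventral-apical (VA) region stays aerated while the dorsal-diaphragmatic (DD)
region consolidates, pushing their HU distributions apart; in a diffuse lung
the two distributions coincide.

The focal index condenses this into one number. Let $f_{VA}$ and $f_{DD}$ be
the two regional HU distribution curves, each normalised to unit probability
mass over $[-1000, 100]$. Then

$$\mathrm{FI} \;=\; 100 \int \lvert f_{VA}(x) - f_{DD}(x)\rvert\, dx
 \;=\; 100 \sum_{b=1}^{220} \lvert p_{VA}(b) - p_{DD}(b)\rvert
 \;=\; 200\, d_{TV}(p_{VA}, p_{DD}),$$

where $p$ are the per-bin masses on the 5-HU grid and $d_{TV}$ is the total
variation distance. The scale runs from 0 (complete overlap) to 200 (disjoint
support). Because profiles are stored as percent per bin, the implementation
is literally the summed absolute percent difference.

One normalisation subtlety deserves a note. If each curve is normalised to an
*area of 100* and the integral is additionally multiplied by 100, the literal
composition yields a 0–20,000 scale. The 0–200 range quoted above only
results when the curves are treated as unit-area densities scaled by 100 —
equivalently, percent-per-bin histograms summed without the extra factor.
This package adopts that reading throughout: it is the only one consistent
with the score's stated endpoints, and it makes the identity with total
variation exact.

The index is symmetric, bounded, inherits the triangle inequality from
$d_{TV}$, is invariant to duplicating voxels (only distributions matter), and
can only decrease under bin coarsening — all properties enforced in the test
suite against an independent brute-force re-binning oracle.

## The regional partition

Eighteen axial slices are selected evenly over the lung's craniocaudal
extent, endpoints always included; ideal positions come from a uniform real
grid, are rounded (half caudally), and collisions shift caudally to the next
free slice. The 18 slices split 6/6/6 into apical, mediastinal and
diaphragmatic groups. On each selected slice, the anterior-posterior extent
of the lung mask is cut into equal-length ventral, medial and dorsal thirds;
each in-mask voxel is labelled by the band containing its AP coordinate. The
3 × 3 product yields nine 3-D regions whose labels are mutually exclusive and
jointly exhaustive over the analysed voxels.

Two open choices had to be fixed:

* **Per-slice vs global extent.** The gravitational thirds follow the lung's
  extent *on each slice* by default (`grav_extent = "per-slice"`), so the
  bands track the lung as its cross-section changes; a `"global"` mode using
  one extent over all selected slices is provided for sensitivity analyses.
* **Geometric vs voxel-count thirds.** Bands are equal length, not equal
  count. Boundaries are half-open and ventral-closed: a voxel exactly on a
  boundary joins the more dorsal band. Since AP spacing is uniform, lengths
  are computed in row-index units, which keeps band boundaries immune to the
  float32 truncation that NIfTI applies to header spacing (this matters: a
  boundary tie can otherwise flip between an in-memory and an on-disk run of
  the same scan).

Slice selection proceeds on native slices whatever the acquisition thickness;
the thickness is recorded in the selection rather than enforced.

## Profiles, compartments, quantitation

Profiles live on a fixed grid: 220 bins of 5 HU covering $[-1000, 100]$,
half-open $[\ell, \ell+5)$ with the final bin closed so +100 is counted.
In-mask values outside the domain are *clipped*, not excluded — this keeps
the mask size as the denominator of percentage histograms. Empty regions
yield all-zero profiles carrying an explicit empty flag; the focal index
refuses them rather than treating them as zero curves.

Aeration compartments sum profile mass over hyperaerated $[-1000, -800)$ and
non-aerated $[-100, +100]$ ranges (with normally and poorly aerated
compartments at the conventional −500 split as extras). The "between"
phrasing of compartment bounds is ambiguous at the shared boundaries; bins
belong to the compartment containing their left edge, the cut points are
configurable, and with 5-HU bins any alternative moves at most one bin
(≤ a few percent of mass in realistic profiles).

Gas volume and weight use the standard linear decomposition: gas fraction
$-x/1000$ for $x \in [-1000, 0]$ (zero above water), tissue density
$(x + 1000)/1000$ g/ml. Whole-lung totals linearly interpolate the per-slice
measurements across all intervening lung slices, holding the outermost
measured values to the lung ends; the interpolant is exact at analysed slices,
so analysing every slice reproduces the direct sum, and gas + tissue volume
equals the in-mask volume identically.

## Segmentation

The package prefers an externally supplied mask; its own segmentation is a
fallback implementing the standard quantitative-CT recipe: threshold at
−300 HU, remove components touching the in-plane image border (exterior air),
keep 3-D connected components of at least 50 ml, and close with a 3-mm ball
so dense consolidations enclosed by aerated lung are re-included. Optional
seed points restrict the result to seeded components — the "semiautomatic"
interaction. None of the scientific core depends on this module; all
validation runs from ground-truth masks.

## The phantom generator

The generator emulates what the pipeline needs to be validated against:
two lung-shaped 3-D regions whose regional HU laws range continuously from
perfectly homogeneous to fully separated, with the focal index of the
generating laws known exactly.

Each region's law is a two-class mixture of an *aerated* material
(−850 ± 10 HU) and a *consolidated* material (−50 ± 10 HU), convolved with
Gaussian acquisition noise (SD 6 HU) and clipped to the HU domain exactly as
`clip_hu()` treats data. The consolidated weight of a region is
$\alpha = \varphi\, g$, where $\varphi \in [0,1]$ is the focality parameter
and $g \in [0,1]$ the region's position along the combined ventral→dorsal and
apex→diaphragm gradient (equal weights by default, configurable). Thus
$\varphi = 0$ gives one homogeneous aerated law everywhere (analytic FI 0) and
$\varphi = 1$ gives pure-aerated VA vs pure-consolidated DD (analytic FI 200,
disjoint supports); the analytic index is linear in between, computed exactly
from the mixture CDFs projected on the 5-HU grid (clipped tails lumped into
the end bins) and cross-checked in tests against a fine-grid (0.1 HU) density
integration.

Design notes, in the order they were decided:

* **Material classes are narrow (SD 10 HU) by construction**, like the
  uniform-density inserts of physical QA phantoms, with acquisition noise as
  a separate dial. The empirical focal index of two *identical* laws is pure
  sampling noise with expectation $\approx 100 \sum_b \sqrt{2 p_b/n}\,
  \sqrt{2/\pi}$, which grows with the law's effective spread; concentrated
  classes make the measured index converge to the analytic value at the
  voxel counts the recovery checks use ($10^5$ per region: bias ≈ 1,
  SD ≈ 0.3). A patient-realistic broad profile (SD 50–100 HU) would leave
  2–4 index points of irreducible sampling noise at the same voxel count —
  worth remembering when interpreting small FI differences in real data.
* **Default geometry** (18 slices, in-plane semi-axes 115 × 165 voxels, two
  ellipsoids side by side in a soft-tissue body at +40 HU on an air
  background) is sized so that the *smallest* of the nine regions holds at
  least $10^5$ voxels; `scale` shrinks the in-plane dimensions for quick
  experiments with the same machinery.
* The phantom labels its regions with the package's own partition of the
  ground-truth mask, then draws each voxel independently from its region's
  law; one integer seed fully determines the output, and the generator
  restores the caller's RNG state.

What passing recovery tests does and does not show: the phantom validates
binning, partition bookkeeping, normalisation and the TV computation end to
end, but its voxels are spatially independent within regions — no texture,
airways, vessels, gravity-dependent gradients *within* a region, or
respiratory-phase effects. Agreement on phantoms is a necessary, not a
sufficient, condition for validity on patients. One consequence worth noting:
in this family, lung weight *rises* with focality (consolidation replaces gas
with tissue at fixed anatomy), whereas oedema physiology in real diffuse
injury can produce the opposite cohort-level trend; the phantom makes no
attempt to emulate that.

## Cohort statistics

Correlations use Pearson's $r$ (the rank-based Spearman variant is exposed as
an option) with the Fisher z-transform 95% interval and a two-sided t-test on
$n-2$ degrees of freedom, via `stats::cor.test()`. Rater agreement on the
binary diffuse/focal call uses Cohen's kappa with the large-sample standard
error $\sqrt{p_o(1-p_o)/(n(1-p_e)^2)}$, the interval truncated to $[-1, 1]$;
with 37 scans of which 35 are rated diffuse by both raters, one split and one
focal by both, $\kappa = 70/107 \approx 0.65$ with an interval reaching the
truncation bound — a reminder that agreement is poorly identified when one
category dominates. The sensitivity regression is plain OLS of the focal
index on PEEP (cmH₂O), respiratory rate (breaths/min) and Vt/PBW (ml/kg),
with explicit collinearity detection; under the null of no influence,
$E[R^2] = k/(n-1)$ (≈ 0.086 at $n=36$, $k=3$) while adjusted $R^2$ centres at
zero — the test suite verifies both by simulation.

## Numerical and engineering choices

* Canonical storage order is fixed (cranial→caudal, ventral→dorsal,
  left→right) and derived from header orientation only — volumes with no
  orientation metadata, oblique DICOM geometry, or inconsistent series are
  rejected rather than guessed at. No in-plane tilt correction is applied.
* DICOM support is a deliberately minimal reader/writer (uncompressed,
  implicit/explicit VR little endian, axis-aligned), sufficient for
  conventional axial CT exports; its encoding is verified in tests against an
  independent DICOM implementation.
* Reports serialize to JSON at full precision; a scan report is a pure
  function of inputs and configuration (a config digest is embedded), and
  reruns are byte-identical. Statistics are computed on a cohort table sorted
  by scan id, so manifest row order is irrelevant.
* Problem sizes used in the shipped tests: recovery runs 20 full-size
  phantoms (four seeds at each $\varphi \in \{0, .25, .5, .75, 1\}$, ≈ 1.4M
  lung voxels each); oracle equivalence uses 100 random profile pairs; the
  null-regression simulation uses 1000 replicates at the study's $n = 36$.
  Smaller `scale` phantoms are used where only bookkeeping is under test.

## Known limitations

Ellipsoidal anatomy and regionally-iid voxels (above); header-based
reorientation only; segmentation makes no attempt to excise airways or large
vessels from the parenchyma; the interpolation scheme for whole-lung totals
is linear (smooth alternatives would differ slightly on sparse selections);
and the package deliberately stops short of proposing clinical cut-offs for
"focal" vs "diffuse" — the score is continuous by design.
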