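---
title: "Quantifying toroidal nucleoid organization: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying toroidal nucleoid organization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleotorus)
```

## The measurement problem

In *Escherichia coli* cells widened with the MreB inhibitor A22, the
chromosome relaxes into a toroidal (donut-shaped) conformation, and when
sister decatenation fails, into a figure-eight of two catenated rings. At
this geometry, multi-channel fluorescence imaging (phase contrast, a DNA
stain, labeled MukBEF — the *E. coli* SMC condensin — and FROS foci marking
the replication origin *ori* and terminus *ter*) resolves where the SMC sits
on the chromosome and what it does to local DNA density. `nucleotorus`
implements the per-cell quantification for such images:

* cell masks from phase contrast with automated proximity QC;
* per-channel signal masks (Gaussian smoothing, background removal, Otsu);
* the chromosome central ridge (backbone), its topology class
  (toroid / figure-eight / open / complex), contour length, and
  full-width-at-half-maximum (FWHM) width;
* Feret diameters of MukB clusters;
* intensity-overlap colocalization and binary focus–mask colocalization;
* the per-area DNA **compaction ratio** in MukB-occupied regions;
* the **arm asymmetricity** `A = |ΣIR − ΣIL| / (ΣIR + ΣIL)` around *ori*;
* normalized sum chromosome signal and ploidy classification;
* one-way ANOVA with the conventional star annotations;
* a circular-genome window count of binding-site peaks around *oriC*.

Because no raw microscopy data accompany the study conditions this package
targets, a first-class synthetic generator (`render_cell()`,
`render_population()`, `write_fixture_suite()`) produces images with known
ground truth; every estimator is validated by parameter recovery against it.

## The synthetic image model

A cell is a bright-background phase-contrast disk (dark interior, edge halo)
containing a DNA tube rendered as a Gaussian-profile annulus along a
parametric curve: one circle of radius $R$ for a toroid, two tangent circles
for a figure-eight dimer, or a circular arc (default 300°) for an open
nucleoid. The tube cross-section is Gaussian with sigma $\sigma_t$, so the
pre-blur width is $\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma_t$ and the toroid
contour length is $2\pi R$ — these analytic truths are stored per cell.

MukB occupies an angular arc of the ring. Compaction is a multiplicative
density factor $c \ge 1$ on the DNA tube inside that arc, renormalized so
the summed DNA intensity always equals the spec'd photon total (which keeps
intensity conservation testable). Arm bias $b \in [0,1]$ multiplies the
density by $(1+b)$ on the clockwise side of the ori axis and $(1-b)$ on the
other side, so the asymmetricity formula applied to the noiseless, unblurred
MukB channel returns exactly $b$ — provided the pixel grid is symmetric
about that axis. For this reason cells default to a half-integer ring center
in an even frame: no pixel row then lies exactly on the axis, and the
self-consistency identity holds to 1e-6 (it is tested at that tolerance).
Foci are point sources splatted at sub-pixel positions; after PSF blur they
become Gaussian spots of the PSF width.

Imaging corruption is a Gaussian PSF (zero-padded convolution, conserving
in-frame intensity to < 1% for objects away from the border), Poisson shot
noise, and optional Gaussian read noise (sd 2 photons). One integer seed
drives everything; populations derive one stream per cell by counter, so
fixtures are bit-reproducible.

**Which PSF?** The quantification is meant to run on deconvolved stacks, as
is standard for this kind of data; the generator therefore defaults to a
post-deconvolution-like lateral PSF of $\sigma = 0.07\,\mu m$ (FWHM ≈ 165
nm). The raw widefield PSF (FWHM 0.35 µm laterally, 0.80 µm axially) is kept
in `imaging_config()` and is used for the binary focus-footprint rule. At
the raw widefield width the tube would appear ~28% wider than truth and the
measured asymmetricity would be attenuated by ~0.08 — effects of optics, not
of the estimators.

**Photon budgets.** The study conditions state no per-channel SNR, so the
fixtures use 2×10⁵ DNA photons, 6×10⁴ MukB photons, and 1.5×10⁴ photons per
focus per cell, chosen so the peak tube signal is roughly 40× its shot
noise — a realistic regime for bright nucleoid stains. The fixture manifest
records these values.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `pixel_size_um` | 0.065 | µm/px | physical calibration |
| `roi_diameter_px` | 20 (= 1.3 µm) | px | asymmetry ROI around *ori* |
| `smooth_sigma_px` | 1 | px | smoothing before thresholding |
| `min_cluster_px` | 4 | px | minimum cluster area kept |
| `psf_fwhm_lateral_um` | 0.35 | µm | focus footprint diameter |
| `prune_len` (backbone) | 5 | px | spur pruning length |
| `station_step` / `profile_half_px` | 3 / 12 | px | FWHM sampling geometry |
| multiplicity thresholds | 1.5, 3 | — | monomer/dimer/multimer cuts |

The strain presets (`strain_preset()`) encode the population conditions each
strain exhibits: wildtype (ring 4.5 µm contour, tube FWHM 0.44 µm,
compaction 1.8, MukB arc ±25° over *ori*, MukB arm bias 0.33, DNA arm bias
0.27), a MatP deletion (contour 3.5 µm, compaction 1.75, a wide arc
spreading across one arm onto *ter*, arm bias 0.49), an ATPase-deficient
MukB-EQ mutant (contour 3.8 µm, compaction 1.2, near-uniform arc covering
*ter*, arm bias 0.26), and a MukB-deletion dimer (figure-eight, twice the
DNA content, 2 *ori* + 2 *ter* foci).

## Numerical and design choices

**Threshold rule.** The field's description of this stage — Gaussian filter,
background removal, thresholding — fixes no rule, so the package uses Otsu
on the smoothed, background-subtracted in-cell histogram: parameter-free and
recorded per cell. The background estimate is the median of in-cell pixels
below their 25th percentile, robust to large bright structures.

**Sums on raw, masks from smoothed.** All intensity sums (overlap
percentages, compaction, asymmetry, center of mass, total DNA) are taken on
the raw background-subtracted image. Smoothing is used only to derive masks
and to detect foci: a 1 px smoothing kernel mixes signal across the central
axis exactly like PSF blur and would attenuate the measured asymmetricity by
about 0.05.

**Mask-dependent truths and recovery.** The compaction ratio and the
DNA-in-MukB fraction depend on the region definition. Any global intensity
threshold yields a radially wider DNA band inside the brighter
(compacted) arc than outside it, which dilutes the measured per-area ratio
(≈1.6 measured at a true factor of 1.8, saturating there even as the
threshold is lowered). Recovery tests therefore evaluate these two
estimators with the geometric ground-truth footprints (`true_masks()`: the
half-maximum tube band, cut to the MukB arc), isolating estimator and
imaging error from segmentation error; segmentation fidelity is tested
separately (mask–footprint IoU ≥ 0.8 on noiseless fixtures), and the
end-to-end Otsu-mask values are validated through the strain orderings they
must reproduce. With truth footprints, blur leaking intensity across the
footprint boundary leaves a residual bias of about −0.09 at factor 1.8,
within the ±0.15 recovery band.

**Contour length.** The ordered skeleton path counts diagonal steps as √2
px, but a raw (1, √2) chain length over-reads a digital circle by ~5–6% on
average. The path is therefore lightly smoothed (moving average, window 5;
circular for loops, symmetric and endpoint-preserving for open paths) before
summing segment lengths. Collinear runs are fixed points of this filter, so
straight and 45° paths keep their exact length, while the zigzag bias on
curves disappears (a rendered annulus of radius 10 px reads within 2% of
2π·10). For non-toroidal nucleoids the loop/path lengths are summed and the
topology class flags the case; note that skeletonization erodes open-path
ends by roughly the tube half-width, so open contours are under-read by
~15% — only closed-loop lengths should be compared across strains.

**Backbone.** Medial-axis thinning (Zhang–Suen), spur pruning below 5 px,
and loop detection on the skeleton adjacency graph, with diagonal edges
dropped when they shortcut a shared 4-neighbor. Deterministic path ordering
(topmost-then-leftmost start, clockwise loops) makes the left/right side
labels reproducible across runs. A figure-eight of two tangent circles
yields two cycles sharing one or two junction-pixel clusters depending on
discretization; classification requires two cycles and at least one shared
branch node.

**Asymmetricity conventions.** The ROI is a disk of *diameter* 20 px (the
stated 1.3 µm at 0.065 µm/px resolves diameter vs radius). Pixels exactly on
the axis split 50/50 between the arms (an exclude-axis mode exists). When
two *ori* foci are present the brighter one anchors the ROI and the cell is
flagged multi-ori. Side labels are geometric (clockwise/anticlockwise), not
genomic: imaging alone cannot orient the arms.

**Ploidy.** The reference statistic for the normalized sum signal is the
median over 1-*ori*/1-*ter* cells (robust, and exactly 1 by construction for
the reference group). Classification thresholds sit at the midpoints between
integer chromosome equivalents (1.5 and 3) and are configurable.

**Circular genome windows.** Peak membership is by interval midpoint;
upstream/downstream mean increasing/decreasing genomic coordinate relative
to a user-supplied *oriC* position (the mapping to physical left/right arms
is a labeling convention). Genome length and *oriC* coordinate are required
inputs — there are no defaults for circular arithmetic.

**Statistics.** Group comparisons use a single-factor ANOVA
(`stats::oneway.test` with equal variances, the classic sum-of-squares
decomposition; the test suite checks it against an explicit hand
decomposition and against F = t² for two groups). Stars follow ns / * / ** /
*** / **** at 0.05 / 0.01 / 0.001 / 0.0001 with boundary values assigned to
the more significant bin. No multiple-testing correction is applied, and
medians are reported alongside means because asymmetricity distributions are
skewed.

## What the generator does and does not emulate

The generator reproduces the *statistical structure* the estimators assume:
ring/figure-eight geometry with Gaussian tube profiles, an SMC arc with a
multiplicative compaction factor, constant per-arm bias, diffraction-limited
foci, Poisson + Gaussian noise, and grid discretization. It does not emulate
cell-to-cell shape irregularity, 3-D structure of the ~1 µm-tall cell,
intracellular background gradients, photobleaching, or the deconvolution
step itself. Passing recovery tests therefore demonstrates that the
estimators are unbiased at realistic SNR under the model's assumptions — not
that real images satisfy those assumptions. Two quantified model-level
caveats: the global (1 ± b) arm bias confounds the compaction ratio when the
MukB arc is not symmetric about the ori axis (recovery fixtures isolate one
parameter at a time), and measured asymmetricity is attenuated by any
residual PSF (≈ −0.055 at σ = 0.07 µm), so image-level medians
systematically understate the underlying occupancy bias — for real data as
for synthetic.

## A worked population run

```{r population, eval = FALSE}
pop <- render_population(
  rep(list(strain_preset("wildtype", noise_model = "poisson+gaussian")), 50),
  layout = "grid", seed = 11)
res <- analyze_stack(pop$stack, strain_label = "wildtype")
summarize_population(res)
```

On this 50-cell wildtype population the pipeline reports median
asymmetricity ≈ 0.24 for DNA and ≈ 0.28 for MukB (ordered as generated:
0.27 vs 0.33 before attenuation), mean contour length ≈ 4.37 µm (truth
4.5 µm), mean FWHM ≈ 0.47 µm apparent (tube truth 0.44 µm before blur),
and classifies all 50 backbones as toroids. Problem sizes throughout the
test suite (50-cell populations, 6–12 cells per recovery fixture) keep the
whole validation run at a few minutes on a single core while holding the
recovery standard errors well inside the stated tolerances.

## Known limitations

* Otsu-mask compaction and overlap values are threshold-dependent; compare
  them across strains processed identically, not against absolute truth.
* Open and complex topologies get summed path lengths with end-erosion bias.
* Asymmetricity near-zero biases upward under noise (it is a folded
  statistic), which is why population *medians* of a zero-bias channel sit
  near 0.01–0.05 rather than 0.
* The CLI (`inst/cli/nucleotorus.R`) and `run_pipeline()` cover the
  simulate → analyze → report path; proprietary microscope formats are out
  of scope (TIFF + JSON sidecar only).
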