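---
title: "Simulating segmentation variability and scoring radiomic feature stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating segmentation variability and scoring radiomic feature stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Radiomic features are summary statistics of the image intensities inside a
region of interest (ROI). When different annotators contour the same organ —
here, the whole prostate gland on multi-parametric MRI — they produce
slightly different masks, and features that change appreciably under those
differences are unreliable as biomarkers. Recruiting several radiologists per
study is rarely feasible, so `segstab` simulates annotators instead: it
perturbs a single ground-truth mask under bounded affine transformations that
mimic the contouring behaviour observed between human raters, extracts the
full radiomic feature vector for every synthetic contour, and scores each
feature's stability with the intraclass correlation coefficient ICC(1,1).

## The contour generator

Each synthetic contour plays the role of one rater. Two perturbation
mechanisms are composed:

* **In-plane.** For every axial slice, the tight bounding box of the slice
  contour is measured (width $w$, height $h$, in mm). The slice is resampled
  through the affine map that scales the contour to $w + dw$ and $h + dh$
  about its own centroid and rotates it by $\alpha$ about the slice normal,
  with $dw, dh \sim U(-2.7, 2.7)$ mm and $\alpha \sim U(-5^\circ,
  +5^\circ)$. The 2.7 mm bound is the 95% range corresponding to the
  ~1.1 mm standard deviation reported for inter-observer prostate contouring
  on MRI. Binary slices are resampled through the inverse map with
  nearest-neighbour interpolation, which preserves binarity.
* **Out-of-plane.** The choice of the first and last ROI slice in the
  cranio-caudal direction is shifted independently at each end by
  $\delta \in \{-1, 0, +1\}$ slices, drawn uniformly. A shrink empties the
  boundary slice; a growth replicates the current boundary contour into the
  adjacent empty slice — the minimal assumption, introducing no new shape.

Two rater biases are modelled for the in-plane component. Under **random**
bias every slice draws $dw$, $dh$, $\alpha$ independently. Under
**systematic** bias the *signs* of $dw$, $dh$ and $\alpha$ are drawn once per
contour and only the magnitudes vary per slice, emulating consistently
"abundant" or "restrictive" annotators. Five scenarios result: in-plane
(random/systematic), out-of-plane (always random — boundary-slice choice has
no natural direction preference), and their composition, where the
boundary shift is applied first and the in-plane perturbation acts on the
resulting extent.

Design choices worth making explicit:

* Signs under systematic bias are fixed *per contour*, independently for
  $dw$, $dh$, $\alpha$: each of the 15 contours is one rater with one
  tendency. The rotation magnitude is drawn per slice by default
  (`alpha_scope = "slice"`); a per-contour rotation is available.
* Width and height are axis-aligned bounding-box extents of the slice
  foreground — well defined for irregular contours and matching the usual
  illustration of contour "dimension change".
* Scaling and rotation are centred on the per-slice foreground centroid, so
  the perturbation changes dimensions in place rather than drifting the
  contour. An optional centroid translation bound exists
  (`translation_bound`, default 0 = off) because "shifting" is sometimes
  listed among plausible rater variations, but its intended magnitude is not
  established; it is excluded from the default experiments.
* Degenerate slivers: with 3 mm slices an irregular gland often terminates
  in a one-voxel-wide boundary sliver ($w \approx 1$ mm). A draw with
  $w + dw \le 0$ is interpreted as the scale $\to 0$ limit — the simulated
  rater omits the sliver and the slice becomes empty (logged with applied
  scale 0). Erroring here would make the default bounds unusable on
  realistic glands.

Contour fidelity is summarised by the Dice coefficient
$2|A \cap B| / (|A| + |B|)$ against the ground truth, evaluated on each
sequence's native grid (the per-sequence grids differ, which is why
per-sequence Dice tables are reported before any resampling).

## The phantom

All experiments are runnable without patient data. A phantom subject is an
irregular ellipsoidal "gland" (default semi-axes 22.5 × 19 × 20 mm,
prostate-scale) voxelised on one grid per sequence (defaults: T2w
0.297 × 0.297 × 3 mm, DWI 1.25 × 1.25 × 3 mm, DCE 1.136 × 1.136 × 3 mm).
Surface irregularity is a band-limited radial modulation — a short sum of
random low-frequency plane-wave cosines on the unit sphere, amplitude
`surface_irregularity` × local radius (default 0.1) — which yields smooth,
connected, non-ellipsoidal glands. Intensities are smooth Gaussian random
textures (3 mm correlation length) with distinct in-gland/background means;
the DWI stack follows $S(b) = S_0 e^{-bA}$ with a spatially varying $A$
around $1.2 \times 10^{-3}$ mm²/s; the DCE series follows a gamma-variate
enhancement curve with time-to-peak 75 s over acquisitions every 10 s from 0
to 180 s, so wash-in (positive) and wash-out (negative) subtractions are both
non-zero around the 90 s split. Additive noise is available
(`noise_sd`) but defaults to 0, keeping the ADC-recovery contract exact.

In the Dice experiments, per-subject semi-axes are jittered ±10% to emulate
population size variation; that choice was made once, up front. What the
phantom does **not** emulate: zonal anatomy, lesions, MR physics (bias
fields, coils, k-space artefacts), or the tissue-boundary ambiguity that
drives real annotator disagreement. A green phantom test therefore
establishes that the *machinery* reproduces the published contour-overlap
statistics at prostate scale, not that any particular feature is stable in
patients.

## Preprocessing

Derived maps are computed in native space: the apparent diffusion
coefficient as the negative slope of an ordinary least-squares line through
$(b, \ln S)$ (exact for mono-exponential signals; non-positive samples are
excluded voxelwise and voxels with fewer than two usable points are zeroed
and tallied), and the dynamic contrast-enhanced subtraction maps by
splitting the series at the earliest acquisition at or after 90 s
($\varepsilon \ge 0$, matching the $90 + \varepsilon$ notation): wash-in =
split − first, wash-out = last − split.

All volumes are then resampled to 2 × 2 × 2 mm: intensity images with a
cubic interpolant in-plane and nearest neighbour through-plane (avoiding
interpolation artefacts across thick slices), masks with nearest neighbour
everywhere. The in-plane cubic pass is implemented as separable natural
cubic-spline interpolation matrices; this is a different member of the same
family as the third-order B-spline interpolator used by ITK-based pipelines
(both are C² cubic interpolants, exact on constants and linear ramps), and
no claim of voxel-level parity with ITK resampling is made.

Intensities are normalized by z-scoring on the ground-truth ROI (T2w and
subtraction maps, whose intensities are relative) or on the pooled ROI
voxels of all subjects (the ADC map, whose values have absolute meaning),
clipping at 3σ, and rescaling to mean 300 / sd 100, which places virtually
all values in [0, 600]. Normalization statistics always come from the
ground-truth ROI; the perturbed contours reuse the same affine map, since
re-normalizing per contour would confound the stability experiment with
normalization variability.

## Feature extraction

Features are extracted from 17 image variants: the original image, four
scale-normalised Laplacian-of-Gaussian responses (σ = 2, 3, 4, 5 mm,
physical units — hence the isotropic-grid requirement), eight single-level
separable wavelet decompositions (H/L per axis), and four monotone intensity
remappings (square, square root, logarithm, exponential, each rescaled to
the input range). The wavelet kernels are undecimated Haar pairs normalised
as mean and half-difference, so the all-low-pass variant of a constant image
is that constant; the coif1 kernels of the reference Python extractor are
not reproduced, and parity for wavelet/LoG variants is accordingly not
claimed (the intensity filters and the matrix-based features follow the
reference definitions).

Grey levels are discretised at a fixed bin width of 5 intensity units
anchored at the ROI minimum: label = ⌊(x − min)/5⌋ + 1 with
⌈(max − min)/5⌉ bins and the exact top edge folded into the last bin, so a
full-range [0, 600] ROI yields exactly 120 grey levels. Per variant, 72
features are computed — 18 first-order, 22 grey-level co-occurrence, 16
run-length, 16 size-zone — for 1224 features per image/mask pair. The
co-occurrence family implements the 22 features active by default in the
reference extractor (SumAverage, redundant with JointAverage, and MCC are
excluded); the exact name list is emitted in every output header.
Co-occurrence and run-length matrices are built per direction over the 13
unique 3D offsets, symmetrised (co-occurrence) and averaged feature-wise
across directions; size zones are 26-connected components of equal grey
level. Degenerate matrices (single-voxel ROIs with no voxel pairs) produce
zero-valued features carrying a degenerate flag rather than NaN, so a single
pathological rater cannot silently poison a ratings matrix. Shape features
are deliberately absent: the 1224 = 17 × 72 arithmetic contains none, and
shape is exactly what the perturbation changes.

## Stability analysis

For each feature, the subjects × raters matrix (by default the ground truth
plus 15 synthetic contours, k = 16; the original can be excluded) feeds a
one-way random-effects, single-rater, absolute-agreement intraclass
correlation:

$$\mathrm{ICC}(1,1) = \frac{MS_B - MS_W}{MS_B + (k-1) MS_W}$$

with the 95% confidence interval from the F statistic $MS_B / MS_W$. The
one-way model is the right one here because each synthetic contour is a
random draw from a population of raters, not a fixed panel. A feature is
**stable** when the CI lower bound is strictly above 0.90 ("above"
verbatim, hence strict); **robust** when the minimum of the internal and
external lower bounds clears the same threshold — equivalently, stable in
both datasets. Per base feature, the stable-filter set consists of the
internally stable variants and the best filter(s) maximise the
cross-dataset overlap (ties all reported). Family-level summaries report
the fraction of base features stable/robust under the Original
(unfiltered) configuration and under Best-Filtered, where any qualifying
variant counts. Features with any non-finite value across raters are
excluded and listed, never imputed — imputation would fabricate agreement.
A ratings matrix with no variance at all is flagged degenerate and treated
as not stable, never silently ICC = 1.

## Numerical and testing choices

* Tolerances: the ICC implementation is required to match a brute-force
  ANOVA oracle to 1e-10; analytic phantom-volume and area-scaling checks
  use 2% bands reflecting nearest-neighbour voxelisation error.
* Dice reproduction runs on the diffusion-like grid (1.25 × 1.25 × 3 mm):
  the published per-sequence means are identical across in-plane spacings,
  and the coarser grid keeps 100 subjects × 15 contours × 3 scenarios under
  a minute.
* Identity shortcut: zero-magnitude slice parameters return the slice
  untouched, so zero-bound configurations are bit-exact identities and the
  end-to-end identity contract (`dice = 1`, ICC = 1 or degenerate) holds
  without floating-point caveats.
* Determinism: every stochastic stage takes a seed; `augment()` restores
  the caller's RNG state, and the pipeline derives per-subject seeds from
  the global one, so a manifest replay reproduces every CSV byte for byte.
* Whether the ground-truth contour joins the rater panel is configurable
  (`include_original`, default TRUE, recorded in the run manifest); the
  published description leaves this open and the default mirrors the
  workflow figure, where the original segmentation accompanies the
  synthetic contours.
* ADC population statistics are recomputed per cohort by default; freezing
  them from a reference cohort is possible by applying
  `normalize_population()` to the pooled reference and reusing its
  attributes, but no cohort transfer is attempted here.

## Known limitations

The perturbation family is affine per slice plus boundary-slice shifts: it
cannot produce locally non-rigid disagreement (elastic boundary wobble) or
intensity-driven ambiguity. Cohort-specific robustness percentages from the
original patient populations are not reproducible from phantoms and are out
of scope; the package reproduces the structural counts, the Dice
distributions at phantom scale, and the statistical machinery that turns
feature tables into stability verdicts.
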