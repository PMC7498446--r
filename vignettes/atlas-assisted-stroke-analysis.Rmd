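---
title: "Atlas-assisted analysis of stroke neuroimages: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atlas-assisted analysis of stroke neuroimages: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(strokeatlas)
```

# Overview

`strokeatlas` implements an atlas-assisted workflow for stroke neuroimaging:

1. **Midsagittal plane (MSP) extraction** from a 3D scan by a symmetrized
   Kullback–Leibler (KL) intensity divergence, with a skull-fit pre-rotation
   extension for acquisitions with a large head tilt.
2. **Ellipse-based landmark estimation and piecewise-linear atlas mapping**
   (the Talairach-style 12-region transform and its extended 24-region form),
   producing an individualized anatomy/territory atlas on the scan grid.
3. **Region-of-interest analysis** in three regimes: atlas-defined ROIs
   (left/right paired comparison for detection), atlas-quantified ROIs
   (structure contributions to a lesion; thrombolysis decision ratios), and
   ROIs that create an atlas (the probabilistic stroke atlas, PSA).
4. **Lesion segmentation**: multi-modal thresholding for white-matter
   hyperintensities, hemisphere-PDF divergence for diffusion lesions, skull-
   based CT brain extraction and template-confined CSF removal.
5. A **procedural head-phantom and cohort generator** that provides ground
   truth for every stage, so the whole pipeline is testable without clinical
   data.

Everything operates on a plain `vol3d` container (3D array + voxel spacing +
world origin, axes right/anterior/superior); NIfTI-1 files are read and
written through RNifti.

# The synthetic head phantom

The generator emulates the aspects of a head scan that the algorithms
actually consume, not photorealism:

* a left-right symmetric **brain ellipsoid** (default semi-axes 60 x 75 x 55
  mm) with a gray-matter shell and white-matter core (CT means 106 / 96 on an
  8-bit-like scale);
* an **interhemispheric fissure**: a CSF sheet (mean 30) on the exact
  midplane whose width undulates smoothly between 0.8 and 2.4 mm, bridged by
  a corpus-callosum patch, and carrying a thin **falx** membrane (mean 150)
  in its superior part. Both sheets are rendered with analytic
  partial-volume fractions so they survive coarse voxel grids;
* paired **lateral ventricles**, a CSF-filled subarachnoid gap (4 mm) and a
  6 mm **skull shell** (mean 250) for the CT modality; MR-style modalities
  (`"mr"` giving T1/T2/PD views, `"dwi"`) use modality-specific tissue means
  and a dark skull;
* acquisition effects: a Gaussian point-spread function (`psf_mm`, default
  1 mm), additive noise (`noise_sd`, default 2), an optional low-order
  polynomial multiplicative bias field (`inhomogeneity_pct`), thick-slice
  resampling along z (`slice_thickness_mm`), and rigid rotation
  (`rotation_deg`, applied by trilinear resampling while the ground truth is
  transformed analytically);
* a smooth **intra-tissue texture** field (`texture_sd`, default 4,
  correlation length 8 mm). The field is exactly mirror-symmetric about the
  midplane, so it makes tissue histograms realistic without introducing
  hemispheric asymmetry. Without it, partial-volume mixtures at tissue
  boundaries are "novel" intensities that exist nowhere else in the volume
  and systematically distract any histogram-novelty objective — uniform-
  tissue phantoms are actually *harder* for the KL method than real scans;
* spherical **lesions** (hypodense 75, hyperdense 170, or WMH contrast on
  MR), clipped to the brain.

What the phantom deliberately does **not** model: cortical folding, gray
matter heterogeneity beyond the texture field, perfusion physics, beam
hardening or streak artifacts, and non-spherical lesion shapes. Passing
tests on phantoms therefore demonstrate algorithmic correctness under
controlled symmetry/contrast conditions, not clinical performance.

Cohorts (`make_cohort`) place spherical lesions uniformly inside the
normalized-space brain and generate outcome variables as
`coupling(centroid, volume) + noise`. Couplings are functions of both the
lesion centroid and its volume: the study design this emulates selects
comparable patients by infarct volume and severity scores, which only makes
sense when outcomes actually co-vary with those variables. The default
couplings are mild linear gradients (e.g. mRS-like outcome
`3 + 0.025 x + 0.04 (V - 20)`), with noise SD 0.3 in grade units.

# Midsagittal plane extraction

**Coarse stage** (as the KL formulation prescribes): the sagittal slice
stack is restricted to a volume of interest around the head's own sagittal
centre (half-width = half the head's sagittal extent by default); the first
VOI slice is the reference; every slice's foreground intensity histogram
(64 bins over the robust range, background excluded by an air-peak decay
threshold, a bright skull shell excluded by a high cut) is scored with the
symmetrized KL measure against the reference, and the maximizer is the
coarse MSP, ties resolved towards the centre.

The KL measure itself is the J-divergence `sum((p-q) log(p/q))` computed
after adding `eps` to each bin and renormalizing; the symmetrized form
removes the dependence on which distribution is called the reference.

**Fine stage**: the plane is parameterized by the sagittal offsets of three
corner points (equivalently: sagittal position + two tilt slopes). A global
scan over tilts up to ±27° and sagittal positions around the head centroid
is followed by multi-start coordinate descent (one round from each of the
three best mutually distinct scan candidates, full depth from the winner), a
shrinking-range corner-offset search, and a final polish on a 3x denser
lattice (the objective's sampling noise shrinks with the sample count). Plane intensities are sampled on a golden-ratio lattice — a regular
lattice beats against the voxel grid and produces spurious local maxima.

Two design choices here were genuinely open and deserve justification:

* **Search range.** The initial search must span the whole robustness band
  (±15° single-axis and beyond), so the tilt scan covers ±27°; a search
  seeded only a few slice-spacings from the coarse plane could never reach a
  15° tilt.
* **Fine-stage reference distribution.** Scoring candidate planes against a
  *single* lateral slice makes partial-volume "walls" beside the fissure the
  global maximizer on some grids: their mixture intensities are rare in any
  one slice. The fine stage therefore scores against the *averaged*
  histogram of the VOI's outer slices on both sides. That reference already
  contains every ordinary boundary mixture (ventricle walls, subarachnoid
  rim), so only genuinely midline features — fissure CSF, falx — remain
  novel, and the KL maximum lands on the midsagittal plane. The coarse
  stage is unchanged.

**Tilt extension** (`extract_msp_tilted`): the skull shell is thresholded at
80% of the 99.5th intensity percentile; per axial slice the shell points are
fitted with the direct least-squares ellipse, yaw is the median in-plane
major-axis orientation, and pitch/roll come from the linear drift of the
ellipse centres along z. The volume is counter-rotated, the KL extraction
runs on the reoriented volume, and the pre-rotation is composed back into
the returned plane. The estimate only needs to bring the residual tilt
inside the base method's ±27° range, which is why the method keeps working
to 50° yaw. Volumes without a bright shell raise an error directing the
caller to the plain KL path.

Numerical behaviour worth knowing: at sagittal voxel sizes of 2 mm and
above, the plane's *offset* can lock onto a fissure wall within ~2.5 mm on
some noise realizations (the fissure is then sub-voxel); the angular
estimate is unaffected. Angular accuracy on 1.5 mm phantoms is typically
0.1–0.9° across rotations up to 25°.

# Ellipse mapping and the piecewise-linear transform

The cortex outline is taken from a 10 mm maximum-intensity-projection slab
around the MSP: background and skull are removed by two-stage thresholding
(air split, then Otsu between CSF and tissue), the largest component is
kept, and the boundary is traced at subpixel accuracy with `contourLines`
at the threshold level — keeping a 2-pixel halo of original intensities so
the contour interpolates along the true edge ramp rather than a truncated
one (zeroing at the component edge biases the outline ~0.4 mm inwards,
which is a 1% scale error on the transform).

The direct least-squares conic fit (ellipse-constrained) converts ~128
evenly spaced boundary fiducials into centre, semi-axes and orientation.
Landmarks are placed at fixed fractions of the fitted axes; the fractions
are exact ratios of the normalized space's geometry (e.g. the AC sits
16/86 of the semi-major axis anterior to the ellipse centre), so the
construction reproduces the stored atlas landmarks on the atlas ellipse by
definition — that calibration is itself a test. The lateral L/R landmarks
cannot come from the midsagittal image; they are the maximal lateral
extents of the 3D brain mask (the classical definition of the cortical L/R
landmarks; measuring them at the AC-PC axial level instead would
systematically underestimate the brain's half-width on any head whose
widest level is not the AC-PC plane).

The piecewise-linear transform subdivides the bounding box at the landmark
planes: 2 lateral x 3 anterior-posterior x 2 vertical slabs = 12 cuboidal
regions with 13 degrees of freedom (7 scales + 3 translations + 3
orientation); the extended form splits the vertical slabs at the
corpus-callosum top and orbito-frontal floor, giving 24 regions and 15
degrees of freedom. The mapping is separable per axis and continuous across
shared planes; half-open cuboids make region membership unambiguous.
`apply_to_points` clamps out-of-box points (with a warning), which is the
robust choice when mapping user-supplied coordinates; label resampling
instead *extrapolates* linearly with the edge slab's scale, because
clamping would smear boundary labels onto every grid point beyond the
cortex. Labels are pulled with nearest-neighbour sampling; intensities,
when needed, with trilinear interpolation.

When the extracted MSP is tilted more than 2° the scan is reoriented (the
minimal rotation taking the x axis onto the plane normal) before the
MIP/outline/landmark stages, and the returned transform composes that
rotation, so individualized atlases remain mirror-consistent about the
extracted plane on rotated scans. The plane itself is never re-extracted on
the reoriented volume: the base KL extraction is accurate (offset included)
up to ~25° on the original volume, and every resampling pass smears the
sub-voxel midline structures that the offset estimate depends on; the
skull-fit path is selected only when a cheap pose estimate exceeds 25°.

# Detection, quantification, thrombolysis

`detect_stroke` compares every lateralized label pair (anatomy and
territory atlases, paired through the legend's mirror codes) on the
CSF-removed scan. A pair is mismatched when |Δmean| > 6, |ΔSD| > 6 or
|Δpeak| > 0.05 on the 8-bit scale (64-bin normalized histograms, population
SD). The defaults were chosen so a symmetric phantom at the default noise
level produces no findings while a large territorial infarct (≈15% of its
territory's volume) trips the SD and peak conditions; they are deliberately
user-settable, since the boundary between normality and pathology is an
operating point, not a constant. Two robustness guards matter in practice:

* voxels within 5 mm of the MSP are excluded from the paired statistics —
  midline structures (falx, interhemispheric CSF) belong to neither
  hemisphere and would register as spurious asymmetry under any small
  plane-localization error;
* pairs whose ROIs were mostly removed by the CSF mask carry only boundary
  voxels and are skipped, and ventricle-dominated labels are excluded
  outright (CSF spaces are not parenchyma);
* the reference "normal tissue" mode of a pair's histograms is taken where
  *both* sides carry mass, so a lesion occupying most of its ROI is not
  mistaken for the tissue peak.

The affected side and lesion contrast are attributed from the tails of the
paired histograms (excess low-intensity mass = hypodense/infarct evidence,
excess high = hyperdense/hemorrhage), with a secondary attribution when the
opposite tail's excess is at least 35% of the dominant one (a hyperdense
core inside a hypodense lesion). The diagnosis upgrades to hemorrhagic
transformation when hyperdense evidence falls within 3 mm of infarct
evidence; the category is standard, the overlap rule is this package's
choice.

`quantify_roi` tallies per-structure volume (cm^3) and percent occupancy of
a lesion ROI. `assess_thrombolysis` computes all volumes and ratios in 3D:
infarct/territory ratios on the infarct's majority side (MCA with terminal
and penetrating sub-ratios, ACA, PCA) and the penumbra/infarct mismatch
ratio, with strict `>` comparisons against the 1/3 and 1/2 thresholds.

# Lesion segmentation

* **WMH**: a voxel is WMH iff its intensity lies in the configured range in
  all three of T1/T2/PD (intersection semantics). Ranges are user-set from
  the known bright/iso/dark behaviour; on the phantom, ranges halfway
  between the WMH and surrounding-tissue means recover the planted loci
  completely. Quantification labels 26-connected components and measures
  exact Euclidean distances to the ventricular surface (boundary voxels of
  the mask); the periventricular flag uses a configurable 10 mm cut-off.
* **CT brain extraction**: the skull shell is thresholded at the lower
  shoulder of its intensity mode; the shell's filled interior (minus a
  1.5-voxel inner margin that removes the partial-volume rim) is intersected
  with a CSF-excluding threshold; the largest component is closed
  morphologically (reabsorbing the fissure) and holes are filled
  (recovering the ventricles).
* **CSF removal**: confined to the dilated individualized ventricular
  template; the CSF/tissue threshold is Otsu within the template ROI, and
  nothing is removed unless the split is genuinely bimodal (means separated
  by at least 3 pooled SDs) — otherwise a template lying in uniform tissue
  would carve away half its voxels.
* **DWI lesions**: left/right hemisphere PDFs on shared bins (robust range,
  smoothing 1e-6); bins with a side ratio >= 3 are flagged; flagged-side
  voxels in flagged bins are cleaned by a one-voxel opening and a 1 ml
  minimum component volume. The ratio threshold, bin count and cleanup are
  engineering defaults (the method statement fixes only the measure); the
  segmentation is invariant to global affine intensity rescaling because
  the bin edges are computed from the data's own robust range.

# Probabilistic stroke atlas

`build_psa` normalizes each case's lesion contours into the standard space
(identity for cohorts generated there; the inverse of a stored
atlas-to-scan transform; or the full ellipse pipeline when only a scan is
available) and aggregates the case's parameter value into every ROI voxel.
Eight aggregation schemes are registered: `mean_global_n` (divide by the
total case count — the literal reading of "divide by the number of cases"),
`mean_coverage` (divide by per-voxel coverage), `median`, 20% trimmed mean,
`min`, `max`, a lesion-size-weighted mean, and the raw sum. Both mean
readings are provided because the phrase is ambiguous; `mean_coverage` is
the default for prediction since the global-N variant shrinks values toward
zero wherever coverage is sparse. Averaging aggregations extend
incrementally (`psa_add_case`), which equals a batch rebuild exactly.

Constrained instances (`constrain_cases`) split each selection variable
into quantile ranges (quartiles by default, half-open, computed on the
cohort excluding the target) and keep the cases sharing the target's range;
the target itself is always excluded (leave-one-out). Prediction reads the
PSA values at the ROI's covered voxels and reports mean, population SD and
the 25/50/75 percentiles. `loo_evaluate` wires these together and reports
mean absolute errors; `enumerate_design` reproduces the combinatorics of a
full design (aggregations x selection ranges x parameters x cases).

The PSA grid defaults to the normalized space at 2 mm; the evaluation
helpers accept any grid prototype (the test suite uses 4 mm for speed; the
vignette-scale simulations use cohorts of 20–100 cases, which keeps a full
leave-one-out pass in seconds while still showing the error-versus-n
trend).

# The normalized space and the simplified atlases

The normalized space is a Talairach-like box: AC at the origin, PC 24 mm
posterior, cortical extents x ±68, y +70/−102, z +74/−44 mm, extended
landmarks at z = +36 (corpus-callosum top) and z = −16 (orbito-frontal
floor); the brain ellipsoid has centre (0, −16, 15) and semi-axes
(68, 86, 59). The default grid is 2 mm isotropic with an even sagittal
dimension, so no voxel sits on x = 0 and every lateralized label has an
exact mirror voxel — left-right exactness is load-bearing for detection,
clinical fidelity of the parcel shapes is not. Per hemisphere the anatomy
atlas carries eight parcels (frontal/parietal/temporal/occipital blocks,
deep gray, white matter, ventricle, brainstem-cerebellum) and the territory
atlas four (ACA, MCA terminal, MCA penetrating, PCA), built from planar and
ellipsoidal surfaces that depend on |x| only and tile the brain exactly.
The ventricle parcels follow the phantom's ventricle geometry expressed as
fractions of the brain semi-axes, so individualized templates land on
phantom ventricles.

# Known limitations

* The MSP offset (not angle) can lock onto a fissure wall within ~2.5 mm at
  sagittal voxel sizes >= 2 mm.
* Landmark estimation assumes a roughly axis-aligned head after the MSP
  reorientation; residual pitch is absorbed by the ellipse orientation only
  approximately.
* The simplified atlas geometry is procedural; structure names are
  positional conventions, not anatomy.
* Detection attributes one contrast per histogram tail per label pair; two
  same-contrast lesions in mirror-image positions cancel (as they would for
  any pure asymmetry method).
* The cohort generator couples outcomes to lesion centroid and volume only;
  no interaction terms, no censoring, no missing data.
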