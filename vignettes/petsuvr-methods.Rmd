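---
title: "Methods: cortical SUVr quantification and its phantom validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cortical SUVr quantification and its phantom validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, numerical choices and design decisions
behind `petsuvr`, in the spirit of a methods section: what is computed, under
which assumptions, and what the phantom validation does and does not show.

## The quantity of interest

All pipelines report the regional standard uptake value ratio

$$\mathrm{SUVr}(r) \;=\; \frac{\overline{\mathrm{SUV}}_r}{\overline{\mathrm{SUV}}_{\mathrm{cerebellum}\setminus\mathrm{vermis}}}$$

the mean tracer intensity over a report region divided by the mean over the
whole cerebellum with the vermis excluded. Because injected dose and body
weight enter numerator and denominator identically, raw image intensities
stand in for calibrated SUV without loss; `normalize_suvr()` therefore never
applies dose/weight scaling and the tables label the numerator column
`mean_suv` in raw intensity units. The cerebellar reference is deliberately
*not* grey-matter masked (whole cerebellum minus vermis); the grey-matter
restriction applies to the cortical target regions only.

The ten report regions are a global cortex, the five lobes (frontal,
temporal, insular, parietal, occipital) and four regions of interest
(orbitofrontal, anterior cingulate, posterior cingulate, precuneus). In the
shipped `region_scheme()` the ROIs are subsets of their anatomical lobes
(orbitofrontal and anterior cingulate within frontal; posterior cingulate
and precuneus within parietal), so the five lobes tile the global cortex
exactly. *Global* is defined as the voxel union of all cortical member
labels — the mean over all cortical voxels — not the mean of the regional
means; both readings of "mean global SUV" are defensible, and the
voxel-union one was chosen because it is the one that corresponds to a
measurable region. The label-to-region table is an editable JSON config
(`read_region_scheme()`), so a real anatomical atlas and the phantom
parcellation run through one code path.

## The two routes

**Route 1 (template space).** The subject PET is registered onto a tracer
template with a 12-degree-of-freedom affine transform and trilinear
interpolation, then sampled on the template grid. The template-space atlas
is restricted to a grey-matter probability mask binarised at threshold 0.3
with a *strict* inequality (a voxel is kept only if $p > 0.3$); regional
means and the cerebellar normalisation follow.

**Route 2 (subject space).** The CT acquired together with the PET (hybrid
scanner, shared grid) is registered onto the subject's T1; the recovered
transform carries the PET into T1 space. Grey matter is segmented from the
T1 itself and binarised at the same 0.3 threshold. The atlas reaches
subject space through the *inverse* of the T1-to-template transform.
Quantification happens entirely on the T1 grid: the methodological point of
the subject-space route is that PET data are never warped into a group
space. PET-CT co-registration at acquisition is assumed; an extra PET-to-CT
rigid step can be added by registering those volumes explicitly if a
dataset requires it.

Both drivers log per-stage voxel counts, and can write every transform,
mask and intermediate volume to an audit directory.

## Registration

`register_affine()` is an intensity-based affine registration:

* **Parameterisation.** 12 parameters — 3 translations (mm), 3 rotations
  (radians, applied x then y then z), 3 scales, 3 shears — composed in the
  fixed order translation ∘ rotation ∘ scale/shear. The decomposition of a
  matrix back into parameters uses the QR factorisation with positive
  diagonal, and round-trips to 1e-9.
* **Cost functions.** `correlation_ratio` (variance of the moving image
  conditioned on 32 intensity bins of the fixed image) for cross-modal
  pairs (CT→T1, PET→template); `normalized_correlation` for same-modality
  pairs; `mean_squares` for completeness. Costs are evaluated on the voxels
  where the back-projected moving image lands inside its field of view,
  with a penalty discouraging solutions that shrink the overlap below half.
* **Search.** Derivative-free Nelder-Mead descent inside a 3-level
  multi-resolution pyramid (smooth + subsample ×4, ×2, ×1; 200 iterations
  per level; parameter scaling 1 mm ≈ 0.02 rad ≈ 0.02 scale/shear units),
  initialised at the centre-of-mass alignment, plus one simplex restart at
  full resolution. Degrees of freedom are released progressively — rigid at
  the coarsest level, scales at the middle, shears only at full resolution.
  This matters: a near-ellipsoidal object is invariant under a family of
  rotation-plus-shear maps, and releasing all 12 parameters at a blurred
  coarse level lets the search wander into that family. A final safeguard
  re-optimises from the initialisation if the pyramid ever ends above the
  initial full-resolution cost, so the returned transform never degrades
  the cost. The whole search is deterministic for fixed inputs.

Label images are never interpolated as intensities: `transform_labels()`
resamples each label's indicator trilinearly and re-binarises at weight
0.5, resolving overlaps by the larger weight — this follows the
trilinear-then-binarise convention of the quantification protocol and
cannot invent labels absent from the input.

## Tissue segmentation

`segment_tissues()` is deliberately simple: a 3-class Gaussian mixture
(`mclust`, model "V") over the T1 intensities inside an automatic brain
mask (voxels above 18% of the 99.5th percentile), fitted on a deterministic
stride subsample of at most 20 000 voxels, with posteriors evaluated at
every brain voxel. Classes are identified by mean-intensity rank (CSF < GM
< WM), making the labelling deterministic. If the mixture EM degenerates —
as it does on noiseless data with exact class intensities — a 3-means
fallback with variance floors produces the same soft-posterior interface.
This is an intensity-only stand-in for full anatomical segmentation
pipelines (no spatial priors, no MRF regularisation, no subcortical shape
models); its fidelity target is the phantom's ground truth, not the output
of any specific neuroimaging tool. On real data it would under-perform
dedicated tools near intensity inhomogeneities.

## Statistics

* **Route comparison (within group):** paired two-sided t test on the
  route-1 minus route-2 differences per region.
* **Group comparison (per route):** Welch's unequal-variance t test by
  default. The protocol sentence describing both comparisons names a paired
  test, but patients (n = 22) and controls (n = 17) cannot be paired;
  Welch is the defensible reading for the between-group case, and the
  pooled-variance Student test is available via `var_equal = TRUE`.
* **Multiplicity:** Holm's step-down procedure across the ten regions of
  one comparison family (one family per group or per route). The family
  definition is a choice; applying it per comparison family of ten regions
  is the default and the alternative (regions × routes jointly) can be had
  by adjusting the returned raw p values directly.
* **Effect sizes:** Cohen's d with sample-size-weighted pooled SD. "Weighted
  by sample size" is ambiguous between n and n−1 weights; the standard
  pooled estimator ((n−1)-weights) is the default, n-weighting is a flag.
* **ROC:** empirical curve over all observed thresholds with `score ≥ t`
  called positive; AUC by trapezoid, which equals the concordant-pair count
  with ties at half weight (Mann-Whitney identity — tested against
  exhaustive pair counting). The optimal cut-off maximises Youden's J;
  ties break toward the lower cut-off, i.e. toward sensitivity.
* **Signal detection:** d′ = z(H) − z(F), C = −(z(H)+z(F))/2 with `qnorm`
  as the quantile. Rates of exactly 0 or 1 are rejected unless the 1/(2n)
  count correction is requested; the published operating points never touch
  the boundary, so the worked examples are correction-free.
* Degenerate inputs (zero-variance differences) are reported as
  p = machine floor with a warning rather than an error, so screening runs
  on constant columns fail soft.

## The phantom: what it emulates

`make_subject()` builds a geometric head: nested ellipsoids (skull shell,
CSF shell, 9 mm cortical grey-matter ribbon, white-matter core with paired
CSF lateral ventricles) over a posterior-inferior cerebellar compartment
with a midline vermis slab. The cortical ribbon is divided into nine
sectors by simple coordinate rules; the posterior cingulate sector sits
medially against the white-matter core, so spill-over tests can target it.
The head is ~9 cm across — a scaled-down brain on the true acquisition
grids (T1 1 mm isotropic, PET/CT 1 × 1 × 1.5 mm). Tissue intensities are
class-constant (T1: CSF 30 < GM 70 < WM 110; CT skull-dominated with weak
GM/WM contrast), PET uptake is ratio × cerebellar level with nonspecific
white-matter binding (default WM:cerebellum = 1.6, CSF = 0.3), blurred by
a 5 mm FWHM Gaussian PSF and degraded with Gaussian noise (default SD 5% of
the cerebellar level). CT and PET live on a grid displaced by a known
affine misalignment from the T1, and the whole subject is displaced from
template space by a second known affine (default: mm-scale translations,
1.5–2° rotations, 2–3% scales). Everything is deterministic under the
spec's seed, to the byte.

Default cortical ratios follow the published cognitively-normal
subject-space profile (global ≈ 1.18, posterior cingulate 1.36, …);
`make_cohort()` draws per-subject ratios from the published group profiles
(`table2_profiles()`), truncated at 0.5, and returns the generating truth
table alongside the subjects. For purely statistical properties
(`build_volumes = FALSE`) only the truth table is produced, which is
distributionally identical and cheap.

Design choices worth stating:

* **Geometry was tuned once, against the blur-limited truth-mask case.**
  With a 5 mm PSF, an infinitely thin cortex cannot be recovered to ±0.05;
  the ribbon thickness (9 mm), sector boundaries and the cerebellum's
  placement against cerebral white matter (so reference spill roughly
  cancels) were chosen so that truth-mask quantification of the blurred
  phantom stays within ±0.04 of the generating ratios. These are properties
  of the phantom, not of the pipelines under test.
* **Ventricles are load-bearing for registration.** Without internal
  asymmetric structure, a 12-DOF registration of near-ellipsoidal images is
  ill-posed (rotation is exchangeable with shear along the ellipsoid's
  self-map family). The paired lateral ventricles anchor all three
  rotations, as they do in real images.
* **Two template grey-matter maps.** `make_template()` returns the
  canonical (matched) map and a population-average map (canonical GM
  smoothed by 8 mm FWHM, clipped to [0, 1]). Parameter-recovery validation
  uses the matched map — it asks whether the pipeline machinery loses
  information. The mechanism demonstration uses the population map — it
  asks what a mismatched mask does under elevated white-matter binding. A
  single map cannot serve both questions, because with WM binding at 1.6
  the mask mismatch *alone* biases thin regions by up to +0.1: that bias is
  the phenomenon, not a pipeline defect.
* **The template-space atlas extends ~3 mm into subjacent white matter**,
  as anatomical parcellations do; the grey-matter mask, not the atlas
  boundary, decides what is quantified. This is what makes the mask
  mismatch mechanism expressible at all.

## What passing tests show — and do not show

The suite validates, on phantoms: ±0.05 (route 1) and ±0.07 (route 2)
recovery of the generating regional ratios through the full pipelines under
default noise and misalignment; 12-DOF transform recovery to 0.5 mm/0.5°
(1 mm/1° cross-modal); the directional mechanism that a population mask
plus white-matter binding inflates template-style global SUVr while
subject-specific masking stays nearer truth; exact agreement of every
statistic with independent oracles; ≥90% Holm-corrected power to detect the
published group separation over 500 simulated cohorts; and byte-level
determinism of the command-line pipelines at fixed seed.

The phantom is geometric, not anatomical: no gyrification, no partial
intensity inhomogeneity, no MR bias fields, no reconstruction artefacts, no
inter-subject anatomical variability beyond an affine map. Passing these
tests therefore demonstrates the correctness of the algorithms and the
plausibility of the mechanism — it does not certify accuracy on clinical
images, where segmentation and registration face conditions the phantom
does not emulate.

## Problem sizes and numerical details

The default phantom is 80 × 96 × 80 voxels (T1) and 80 × 96 × 53 (PET/CT);
tests and examples use one to two subjects per pipeline run and
`build_volumes = FALSE` cohorts for statistical properties, with a
half-scale phantom (`scale = 0.5`) in the command-line integration checks.
Interpolation is trilinear with zero fill outside the field of view
(out-of-field voxels are counted); nearest-neighbour is available for label
data, though `transform_labels()` is preferred. The Gaussian PSF kernel is
renormalised at grid boundaries, conserving total signal to well under
0.5% away from hard edges. Probability maps tolerate 1e-6 numerical slack
at the [0, 1] boundaries; binary masks are strictly {0, 1}. All error
conditions raise classed conditions (`petsuvr_error_*`), which the CLI maps
to exit codes (1 usage, 2 data/processing).
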