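---
title: "Knowledge-based linear registration with mediator libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-based linear registration with mediator libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(medbridge)
```

## The problem

Linear (affine) registration of a T1-weighted head image into a template
space such as MNI is the first step of almost every brain-imaging pipeline,
and it fails more often than its mathematical simplicity suggests. Clinical
acquisitions — sagittal protocols with large fields of view, neck and
shoulder tissue in frame, highly variable head position and orientation —
give intensity-based optimizers many ways to lock onto the wrong optimum.

`medbridge` implements a knowledge-based remedy: instead of registering a
subject directly to the template, register it to each member of a *mediator
library* — a curated collection of head images whose own affine transforms
into the template space are already known and quality-verified. If the
subject registers well to some mediator *m*, the composition

subject &rarr; m &rarr; template

is typically far more reliable than the direct subject &rarr; template
registration, because subject and mediator can share field of view, contrast
and head pose in a way the subject and template do not. The library only has
to be built once; afterwards every new subject reuses it.

## Transforms and their convention

All transforms are 12-parameter affines acting on world coordinates (RAS+
millimetres, taken from the NIfTI mapping) — never on raw voxel indices, so
mixed fields of view and anisotropic voxels need no special handling. A
transform labelled `a -> b` is stored in the *pull-back* (resampling)
convention: it maps a world point expressed in space `b` to the
corresponding point in space `a`. Two consequences:

* resampling image `a` onto grid `b` evaluates `a` at the pulled-back points
  (`resample()`), and
* the chain `a -> b` then `b -> c` is the plain matrix product of the two
  4x4 matrices (`compose_affine()`), which is exactly the composition the
  mediator workflow needs.

The 12 parameters are rotations (degrees, intrinsic Z-Y-X), translations
(mm, applied last), scales and shears (unit upper-triangular factor, applied
first). The decomposition is unique — and `affine_params_from_matrix()` an
exact round-trip — for positive scales and rotations inside (-90, 90)
degrees, which covers every transform this workflow produces.

## The registration engine

`register_affine()` minimizes the ratio-image-uniformity (RIU) cost: the
coefficient of variation sd(r)/mean(r) of the voxelwise ratio r =
fixed/moving over the overlap domain. RIU is zero exactly when the images
are proportional on the domain, which makes it insensitive to global
intensity scaling. We use the global (non-partitioned) form with the sample
(n-1) standard deviation; the overlap domain excludes air background by
thresholding both images at `intensity_floor_fraction` (default 0.05) of
their robust maximum (99th percentile) — a segmentation-free guard against
the ratio exploding on noise-level intensities.

The optimization is deliberately simple and fully deterministic:

* **Pyramid** (default factors 4, 2, 1): each level Gaussian-smooths with
  sigma = factor/2 voxels and subsamples; world-space transforms carry over
  between levels unchanged.
* **Initialization**: a center-of-mass translation is always applied first.
  The cohorts this tool targets have grossly variable head positions, and an
  identity start fails trivially.
* **Optimizer**: a Hooke-Jeeves pattern search (exploratory moves plus
  pattern extrapolation, step halving) over the 12 parameters, scaled so
  one step unit is 1 degree = 1 mm = 0.01 scale = 0.01 shear. The step
  starts at the pyramid factor and stops at `param_tolerance` (default
  0.01 units). The search is boxed to a generous plausible-pose region
  around the initialization (30 degrees, 60 mm, scales 0.6–1.4, shears
  0.2), which keeps pattern extrapolation from running out of the basin
  structure entirely. No gradients, no stochastic restarts: identical
  inputs give identical transforms.
* **Coarse-level multi-start**: the centre-of-mass initialization is
  systematically biased along the inferior–superior axis when the moving
  image contains neck tissue the fixed image lacks. The coarsest level
  therefore probes three deterministic starts — the centre-of-mass
  translation and z-offsets of +-20 mm — and keeps the lowest-cost basin
  before refining.
* **Degree-of-freedom schedule**: the coarsest level optimizes only
  rotations, translations and scales; shears join at the finer levels. On
  smooth, nearly ellipsoidal heads a full-DOF coarse search can trade a
  rotation against a shear and settle in a compensated optimum; deferring
  shear until the finer structure is visible removes that failure mode.
* **Conditioning**: rotations/scales/shears are parametrized about the fixed
  image's intensity centroid internally; the returned transform is
  re-decomposed into canonical origin-centred parameters.

If no pyramid level improves on the initialization cost, the initialization
itself is returned with `converged = FALSE` and a warning. Note this also
happens when the initialization is already optimal (registering an image to
an exact copy of itself), in which case the returned transform is simply
correct.

## Selecting the best mediator

After registering the subject to every mediator, one candidate must be
chosen. Scores are computed on each mediator's grid — the subject is
resampled onto the mediator — with out-of-field voxels set to zero, so poor
overlap is penalized rather than hidden:

* **SSD** (select the minimum): sum of squared intensity differences over
  the whole grid. Because SSD is meaningless across different intensity
  scales, the mediator is first histogram-matched to the registered subject
  (256-level quantile mapping, `histogram_match()`).
* **MI** (select the maximum): mutual information from a 64 x 64-bin joint
  histogram, in bits, with no intensity normalization. Raw MI is unbounded
  above (self-MI equals the marginal entropy), but selection only uses the
  argmax, which any monotone normalization leaves unchanged.
* **Oracle Dice** (select the maximum): when the subject's brain mask is
  available, the Dice overlap of that mask — carried through each composed
  transform — against the template mask identifies the *true* best mediator.
  This is an upper bound used for evaluation, not a practical criterion:
  real subjects do not arrive with template-space masks.

Ties break toward the earlier library entry, for determinism. Candidate
registrations are independent of one another, so they may be executed
concurrently without changing any result; the implementation runs them
sequentially.

## Evaluation

Registration quality is measured as the Dice coefficient
2|X&cap;Y|/(|X|+|Y|) between binary brain masks (grey matter + white matter
+ ventricles) in template space, with Dice > 0.85 conventionally counted as
a successful alignment. Masks are always resampled with nearest-neighbour
interpolation so their value set stays exactly {0, 1}; trilinear
interpolation plus re-thresholding would blur the boundary and make Dice
depend on the threshold.

## Shrinking the library

A library of N mediators costs N registrations per subject. Mediators that
register to each other accurately carry redundant geometric information, so
the library can be compressed: `build_similarity_matrix()` registers every
ordered mediator pair, histogram-matches, records SSD, and averages the two
directions (the two directed registrations differ in general; averaging is
the symmetrization with no extra machinery). `cluster_library()` runs
complete-linkage agglomerative clustering on this dissimilarity matrix —
complete linkage being the default of the heatmap-clustering tool named in
the original analysis — and cuts the dendrogram at the requested k; cutting
one tree guarantees nested partitions across k. Each cluster is represented
by its **medoid**, the member with the smallest summed dissimilarity to its
co-members, which is deterministic and needs no further registrations. A
failed pairwise registration is recorded and imputed as its row maximum,
i.e. treated as maximally dissimilar.

## The synthetic phantom cohort

Everything above is exercised end-to-end without any external data by the
phantom module. `make_canonical_brain()` builds a T1-like head on a 96^3
grid of 2 mm voxels (a scale at which a full multi-mediator experiment runs
in minutes on one core; the grid is a parameter, not a constant): nested
compartments — bright white-matter core, grey-matter shell, dark CSF rim,
skull shell — on ellipsoidal surfaces, plus deliberately *asymmetric*
interior anatomy: unequal lateral ventricles, a cerebellum-like
posterior-inferior lobe and a brainstem column. The asymmetry matters: a
plain nested-ellipsoid head is nearly invariant under certain
rotation-shear-scale combinations, and a registration can land in such a
compensated optimum with excellent mask overlap but a wrong transform. Real
brains do not have that degeneracy, and a phantom that is to validate
transform recovery must not have it either.

Per-seed anatomy jitter (axis lengths +-10%, low-order directional surface
harmonics) gives every seed a distinct shape. `perturb()` then applies an
exact affine pose (the stored ground truth), optionally pads the field of
view inferiorly with a high-intensity neck block — emulating the sagittal
acquisitions that make direct registration hard — and adds a seeded smooth
multiplicative bias field and Gaussian noise (defaults: sigma 2 on tissue
intensities of 30-120, bias amplitude 0.1). Gaussian rather than Rician
noise is a deliberate simplification; no MR-physics fidelity is claimed.

`make_cohort()` assembles the study design: the canonical space is the
template; each mediator is a distinct-anatomy phantom under a random pose
(rotations +-10 degrees, translations +-15 mm, scales 0.9-1.1, shears
+-0.05) whose exact inverse-pose transform plays the pre-determined
mediator-to-template matrix; each subject re-perturbs a designated
mediator's sample (same anatomy, additional pose and noise), and the
designation is recorded. Selection criteria can therefore be scored against
the generating mediator, and Dice against ground truth.

What passing these tests shows — and what it does not: the synthetic cohort
has exactly affine geometric variability between subject and mediator, so a
perfect registration engine can in principle recover poses exactly. Real
anatomies differ non-linearly; there the best achievable cross-subject Dice
plateaus around 0.90-0.97 regardless of the linear engine. The phantom
cohort reproduces that plateau only partially (through anatomy differences
between subject and template), so absolute Dice values here are not
forecasts for clinical data; orderings (oracle >= criterion-based >= worst
fixed mediator; degradation under library shrinkage) are the meaningful
outcomes.

## Numerical choices and degenerate inputs

* Trilinear interpolation everywhere for images; points outside the moving
  grid contribute 0. At exact lattice points interpolation is exact.
* The RIU overlap domain must contain at least max(32, 0.1%) of the fixed
  grid during optimization; smaller overlaps score a large penalty so the
  search retreats rather than collapsing the domain.
* Histogram matching collapses duplicated source quantiles to keep the
  mapping single-valued and monotone; constant images are rejected.
* MI bins are equal-width over each image's own [min, max]; a constant
  image lands in one bin and contributes zero entropy.
* Dice on two empty masks is an error, not 0/0.
* `cluster_library()` breaks medoid ties toward the lexicographically
  lowest id; `hclust` tie behaviour is fixed by R itself, so results are
  reproducible.
* All randomness in the phantom module flows from explicit seeds through a
  local RNG scope that neither reads nor disturbs the caller's random
  state.

## Known limitations

* The registration engine is a benchmark-grade affine tool: no non-linear
  refinement, no gradient-based optimizer, no multi-start. It is meant to
  make the mediator framework testable, not to compete with production
  registration suites.
* SSD/MI selection scores are computed on the mediator's grid following the
  subject-to-mediator registration; computing them on the subject's grid
  would be an equally defensible reading and may rank borderline candidates
  differently.
* The similarity matrix costs N(N-1) registrations; for large libraries the
  pairwise registrations dominate everything else in the package.
* Analyze-format (.hdr/.img), DICOM and 4D inputs are out of scope; NIfTI-1
  only.
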