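---
title: "Detecting and removing blood-flow artifacts in T1-weighted MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and removing blood-flow artifacts in T1-weighted MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

T1-weighted brain scans acquired without effective blood suppression show
bright tubular signal where blood flows — along the superior sagittal and
transverse sinuses, in the Sylvian and longitudinal fissures, and in
inferior regions. A T1 template built from blood-suppressed data is dark in
those places. The conflict misleads every similarity-driven step of a
standard morphometry pipeline: brain extraction drags extra voxels into the
mask where an artifact rides the brain surface, and registration — linear
and nonlinear — trades alignment of true anatomy against alignment of
artifact with gyri.

`deblood` implements a conservative heuristic pipeline that (i) identifies
artifact voxels from four independent lines of evidence, (ii) replaces them
with the subject's mean CSF intensity ("deblooding", mimicking what a
working blood-suppression sequence would have produced), and (iii)
quantifies how much the artifacts bent registration, via Dice overlap of
brain masks, mutual-information (MI) similarity, and the Jacobian
determinant and displacement magnitude of the deformation connecting the
two registrations.

## The detection model

All detection happens in subject space on the bias-corrected,
intensity-normalised scan. The four heuristics, each a necessary condition:

1. **Blood prior.** A blood probability map (BPM) is built in template
   space by averaging co-registered MR-angiography volumes and normalising
   by the global maximum. A voxel is an artifact candidate only where the
   BPM (resampled through the current subject-to-template affine) reaches
   `expansion_prob_threshold` (default 0.1, the published bloodless-mask
   operating point).
2. **Bright and outside the main white matter.** Tissue classification is a
   3-component Gaussian mixture over masked intensities (EM, deterministic
   quantile initialisation, components ordered so CSF < GM < WM). Bright
   artifact voxels land in the top component, i.e. are labelled WM. WM
   voxels are grouped by 26-connectivity; true white matter forms one large
   group, so WM-labelled voxels *outside* the main group are suspicious.
3. **Edges the template does not have.** Gradient-magnitude maps (Gaussian
   FWHM 1 mm) of subject and template are subtracted (template map
   resampled into subject space) and the difference blurred at FWHM 2 mm.
   Candidates must reach the `expansion_graddiff_percentile`-th percentile
   (default 90) of this map within the brain mask. The percentile adapts
   the "relatively high gradient" notion to each scan's contrast.
4. **Vascular continuity.** Blood is not isolated voxels. Seeds satisfying
   (1)-(3) are grown by iterative 6-connected dilation, newly reached
   voxels being accepted only if they also satisfy (1)-(3), to a fixed
   point (cap `expansion_max_iters`, default 10).

Two refinements follow. The subject's brain mask minus the current blood
mask re-drives the affine registration, sharpening the BPM alignment; main
white-matter-group voxels with BPM at or above the major-vessel threshold
(0.2) and a passing gradient gate are then recovered — vessels wrapping the
corpus callosum get merged into the main WM group and are otherwise
unreachable. Finally, the brain-mask periphery is trimmed: a morphological
opening (26-connected, 4 erosion passes and 5 dilation passes — the extra
dilation compensates the opening's undershoot on curved surfaces)
reconstructs the smooth artifact-free brain surface, and blood voxels
outside the opened mask — surface bumps dragged in by bright artifacts —
are removed. On phantoms this removes protruding artifact voxels only,
never brain-interior voxels. Blood voxels deep inside the brain stay in
the mask: after deblooding they are CSF-like brain-interior voxels. The
deblooded scan finally receives its own brain mask by re-running
extraction on it (at the corrected scan's foreground threshold, since both
versions share one intensity scale): with the artifacts suppressed,
extraction recovers the clean envelope, which is the mask the evaluation
transforms are applied to.

The design goal is conservativeness: a missed vessel voxel mildly perturbs
registration, but relabelling true white matter as CSF is catastrophic.
Every stage therefore requires the conjunction of all available evidence,
and on phantom data the pipeline is validated to place **zero** blood-mask
voxels inside the true main white-matter body.

## Replacement

The blood mask is dilated (26-connected, 1 pass) and blurred (Gaussian FWHM
1.4 mm), giving weights $w \in [0,1]$; the deblooded scan is the convex
blend $t_1 (1-w) + \overline{\mathrm{CSF}}\, w$, with
$\overline{\mathrm{CSF}}$ the mean intensity over CSF-labelled voxels.
These defaults are the smallest halo that still saturates ($w \ge 0.99$) on
the blood voxels themselves: the 26-connected (cube) dilation is used
because an equally-sized 6-connected margin leaves corner paths through
which the blur sees exterior zeros, and wider halos measurably degrade
registration of the deblooded scan by blending CSF intensity into
surrounding grey matter. Outside the trimmed brain mask the pipeline
suppresses artifact signal toward background instead of CSF — suppressed
flowing blood carries no signal, and there is no CSF compartment beyond the
brain boundary.

## Registration

Affine registration maximises histogram MI (`mi_bins`, default 64 at full
resolution, proportionally fewer at coarse levels) over voxels inside the
fixed mask, with a deterministic coordinate pattern search over 9
parameters (translation, rotation, anisotropic scale about the masked
centre of mass) across a 3-level pyramid (shrink 4/2/1). Nonlinear
registration is a multiresolution demons scheme: intensity-difference
forces along the warped-image gradient, Gaussian-smoothed updates ("fluid",
1 voxel), Gaussian smoothing of the accumulated field ("diffusion", 1
voxel), per-iteration step cap of 1 voxel, and extra smoothing until the
analytic Jacobian determinant of $x + u(x)$ is positive everywhere. A final
gate returns the initial transform if MI did not improve, so completed
registrations never lose similarity. Determinism: the optimiser has no
stochastic component; the `rng_seed` in the configuration is threaded to
the stages that sample (classification interface, phantom generation).

Transforms follow the resampling convention of the major registration
toolkits: the affine matrix maps moving-space world points to fixed-space
world points, the deformation field stores pull-back displacements on the
fixed grid, and resampling evaluates the moving image at
$A^{-1}(x + u(x))$. The Jacobian and displacement analyses read the field
directly as $\varphi(x) = x + u(x)$, deliberately excluding the affine
part: a global affine would add a constant to every voxel of the map,
whereas the quantity of interest is the local, artifact-driven distortion.

## Impact analysis

For each subject, the corrected bloody scan and the deblooded scan each
drive a linear and a linear-plus-nonlinear registration to the template.
Both arms start from the same initial transform (the pipeline's final
subject-to-template affine): with independent starts, the two pattern
searches take different coarse-level paths and the resulting Dice jitter
obscures the systematic artifact effect; with a common start the arms
differ only through the artifacts' pull on the similarity optimum, which
is the quantity under study. Both arms are treated identically.
Each transform is applied to the *deblooded* scan (so only the transforms
are compared) and to the corresponding brain mask. Dice of the transformed
mask against the template mask and MI of the transformed scan against the
template give 8 per-subject scores; cohort means, variances, and two-tailed
paired t-tests make the four-row summary. Registering the
bloody-transformed volume onto the deblooded-transformed volume and taking
voxelwise cohort maxima of |Jacobian| and displacement magnitude localises
where artifacts bend the warp; overlays threshold these at 2 (unitless) and
5 (interpreted as millimetres).

Histogram-MI values depend on the estimator (bin count, masking), so
absolute MI is not comparable across implementations; only the
bloody-versus-deblooded ordering is meaningful, and that is what the
package tests.

## The phantom

Real inputs (multi-site T1 data, MR angiography, a population template) are
not redistributable, so validation uses a synthetic study the package can
regenerate from a seed. The template is a nested-ellipsoid head — CSF
shell, gyrified grey-matter ribbon, white-matter core — with a longitudinal
fissure separating the hemispheres above a callosum-like bridge and two
Sylvian-like lateral clefts. The default vessel tree places artifacts where
the real data shows them and at prominent calibre: a 3 mm superior sagittal
sinus riding the brain surface (half the tube protrudes past the envelope,
so brain extraction is corrupted exactly as in the motivating data), two
3 mm transverse sinuses on the posterior-inferior surface, a 2 mm
pericallosal arc in the fissure, 2 mm Sylvian-cleft vessels, and a 2.5 mm
inferior arc. Artifact intensity is 140 against WM 100, GM 65, CSF 30.
Subjects are generated by pulling the template back through a known random
affine (translations up to 5 mm, rotations up to 5 degrees, scale within
3%) composed with a smooth random warp (peak 3 mm, verified invertible),
then multiplied by a degree-2 polynomial bias field (amplitude 10%) with
additive Gaussian noise (SD 2; a Rician option exists). MR-angiography
volumes are simulated as the tree under per-curve rigid jitter (SD 0.5 mm),
lightly blurred.

What the phantom does *not* emulate: cortical folding at realistic spatial
frequency, pulse-sequence physics, multi-site intensity differences, and
vessel trees that differ topologically between subjects. Passing tests
therefore demonstrate that the heuristics and the evaluation machinery
behave as designed under known ground truth — not clinical-grade
performance on arbitrary real data.

## Numerical choices and degenerate inputs

* FWHM-to-sigma uses $\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})$; blurs are
  separable with boundary renormalisation, so constants are preserved
  exactly.
* Threshold conventions: the bloodless mask keeps strictly-below-threshold
  voxels; binarisation keeps at-or-above voxels, so boundary values count
  as vessel (conservative toward masking).
* BPM normalisation is by the global maximum — the only reading that makes
  0.1/0.2 thresholds meaningful on a [0, 1] map. An all-zero map is
  returned unchanged rather than divided.
* Dice of two empty masks is 1 (identical masks overlap perfectly); the
  paired t-test returns $t = 0, p = 1$ for all-zero differences and
  $\pm\infty, p = 0$ for constant non-zero differences.
* Connected-component ties are broken toward the component containing the
  lowest linear voxel index; components are labelled in raster order.
* Brain extraction thresholds at 0.4 of the Otsu value: Otsu separates
  dominant bright tissue from background, and the reduced cut keeps CSF and
  its partial-volume boundary layer while remaining far above the noise
  floor.
* Bias estimation fits a degree-2 polynomial to the log intensity of the
  brightest 1D-3-means class only; fitting all tissues would absorb anatomy
  into the "bias" and distort unbiased scans.
* The one registration refinement pass mirrors the single refinement loop
  of the method; the configuration allows repeating it.

## Problem sizes

The shipped validation uses 96 voxel cubes at 1 mm: a 10-phantom cohort for
the directional registration-impact replication, 20 phantoms for the
conservativeness/sensitivity check, and 20 random affines for registration
recovery, with registration iteration caps set for desk-scale runs
(pattern-search sweeps 40/25/10, demons iterations 60/30/10). These sizes
were chosen so the full suite reproduces on a single workstation core in
minutes while leaving each effect statistically unambiguous.

## Known limitations

Absolute MI values are estimator-specific; detection thresholds
("relatively high", "bright") are config-exposed operating points, not
claims about optimality; the demons registration is a simplified in-repo
scheme, not a reimplementation of any production tool — an external
registration backend can be substituted behind the same contracts; and the
phantom's artifact prominence was chosen to match the motivating regime of
strong, widespread artifacts, so effect sizes on mildly affected data will
be smaller.
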