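# deblood

Blood-flow artifacts — bright tubular signal from unsuppressed flowing
blood — are common in legacy T1-weighted brain MRI. Against a
blood-suppressed template they create intensity conflicts that corrupt
brain extraction and pull mutual-information registration away from the
anatomically correct alignment, linearly and nonlinearly. `deblood` is an R
package for neuroimaging researchers working with such data. It:

* detects artifact voxels with a conservative four-way heuristic — a blood
  probability map built from MR angiography, tissue classification with
  white-matter connectivity grouping, a blurred subject-minus-template
  gradient-difference map, and vascular-continuity expansion by iterative
  dilation;
* replaces them with the subject's mean CSF intensity through a smooth
  dilate-and-blur weighting ("deblooding"), mimicking successful blood
  suppression;
* quantifies the artifacts' impact on template registration: Dice overlap
  of brain masks, mutual-information similarity, and cohort maximum maps of
  the absolute Jacobian determinant and displacement magnitude of the warp
  separating the bloody-driven from the deblooded-driven registration.

The key quantities: the blood probability map is the max-normalised mean of
co-registered MRA volumes, thresholded at 0.1 (bloodless registration mask)
and 0.2 (major vessels); deblooding is the convex blend
`t1 * (1 - w) + mean(CSF) * w` with `w` the blurred dilated blood mask;
masks are compared by Dice `2|A∩B| / (|A|+|B|)`; volumes by histogram
mutual information; arms by two-tailed paired t-tests; deformations by
`|det(∂φ/∂x)|` and `‖u‖` of `φ(x) = x + u(x)`.

Because the original multi-site data cannot be redistributed, the package
ships a synthetic phantom generator (`phantom_spec()`,
`generate_template()`, `generate_subject()`, `generate_mra_cohort()`) that
produces template/subject pairs with known tissue labels, vessel masks,
bias fields, noise, and known affine + nonlinear misalignments, so every
claim is tested against ground truth.

## Worked example

```r
library(deblood)

spec     <- phantom_spec(rng_seed = 1)          # 96^3, 1 mm phantom study
template <- generate_template(spec)
mra      <- generate_mra_cohort(spec, template, 5, seed = 99)
bundle   <- template_bundle(template$t1, template$brain_mask,
                            build_blood_probability_map(mra))

subject <- generate_subject(spec, template, seed = 21)
res     <- run_subject(subject$t1_bloody, bundle, bn_config())
res
#> <deblood_result> 6928 blood voxels, CSF mean 33.01

truth <- subject$truth_blood_mask$data == 1
det   <- res$blood_mask$data == 1
sum(det & truth) / sum(truth)                   # vessel sensitivity
#> [1] 0.8128858
mean(res$deblooded$data[det & subject$brain_mask$data == 1])
#> [1] 33.09977                                  # detected vessels now CSF-like
```

The pipeline found ~81% of the true artifact voxels on this subject, placed
none inside the main white-matter body (its design goal — mislabelling true
white matter as CSF would be catastrophic), and set the detected voxels to
the subject's CSF mean (33.0 in template-normalised units).

Cohort-level impact of the artifacts on registration:

```r
subjects <- simulate_cohort(spec, template, 10, seed = 1)
coh <- run_cohort(lapply(subjects, function(s) s$t1_bloody), bundle,
                  bn_config(rng_seed = 1), compute_impact = FALSE)
coh$summary[, c("metric", "bloody_mean", "deblooded_mean", "p")]
#>                    metric bloody_mean deblooded_mean            p
#> 1        linear_mask_dice   0.9713925      0.9727443 5.096159e-03
#> 2    linear_similarity_mi   0.8826886      0.8872515 8.529861e-05
#> 3     nonlinear_mask_dice   0.9682468      0.9694105 3.423072e-06
#> 4 nonlinear_similarity_mi   0.9713389      0.9778113 4.920555e-08
```

Registrations driven by the deblooded scans align better than those driven
by the original scans on all four metrics (higher Dice of the transformed
brain mask against the template mask, higher MI of the transformed
deblooded scan against the template), and the paired differences are
significant — the phantom-scale analogue of the effect measured on real
multi-site data.

## Command line

A thin CLI over the same functions lives at `inst/cli/deblood-pipeline.R`
(`phantom`, `run`, `run-cohort` subcommands) for shell-based use on NIfTI
files with a YAML/JSON config.
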