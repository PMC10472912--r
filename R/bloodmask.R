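#' Gaussian-regularised gradient magnitude
#'
#' Smooths with a Gaussian of the given FWHM, then takes the central
#' difference gradient magnitude in intensity units per mm.
#'
#' @param v a [bn_volume()].
#' @param fwhm_mm smoothing FWHM (mm), > 0.
#' @return a non-negative [bn_volume()].
#' @export
gradient_magnitude <- function(v, fwhm_mm = 1) {
  if (fwhm_mm <= 0) stop("fwhm must be positive")
  vs <- voxel_sizes(v)
  s <- smooth3d(v$data, fwhm_to_sigma(fwhm_mm), vs)
  gx <- array_deriv(s, 1, vs[1])
  gy <- array_deriv(s, 2, vs[2])
  gz <- array_deriv(s, 3, vs[3])
  bn_volume(sqrt(gx^2 + gy^2 + gz^2), v$affine)
}

#' Blurred gradient-difference map
#'
#' Subtracts the template gradient map (already resampled into subject
#' space) from the subject's, then blurs, strengthening coherent extra-edge
#' regions such as vessels and weakening incidental ones. The result may be
#' negative where template edges dominate.
#'
#' @param subj_grad subject gradient-magnitude [bn_volume()].
#' @param template_grad_in_subject template gradient map on the same grid.
#' @param blur_fwhm blur FWHM (mm).
#' @return a [bn_volume()].
#' @export
gradient_difference_map <- function(subj_grad, template_grad_in_subject,
                                    blur_fwhm = 2) {
  stop_if_grid_mismatch(subj_grad, template_grad_in_subject, "gradient maps")
  d <- subj_grad$data - template_grad_in_subject$data
  bn_volume(smooth3d(d, fwhm_to_sigma(blur_fwhm), voxel_sizes(subj_grad)),
            subj_grad$affine)
}

#' Group white-matter voxels by connectivity
#'
#' Connected components of WM-labelled voxels; the main group is the largest
#' (ties broken toward the component containing the lowest linear voxel
#' index). True white matter should form a single group; bright artifacts
#' typically land in small separate groups.
#'
#' @param labels a [bn_labels()] with at least one WM voxel.
#' @param connectivity 6, 18 or 26.
#' @return a `wm_grouping`: list with `component` (integer array, 0 outside
#'   WM), `main_group_id`, `counts` (voxels per group).
#' @export
group_white_matter <- function(labels, connectivity = 26) {
  wm <- bn_mask(array(as.integer(labels$data == 3L), dim(labels$data)),
                labels$affine)
  if (mask_count(wm) == 0) stop("no white-matter voxels")
  comp <- mask_components(wm, connectivity)
  counts <- tabulate(comp[comp > 0])
  structure(list(component = comp, main_group_id = which.max(counts),
                 counts = counts, affine = labels$affine),
            class = "wm_grouping")
}

#' @export
print.wm_grouping <- function(x, ...) {
  cat(sprintf("<wm_grouping> %d group(s); main = %d (%d voxels)\n",
              length(x$counts), x$main_group_id, max(x$counts)))
  invisible(x)
}

# percentile gate value of the gradient-difference map within the brain
graddiff_gate <- function(grad_diff, brain_mask, percentile) {
  if (mask_count(brain_mask) == 0) stop("empty brain mask")
  quantile(grad_diff$data[brain_mask$data == 1], percentile / 100,
           names = FALSE)
}

#' Seed blood-flow-artifact voxels
#'
#' A voxel is seeded when all four pieces of evidence agree: (a) it is
#' WM-labelled, (b) it is outside the main white-matter group, (c) its
#' blurred gradient-difference value reaches the configured percentile of
#' the map within the brain mask, and (d) its blood probability reaches the
#' configured floor.
#'
#' @param labels a [bn_labels()].
#' @param grouping a `wm_grouping` from [group_white_matter()].
#' @param grad_diff blurred gradient-difference [bn_volume()].
#' @param bpm_subject blood [bn_probmap()] resampled to the subject grid.
#' @param brain_mask subject brain [bn_mask()] (non-empty).
#' @param config a [bn_config()].
#' @return a [bn_mask()] of seed voxels.
#' @export
seed_blood_voxels <- function(labels, grouping, grad_diff, bpm_subject,
                              brain_mask, config = bn_config()) {
  gate <- graddiff_gate(grad_diff, brain_mask,
                        config$expansion_graddiff_percentile)
  sel <- labels$data == 3L &
    grouping$component != grouping$main_group_id &
    grad_diff$data >= gate &
    bpm_subject$data >= config$expansion_prob_threshold
  bn_mask(array(as.integer(sel), dim(labels$data)), labels$affine)
}

#' Expand the blood mask along the vascular structure
#'
#' Iteratively dilates the current blood mask (6-connected) and accepts
#' newly reached voxels that still meet the seeding evidence — blood is not
#' seen in isolated voxels but in connected vascular structure. Stops at a
#' fixed point or after `expansion_max_iters` passes.
#'
#' @param seed seed [bn_mask()].
#' @inheritParams seed_blood_voxels
#' @return a [bn_mask()] containing the seed.
#' @export
expand_blood_mask <- function(seed, labels, grouping, grad_diff, bpm_subject,
                              brain_mask, config = bn_config()) {
  if (mask_count(seed) == 0) return(seed)
  gate <- graddiff_gate(grad_diff, brain_mask,
                        config$expansion_graddiff_percentile)
  eligible <- labels$data == 3L &
    grouping$component != grouping$main_group_id &
    grad_diff$data >= gate &
    bpm_subject$data >= config$expansion_prob_threshold
  cur <- seed$data
  for (it in seq_len(config$expansion_max_iters)) {
    cand <- cpp_dilate(cur, dim(cur), 6L, 1L) & !cur
    acc <- cand & eligible
    if (!any(acc)) break
    cur <- array(as.integer(cur | acc), dim(cur))
  }
  bn_mask(cur, seed$affine)
}

#' Recover artifact voxels inside the main white-matter group
#'
#' After the refined registration has improved the blood-probability-map
#' alignment, voxels grouped with the main white matter (for example vessels
#' wrapping the corpus callosum) are added where the blood probability
#' reaches the major-vessel threshold and the gradient gate passes.
#'
#' @param grouping a `wm_grouping`.
#' @param bpm_subject refined blood [bn_probmap()] on the subject grid.
#' @param grad_diff blurred gradient-difference [bn_volume()].
#' @param current_blood current blood [bn_mask()].
#' @param brain_mask subject brain [bn_mask()].
#' @param config a [bn_config()].
#' @return union of `current_blood` and the recovered voxels.
#' @export
recover_main_group_blood <- function(grouping, bpm_subject, grad_diff,
                                     current_blood, brain_mask,
                                     config = bn_config()) {
  gate <- graddiff_gate(grad_diff, brain_mask,
                        config$expansion_graddiff_percentile)
  add <- grouping$component == grouping$main_group_id &
    bpm_subject$data >= config$major_vessel_threshold &
    grad_diff$data >= gate
  bn_mask(array(as.integer(current_blood$data == 1 | add),
                dim(current_blood$data)), current_blood$affine)
}

#' Brain mask minus blood mask
#'
#' @param brain_mask,blood_mask [bn_mask()]s on the same grid.
#' @return `brain_mask AND NOT blood_mask`; error if the result is empty.
#' @export
refine_brain_mask <- function(brain_mask, blood_mask) {
  stop_if_grid_mismatch(brain_mask, blood_mask, "masks")
  out <- array(as.integer(brain_mask$data == 1 & blood_mask$data == 0),
               dim(brain_mask$data))
  if (sum(out) == 0) stop("refined brain mask is empty")
  bn_mask(out, brain_mask$affine)
}

#' Trim artifact-driven voxels from the brain-mask periphery
#'
#' An artifact that reaches the brain surface drags extra voxels into the
#' extracted mask as bumps on its periphery. The brain surface itself is
#' smooth at the scale of a few voxels, so a morphological opening
#' (erosion followed by dilation, `opening` passes each) reproduces the
#' artifact-free surface; blood-mask voxels outside the opened mask are the
#' extra periphery voxels and are removed. Blood voxels inside the smooth
#' envelope stay: after deblooding they are CSF-like brain-interior voxels.
#' The largest remaining component is returned.
#'
#' @param brain_mask,blood_mask [bn_mask()]s on the same grid.
#' @param opening erosion/dilation passes (26-connected, so the structuring
#'   element spans `2 * opening + 1` voxels) defining the widest surface
#'   bump attributed to artifacts.
#' @return trimmed [bn_mask()], a subset of `brain_mask`.
#' @export
trim_brain_mask_periphery <- function(brain_mask, blood_mask, opening = 4) {
  stop_if_grid_mismatch(brain_mask, blood_mask, "masks")
  dm <- dim(brain_mask$data)
  # one extra dilation pass compensates the opening's undershoot on curved
  # surfaces, so genuine near-surface brain voxels are not sacrificed
  opened <- mask_dilate(mask_erode(brain_mask, opening, 26), opening + 1, 26)
  remove <- blood_mask$data == 1 & opened$data == 0
  kept <- array(as.integer(brain_mask$data == 1 & !remove), dm)
  largest_component(bn_mask(kept, brain_mask$affine), 26)
}
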