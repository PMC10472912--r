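#' Build the blood probability map from co-registered MRA volumes
#'
#' Voxelwise mean of the input volumes (all already in template space),
#' normalised by its global maximum so the map peaks at 1. An all-zero input
#' set yields an all-zero map.
#'
#' @param mra_in_template list of non-negative [bn_volume()]s on a common grid.
#' @return a [bn_probmap()].
#' @export
build_blood_probability_map <- function(mra_in_template) {
  if (length(mra_in_template) < 1) stop("need at least one MRA volume")
  ref <- mra_in_template[[1]]
  acc <- array(0, dim(ref$data))
  for (v in mra_in_template) {
    stop_if_grid_mismatch(ref, v, "MRA volumes")
    if (min(v$data) < 0) stop("MRA volumes must be non-negative")
    acc <- acc + v$data
  }
  acc <- acc / length(mra_in_template)
  mx <- max(acc)
  if (mx > 0) acc <- acc / mx
  bn_probmap(acc, ref$affine)
}

#' Bloodless registration mask
#'
#' Template brain mask minus high-blood-probability regions: voxels are kept
#' where the brain mask is 1 and the blood probability is strictly below the
#' threshold (default 0.1).
#'
#' @param bpm a [bn_probmap()].
#' @param brain_mask template brain [bn_mask()] on the same grid.
#' @param threshold keep cut in [0, 1].
#' @return a [bn_mask()], a subset of `brain_mask`.
#' @export
make_bloodless_mask <- function(bpm, brain_mask, threshold = 0.1) {
  stop_if_grid_mismatch(bpm, brain_mask)
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  bn_mask(array(as.integer(brain_mask$data == 1 & bpm$data < threshold),
                dim(bpm$data)), bpm$affine)
}

#' Binarize a probability map
#'
#' 1 where the map is at or above the threshold (default 0.2, the major-vessel
#' operating point), else 0.
#'
#' @param bpm a [bn_probmap()].
#' @param threshold cut in [0, 1]; boundary voxels count as vessel.
#' @return a [bn_mask()].
#' @export
binarize_probmap <- function(bpm, threshold = 0.2) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  bn_mask(array(as.integer(bpm$data >= threshold), dim(bpm$data)), bpm$affine)
}
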