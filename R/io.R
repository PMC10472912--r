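#' Read a 3D NIfTI volume
#'
#' Accepts plain and gzipped NIfTI-1. The voxel-to-world affine is taken from
#' the image xform (sform preferred).
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [bn_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) == 4 && dim(a)[4] == 1) a <- a[, , , 1, drop = TRUE]
  if (length(dim(a)) != 3)
    stop(sprintf("expected a 3D image, got %dD", length(dim(a))))
  nf <- sum(!is.finite(a))
  if (nf > 0)
    stop(sprintf("volume contains %d non-finite voxel(s): %s", nf, path))
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4, 4))
  bn_volume(array(as.numeric(a), dim(a)), aff)
}

#' Write a volume as NIfTI
#'
#' @param v a `bn_volume` (or subclass).
#' @param path output path (`.nii` or `.nii.gz`).
#' @return invisibly, `path`.
#' @export
write_volume <- function(v, path) {
  write_nifti_array(v$data, v$affine, path,
                    datatype = if (inherits(v, "bn_mask") ||
                                   inherits(v, "bn_labels")) "uint8" else "double")
  invisible(path)
}

#' Read a binary mask from NIfTI
#'
#' @param path path to the mask image; values must be exactly 0/1.
#' @return a [bn_mask()].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  if (any(v$data != 0 & v$data != 1))
    stop(sprintf("mask file contains values other than 0/1: %s", path))
  bn_mask(v$data, v$affine)
}

#' @rdname write_volume
#' @export
write_mask <- function(v, path) {
  stopifnot(inherits(v, "bn_mask"))
  write_volume(v, path)
}

#' Read/write an affine transform as a plain-text 4x4 matrix
#'
#' The file holds 4 rows of 4 whitespace-separated numbers.
#'
#' @param path file path.
#' @return `read_affine` returns a [bn_affine()].
#' @export
read_affine <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (any(dim(m) != c(4, 4))) stop("affine file must contain a 4x4 matrix")
  bn_affine(unname(m))
}

#' @rdname read_affine
#' @param t a `bn_affine` to write.
#' @export
write_affine <- function(t, path) {
  stopifnot(inherits(t, "bn_affine"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(t$mat, 1, function(r)
    paste(sprintf("%.17g", r), collapse = " ")), con)
  invisible(path)
}

#' Read/write a deformation field as a 5D NIfTI vector image
#'
#' Uses the conventional `nx x ny x nz x 1 x 3` layout with displacements in
#' world millimetres.
#'
#' @param path file path.
#' @return `read_deformation_field` returns a [bn_defield()].
#' @export
read_deformation_field <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) == 5 && dim(a)[4] == 1) {
    a <- array(a, dim(a)[c(1, 2, 3, 5)])
  }
  if (length(dim(a)) != 4 || dim(a)[4] != 3)
    stop("deformation field file must be nx x ny x nz x 1 x 3")
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4, 4))
  bn_defield(array(as.numeric(a), dim(a)), aff)
}

#' @rdname read_deformation_field
#' @param f a `bn_defield` to write.
#' @export
write_deformation_field <- function(f, path) {
  stopifnot(inherits(f, "bn_defield"))
  dm <- dim(f$disp)
  a5 <- array(f$disp, c(dm[1:3], 1, 3))
  write_nifti_array(a5, f$affine, path, datatype = "double")
  invisible(path)
}

write_nifti_array <- function(a, affine, path, datatype = "double") {
  img <- RNifti::asNifti(a, datatype = datatype)
  aff <- structure(affine, code = 2L)
  RNifti::`sform<-`(img, aff) -> img
  RNifti::`qform<-`(img, aff) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Pipeline configuration
#'
#' All tunable parameters of the artifact-detection and evaluation pipeline.
#' Thresholds 0.1 (bloodless mask) and 0.2 (major vessels) and the gradient
#' FWHMs of 1 and 2 mm are the published operating points; the remaining
#' fields parameterise steps the method leaves open (see the methods
#' vignette).
#'
#' @param bloodless_threshold blood-probability cut below which a template
#'   voxel is kept in the bloodless registration mask.
#' @param major_vessel_threshold blood-probability cut at or above which a
#'   voxel counts as major vessel.
#' @param gradient_fwhm_mm Gaussian FWHM (mm) for gradient-magnitude maps.
#' @param graddiff_blur_fwhm_mm FWHM (mm) of the blur applied to the
#'   gradient-difference map.
#' @param wm_connectivity voxel connectivity (6, 18 or 26) for white-matter
#'   grouping.
#' @param expansion_max_iters cap on blood-mask dilation-expansion passes.
#' @param expansion_graddiff_percentile percentile (within the brain mask) of
#'   the blurred gradient-difference map that "relatively high" gradients
#'   must reach for seeding and expansion.
#' @param expansion_prob_threshold blood-probability floor for seeding and
#'   expansion.
#' @param replacement_dilate_iters 6-connected dilations of the blood mask
#'   before blurring into replacement weights.
#' @param replacement_blur_fwhm_mm FWHM (mm) of that blur.
#' @param mi_bins joint-histogram bins for mutual information.
#' @param rng_seed integer seed threaded through every stochastic step.
#' @param affine_levels multiresolution shrink factors for affine
#'   registration (coarse to fine).
#' @param affine_sweeps pattern-search sweep caps per level.
#' @param nl_iters demons iteration caps per level (same levels).
#' @param nl_sigma_fluid Gaussian sigma (voxels) smoothing each demons update.
#' @param nl_sigma_diffusion Gaussian sigma (voxels) smoothing the total
#'   field each iteration.
#' @param nl_max_step_voxels per-iteration displacement-update cap (voxels).
#' @return a validated list of class `bn_config`.
#' @export
bn_config <- function(bloodless_threshold = 0.1,
                      major_vessel_threshold = 0.2,
                      gradient_fwhm_mm = 1,
                      graddiff_blur_fwhm_mm = 2,
                      wm_connectivity = 26,
                      expansion_max_iters = 10,
                      expansion_graddiff_percentile = 90,
                      expansion_prob_threshold = 0.1,
                      replacement_dilate_iters = 1,
                      replacement_blur_fwhm_mm = 1.4,
                      mi_bins = 64,
                      rng_seed = 1,
                      affine_levels = c(4, 2, 1),
                      affine_sweeps = c(40, 25, 10),
                      nl_iters = c(60, 30, 10),
                      nl_sigma_fluid = 1,
                      nl_sigma_diffusion = 1,
                      nl_max_step_voxels = 1) {
  cfg <- list(bloodless_threshold = bloodless_threshold,
              major_vessel_threshold = major_vessel_threshold,
              gradient_fwhm_mm = gradient_fwhm_mm,
              graddiff_blur_fwhm_mm = graddiff_blur_fwhm_mm,
              wm_connectivity = wm_connectivity,
              expansion_max_iters = expansion_max_iters,
              expansion_graddiff_percentile = expansion_graddiff_percentile,
              expansion_prob_threshold = expansion_prob_threshold,
              replacement_dilate_iters = replacement_dilate_iters,
              replacement_blur_fwhm_mm = replacement_blur_fwhm_mm,
              mi_bins = mi_bins,
              rng_seed = rng_seed,
              affine_levels = affine_levels,
              affine_sweeps = affine_sweeps,
              nl_iters = nl_iters,
              nl_sigma_fluid = nl_sigma_fluid,
              nl_sigma_diffusion = nl_sigma_diffusion,
              nl_max_step_voxels = nl_max_step_voxels)
  validate_config(cfg)
  structure(cfg, class = "bn_config")
}

validate_config <- function(cfg) {
  in01 <- function(x) is.numeric(x) && length(x) == 1 && x >= 0 && x <= 1
  if (!in01(cfg$bloodless_threshold)) stop("bloodless_threshold must be in [0,1]")
  if (!in01(cfg$major_vessel_threshold)) stop("major_vessel_threshold must be in [0,1]")
  if (!in01(cfg$expansion_prob_threshold)) stop("expansion_prob_threshold must be in [0,1]")
  if (cfg$gradient_fwhm_mm <= 0 || cfg$graddiff_blur_fwhm_mm <= 0 ||
      cfg$replacement_blur_fwhm_mm <= 0)
    stop("FWHM parameters must be positive")
  if (!(cfg$wm_connectivity %in% c(6, 18, 26)))
    stop("wm_connectivity must be 6, 18 or 26")
  if (cfg$expansion_graddiff_percentile < 0 || cfg$expansion_graddiff_percentile > 100)
    stop("expansion_graddiff_percentile must be in [0,100]")
  if (cfg$expansion_max_iters < 0 || cfg$replacement_dilate_iters < 0)
    stop("iteration counts must be non-negative")
  if (cfg$mi_bins < 2) stop("mi_bins must be at least 2")
  invisible(TRUE)
}

#' Read/write a pipeline configuration (YAML or JSON)
#'
#' The file maps exactly the [bn_config()] fields; missing fields take their
#' defaults, unknown fields are an error.
#'
#' @param path config file; `.yaml`/`.yml` or `.json`.
#' @return `read_config` returns a `bn_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config must be .yaml, .yml or .json")
  known <- names(formals(bn_config))
  bad <- setdiff(names(lst), known)
  if (length(bad) > 0)
    stop(sprintf("unknown config fields: %s", paste(bad, collapse = ", ")))
  do.call(bn_config, lst)
}

#' @rdname read_config
#' @param cfg a `bn_config` to write.
#' @export
write_config <- function(cfg, path) {
  ext <- tolower(tools::file_ext(path))
  lst <- unclass(cfg)
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(lst, path)
  } else if (ext == "json") {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  } else stop("config must be .yaml, .yml or .json")
  invisible(path)
}
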