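#' 3D scalar volume with a voxel-to-world affine
#'
#' The basic container for T1-weighted scans, gradient maps, Jacobian and
#' displacement maps. Voxel indices are 0-based in the voxel-to-world
#' convention; world coordinates are RAS millimetres.
#'
#' @param data numeric 3D array, all values finite.
#' @param affine 4x4 voxel-to-world matrix (mm); last row (0,0,0,1) and the
#'   3x3 block invertible. Defaults to 1 mm isotropic with origin at voxel 0.
#' @return an object of class `bn_volume` with fields `data` and `affine`.
#' @export
bn_volume <- function(data, affine = diag(4)) {
  data <- ensure_array3d(data)
  check_affine_matrix(affine)
  nf <- sum(!is.finite(data))
  if (nf > 0)
    stop(sprintf("volume contains %d non-finite voxel(s)", nf))
  structure(list(data = data, affine = unname(affine)), class = "bn_volume")
}

#' Binary mask on a volume grid
#'
#' @param data array of 0/1 values (logical or numeric accepted).
#' @param affine 4x4 voxel-to-world matrix.
#' @return a `bn_mask` (subclass of `bn_volume`) holding an integer array.
#' @export
bn_mask <- function(data, affine = diag(4)) {
  data <- ensure_array3d(data)
  check_affine_matrix(affine)
  if (is.logical(data)) {
    d <- array(as.integer(data), dim(data))
  } else {
    if (any(!is.finite(data)) || any(data != 0 & data != 1))
      stop("mask values must be exactly 0 or 1")
    d <- array(as.integer(data), dim(data))
  }
  structure(list(data = d, affine = unname(affine)),
            class = c("bn_mask", "bn_volume"))
}

#' Probability map on a volume grid (values in [0, 1])
#'
#' @inheritParams bn_volume
#' @return a `bn_probmap` (subclass of `bn_volume`).
#' @export
bn_probmap <- function(data, affine = diag(4)) {
  data <- ensure_array3d(data)
  check_affine_matrix(affine)
  if (any(!is.finite(data))) stop("probability map contains non-finite values")
  if (min(data) < 0 || max(data) > 1)
    stop("probability map values must lie in [0, 1]")
  structure(list(data = data, affine = unname(affine)),
            class = c("bn_probmap", "bn_volume"))
}

#' Tissue label volume
#'
#' Codes: 0 background, 1 CSF, 2 grey matter, 3 white matter.
#'
#' @param data integer array with values in 0:3.
#' @param affine 4x4 voxel-to-world matrix.
#' @return a `bn_labels` object.
#' @export
bn_labels <- function(data, affine = diag(4)) {
  data <- ensure_array3d(data)
  check_affine_matrix(affine)
  if (any(!is.finite(data)) || !all(data %in% 0:3))
    stop("tissue labels must be integers in 0:3")
  structure(list(data = array(as.integer(data), dim(data)),
                 affine = unname(affine)),
            class = c("bn_labels", "bn_volume"))
}

#' Voxel sizes of a volume (mm)
#'
#' Column norms of the 3x3 block of the voxel-to-world affine.
#' @param v a `bn_volume` (or subclass).
#' @return length-3 numeric vector.
#' @export
voxel_sizes <- function(v) {
  A <- v$affine[1:3, 1:3, drop = FALSE]
  sqrt(colSums(A^2))
}

#' @export
dim.bn_volume <- function(x) dim(x$data)

#' @export
print.bn_volume <- function(x, ...) {
  cls <- class(x)[1]
  vs <- voxel_sizes(x)
  cat(sprintf("<%s> %s voxels, %s mm\n", cls,
              paste(dim(x$data), collapse = "x"),
              paste(signif(vs, 4), collapse = "x")))
  rng <- range(x$data)
  cat(sprintf("  values in [%g, %g]\n", rng[1], rng[2]))
  invisible(x)
}

ensure_array3d <- function(data) {
  if (is.null(dim(data)) || length(dim(data)) != 3)
    stop("expected a 3D array")
  if (!is.numeric(data) && !is.logical(data))
    stop("expected numeric data")
  data
}

check_affine_matrix <- function(affine) {
  if (!is.matrix(affine) || any(dim(affine) != c(4, 4)))
    stop("affine must be a 4x4 matrix")
  if (any(abs(affine[4, ] - c(0, 0, 0, 1)) > 1e-10))
    stop("affine last row must be (0, 0, 0, 1)")
  if (abs(det(affine[1:3, 1:3])) <= 1e-8)
    stop("affine 3x3 block must be invertible")
  invisible(TRUE)
}

# TRUE when two volumes share grid shape and affine (within tolerance)
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$affine - b$affine)) <= tol
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(sprintf("%s are not on the same grid", what))
  invisible(TRUE)
}

# fraction of voxels that are 1
mask_count <- function(m) sum(m$data)

# voxel volume in mm^3
voxel_volume <- function(v) abs(det(v$affine[1:3, 1:3]))
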