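#' World-to-world affine transform
#'
#' The matrix maps world points (mm) of the moving space onto world points of
#' the fixed space; resampling onto the fixed grid pulls intensities back
#' through its exact inverse.
#'
#' @param mat 4x4 matrix, last row (0,0,0,1), invertible 3x3 block.
#' @param direction transform direction label; only "moving_to_fixed" is used.
#' @return a `bn_affine` object.
#' @export
bn_affine <- function(mat = diag(4), direction = "moving_to_fixed") {
  check_affine_matrix(mat)
  structure(list(mat = unname(mat), direction = direction),
            class = "bn_affine")
}

#' Dense deformation field on a reference grid
#'
#' Stores one displacement vector per voxel of the reference grid, in world
#' millimetres, in the pull-back convention: the moving-space point sampled at
#' fixed voxel x is `A^-1(x_world + u(x))` where A is the companion affine.
#' The mapping analysed by [jacobian_determinant_map()] is `phi(x) = x + u(x)`.
#'
#' @param disp 4D array, `dim = c(grid, 3)`, finite values (mm).
#' @param affine 4x4 voxel-to-world matrix of the reference grid.
#' @return a `bn_defield` object.
#' @export
bn_defield <- function(disp, affine = diag(4)) {
  if (is.null(dim(disp)) || length(dim(disp)) != 4 || dim(disp)[4] != 3)
    stop("deformation field must be a 4D array with dim[4] == 3")
  if (any(!is.finite(disp))) stop("deformation field contains non-finite values")
  check_affine_matrix(affine)
  structure(list(disp = disp, affine = unname(affine)), class = "bn_defield")
}

#' Composite transform: one affine followed by an optional deformation
#'
#' @param affine a `bn_affine`.
#' @param field a `bn_defield` on the fixed grid, or NULL.
#' @return a `bn_transform` object.
#' @export
bn_transform <- function(affine = bn_affine(), field = NULL) {
  stopifnot(inherits(affine, "bn_affine"))
  if (!is.null(field)) stopifnot(inherits(field, "bn_defield"))
  structure(list(affine = affine, field = field), class = "bn_transform")
}

#' @export
print.bn_affine <- function(x, ...) {
  cat("<bn_affine> world-to-world (mm),", x$direction, "\n")
  print(signif(x$mat, 6))
  invisible(x)
}

#' @export
print.bn_defield <- function(x, ...) {
  mags <- sqrt(rowSums(matrix(x$disp, ncol = 3)^2))
  cat(sprintf("<bn_defield> %s grid, |u| in [%.3g, %.3g] mm\n",
              paste(dim(x$disp)[1:3], collapse = "x"), min(mags), max(mags)))
  invisible(x)
}

#' @export
print.bn_transform <- function(x, ...) {
  cat("<bn_transform> affine",
      if (is.null(x$field)) "only\n" else "+ deformation field\n")
  invisible(x)
}

#' Invert an affine transform
#' @param t a `bn_affine`.
#' @return the inverse `bn_affine`.
#' @export
invert_affine <- function(t) {
  stopifnot(inherits(t, "bn_affine"))
  bn_affine(solve(t$mat), direction = t$direction)
}

as_bn_transform <- function(t) {
  if (inherits(t, "bn_transform")) return(t)
  if (inherits(t, "bn_affine")) return(bn_transform(t))
  if (inherits(t, "bn_defield")) return(bn_transform(bn_affine(), t))
  stop("not a transform")
}

#' Compose two transforms (apply `a`, then `b`)
#'
#' `resample(v, compose(a, b), ref)` matches
#' `resample(resample(v, a, ref), b, ref)` up to interpolation error.
#'
#' @param a a `bn_affine`.
#' @param b a `bn_affine` or `bn_transform`.
#' @return a `bn_transform`.
#' @export
compose_transforms <- function(a, b) {
  stopifnot(inherits(a, "bn_affine"))
  b <- as_bn_transform(b)
  bn_transform(bn_affine(b$affine$mat %*% a$mat), b$field)
}

#' Build an affine from translation, rotation, and scale parameters
#'
#' Rotations (degrees, applied as Rz Ry Rx) and scaling act about `centre`
#' (world mm); the translation is added afterwards.
#'
#' @param translation length-3, mm.
#' @param rotation length-3, degrees about x, y, z.
#' @param scale length-3 (or scalar) scale factors.
#' @param centre length-3 world point the rotation/scale act about.
#' @return a `bn_affine`.
#' @export
make_affine <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                        scale = c(1, 1, 1), centre = c(0, 0, 0)) {
  if (length(scale) == 1) scale <- rep(scale, 3)
  r <- rotation * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  RS <- Rz %*% Ry %*% Rx %*% diag(scale)
  M <- diag(4)
  M[1:3, 1:3] <- RS
  M[1:3, 4] <- translation + centre - RS %*% centre
  bn_affine(M)
}

#' Decompose an affine into translation, rotation and scale
#'
#' Assumes the matrix was built as in [make_affine()] (no shear); returns the
#' parameters about the same centre.
#'
#' @param t a `bn_affine`.
#' @param centre world point used when the transform was built.
#' @return list with `translation` (mm), `rotation` (deg), `scale`.
#' @export
decompose_affine <- function(t, centre = c(0, 0, 0)) {
  M <- t$mat
  RS <- M[1:3, 1:3]
  scale <- sqrt(colSums(RS^2))
  R <- RS %*% diag(1 / scale)
  if (det(R) < 0) {
    scale[1] <- -scale[1]
    R <- RS %*% diag(1 / scale)
  }
  ry <- asin(pmin(1, pmax(-1, -R[3, 1])))
  if (abs(cos(ry)) > 1e-8) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {
    rx <- atan2(-R[2, 3], R[2, 2])
    rz <- 0
  }
  translation <- M[1:3, 4] - centre + RS %*% centre
  list(translation = as.numeric(translation),
       rotation = c(rx, ry, rz) * 180 / pi,
       scale = as.numeric(scale))
}

#' Resample a volume or mask through a transform
#'
#' Pulls the moving image back onto the reference grid: the value at fixed
#' voxel x is `moving(A^-1(x_world + u(x)))`. Volumes use trilinear
#' interpolation, masks nearest neighbour; voxels mapping outside the moving
#' volume are set to 0.
#'
#' @param v moving `bn_volume` or `bn_mask`.
#' @param t `bn_affine`, `bn_defield` or `bn_transform` (moving to fixed).
#' @param reference volume defining the output grid.
#' @param interp "linear" or "nearest"; defaults by input class. Requesting
#'   linear interpolation for a mask is an error.
#' @return resampled object of the same class as `v` on the reference grid.
#' @export
resample <- function(v, t, reference,
                     interp = if (inherits(v, "bn_mask") ||
                                  inherits(v, "bn_labels")) "nearest" else "linear") {
  t <- as_bn_transform(t)
  is_mask <- inherits(v, "bn_mask")
  is_lab <- inherits(v, "bn_labels")
  if ((is_mask || is_lab) && interp == "linear")
    stop("linear interpolation is not allowed for masks or labels")
  interp_code <- switch(interp, linear = 1L, nearest = 0L,
                        stop("unknown interpolation"))
  field <- NULL
  if (!is.null(t$field)) {
    if (!identical(dim(t$field$disp)[1:3], dim(reference$data)))
      stop("deformation field grid does not match the reference grid")
    field <- as.numeric(t$field$disp)
  }
  # fixed voxel index -> fixed world; (world + u) -> moving voxel index
  vox2world <- reference$affine
  world2mov <- solve(v$affine) %*% solve(t$affine$mat)
  out <- cpp_resample(as.numeric(v$data), dim(v$data), dim(reference$data),
                      vox2world, world2mov, field, interp_code)
  if (is_mask) bn_mask(out, reference$affine)
  else if (is_lab) bn_labels(out, reference$affine)
  else bn_volume(out, reference$affine)
}

field_of <- function(t, reference) {
  t <- as_bn_transform(t)
  if (is.null(t$field)) {
    dm <- dim(reference$data)
    bn_defield(array(0, c(dm, 3)), reference$affine)
  } else {
    if (!identical(dim(t$field$disp)[1:3], dim(reference$data)))
      stop("deformation field is not defined on the reference grid")
    t$field
  }
}

#' Jacobian determinant map of a deformation
#'
#' Per-voxel `|det(d phi / d x)|` of the mapping `phi(x) = x + u(x)` (the
#' deformation part of the transform), computed with central differences in
#' millimetres and one-sided differences at the grid boundary. 1 means no
#' local volume change, >1 expansion, <1 compression.
#'
#' @param t `bn_transform`, `bn_defield`, or `bn_affine` (treated as zero
#'   deformation).
#' @param reference volume defining the grid.
#' @return a `bn_volume` of absolute Jacobian determinants.
#' @export
jacobian_determinant_map <- function(t, reference) {
  f <- field_of(t, reference)
  u <- f$disp
  dm <- dim(u)[1:3]
  vs <- voxel_sizes(bn_volume(array(0, dm), f$affine))
  # grad[[i]][[j]] = d u_i / d x_j (mm/mm)
  J <- vector("list", 9)
  for (i in 1:3)
    for (j in 1:3)
      J[[(i - 1) * 3 + j]] <- array_deriv(u[, , , i], j, vs[j])
  a <- J[[1]] + 1; b <- J[[2]];     cc <- J[[3]]
  d <- J[[4]];     e <- J[[5]] + 1; f2 <- J[[6]]
  g <- J[[7]];     h <- J[[8]];     i9 <- J[[9]] + 1
  det <- a * (e * i9 - f2 * h) - b * (d * i9 - f2 * g) + cc * (d * h - e * g)
  bn_volume(abs(det), f$affine)
}

#' Displacement magnitude map of a deformation
#'
#' Per-voxel Euclidean norm (mm) of the displacement vectors.
#'
#' @inheritParams jacobian_determinant_map
#' @return a `bn_volume`.
#' @export
displacement_magnitude_map <- function(t, reference) {
  f <- field_of(t, reference)
  u <- f$disp
  bn_volume(sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2), f$affine)
}

# partial derivative of a 3D array along axis (1..3), central differences in
# the interior, one-sided at the two boundary slabs; h = spacing (mm)
array_deriv <- function(a, axis, h) {
  dm <- dim(a)
  n <- dm[axis]
  out <- array(0, dm)
  idx <- function(i) {
    ix <- list(seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3]))
    ix[[axis]] <- i
    ix
  }
  gi <- function(i) do.call(`[`, c(list(a), idx(i)))
  if (n >= 3) {
    interior <- (gi(3:n) - gi(1:(n - 2))) / (2 * h)
    ix <- idx(2:(n - 1))
    out <- do.call(`[<-`, c(list(out), ix, list(interior)))
  }
  ix1 <- idx(1); ixn <- idx(n)
  out <- do.call(`[<-`, c(list(out), ix1, list((gi(2) - gi(1)) / h)))
  out <- do.call(`[<-`, c(list(out), ixn, list((gi(n) - gi(n - 1)) / h)))
  out
}
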