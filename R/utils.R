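# FWHM (mm) -> Gaussian sigma (mm)
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# discrete Gaussian kernel, sigma in voxels; radius 3 sigma
gaussian_kernel <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, as.integer(ceiling(3 * sigma_vox)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# separable Gaussian smoothing of a 3D array; sigma_mm scalar, per-axis
# voxel sizes vs (mm). Boundary: renormalised kernel mass.
smooth3d <- function(a, sigma_mm, vs = c(1, 1, 1)) {
  if (sigma_mm <= 0) return(a)
  dm <- dim(a)
  out <- as.numeric(a)
  for (axis in 1:3) {
    k <- gaussian_kernel(sigma_mm / vs[axis])
    if (length(k) > 1)
      out <- cpp_conv_axis(out, dm, k, axis - 1L)
  }
  array(out, dm)
}

#' Gaussian-smooth a volume
#'
#' @param v a `bn_volume`.
#' @param fwhm_mm full width at half maximum of the Gaussian, in mm.
#' @return smoothed `bn_volume` on the same grid.
#' @export
smooth_volume <- function(v, fwhm_mm) {
  s <- fwhm_to_sigma(fwhm_mm)
  bn_volume(smooth3d(v$data, s, voxel_sizes(v)), v$affine)
}

# smooth + stride downsampling by integer factor f; returns bn_volume with
# updated affine (world geometry preserved)
downsample_volume <- function(v, f, presmooth = TRUE) {
  if (f == 1) return(v)
  a <- v$data
  vs <- voxel_sizes(v)
  if (presmooth) a <- smooth3d(a, mean(vs) * f / 2, vs)
  ix <- lapply(dim(a), function(n) seq(1, n, by = f))
  sub <- a[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  A <- v$affine
  S <- diag(c(f, f, f, 1))
  bn_volume(sub, A %*% S)
}

downsample_mask <- function(m, f) {
  if (f == 1) return(m)
  ix <- lapply(dim(m$data), function(n) seq(1, n, by = f))
  sub <- m$data[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  bn_mask(sub, m$affine %*% diag(c(f, f, f, 1)))
}

# mask morphology on bn_mask
mask_dilate <- function(m, iters = 1, connectivity = 6) {
  if (iters < 1) return(m)
  bn_mask(cpp_dilate(m$data, dim(m$data), as.integer(connectivity),
                     as.integer(iters)), m$affine)
}

mask_erode <- function(m, iters = 1, connectivity = 6) {
  if (iters < 1) return(m)
  bn_mask(cpp_erode(m$data, dim(m$data), as.integer(connectivity),
                    as.integer(iters)), m$affine)
}

# connected-component labels of a bn_mask (components numbered from 1 in
# raster order of their first voxel)
mask_components <- function(m, connectivity = 26) {
  cpp_label3d(m$data, dim(m$data), as.integer(connectivity))
}

# largest connected component of a mask
largest_component <- function(m, connectivity = 26) {
  lab <- mask_components(m, connectivity)
  if (max(lab) == 0) return(m)
  counts <- tabulate(lab[lab > 0])
  keep <- which(counts == max(counts))[1]  # ties: lowest first-voxel label
  bn_mask(array(as.integer(lab == keep), dim(m$data)), m$affine)
}

# fill interior holes: complement components not connected to the corner
# voxel (array boundary) are interior
fill_holes <- function(m, connectivity = 6) {
  inv <- bn_mask(1L - m$data, m$affine)
  lab <- mask_components(inv, connectivity)
  dm <- dim(m$data)
  border <- unique(c(lab[1, , ], lab[dm[1], , ], lab[, 1, ], lab[, dm[2], ],
                     lab[, , 1], lab[, , dm[3]]))
  border <- border[border > 0]
  outside <- array(lab %in% border, dm)
  bn_mask(array(as.integer(!outside), dm), m$affine)
}

# grid of world coordinates for each voxel; returns list(x, y, z) of arrays
world_grid <- function(v) {
  dm <- dim(v$data)
  i <- (seq_len(dm[1]) - 1)
  j <- (seq_len(dm[2]) - 1)
  k <- (seq_len(dm[3]) - 1)
  A <- v$affine
  I <- array(rep(i, times = dm[2] * dm[3]), dm)
  J <- array(rep(rep(j, each = dm[1]), times = dm[3]), dm)
  K <- array(rep(k, each = dm[1] * dm[2]), dm)
  list(x = A[1, 1] * I + A[1, 2] * J + A[1, 3] * K + A[1, 4],
       y = A[2, 1] * I + A[2, 2] * J + A[2, 3] * K + A[2, 4],
       z = A[3, 1] * I + A[3, 2] * J + A[3, 3] * K + A[3, 4])
}

# centre of mass (world mm) of a mask or of positive intensities
centre_of_mass <- function(v) {
  g <- world_grid(v)
  w <- as.numeric(v$data)
  w[w < 0] <- 0
  s <- sum(w)
  if (s == 0) stop("cannot compute centre of mass of an empty volume")
  c(sum(g$x * w), sum(g$y * w), sum(g$z * w)) / s
}
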