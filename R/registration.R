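#' Mutual information between two volumes
#'
#' Joint-histogram estimator with `bins` equal-width bins spanning each
#' image's masked intensity range; MI in nats,
#' `sum p(a,b) log(p(a,b) / (p(a) p(b)))`, zero-probability cells contribute
#' nothing.
#'
#' @param a,b `bn_volume`s on the same grid.
#' @param mask optional `bn_mask` restricting the estimate.
#' @param bins number of histogram bins per image.
#' @return MI in nats (non-negative up to estimator round-off).
#' @export
mutual_information <- function(a, b, mask = NULL, bins = 64) {
  stop_if_grid_mismatch(a, b)
  if (is.null(mask)) {
    mk <- array(1L, dim(a$data))
  } else {
    stop_if_grid_mismatch(a, mask)
    mk <- mask$data
  }
  av <- as.numeric(a$data)[mk == 1]
  bv <- as.numeric(b$data)[mk == 1]
  if (length(unique(av)) < 2 || length(unique(bv)) < 2)
    stop("mutual information undefined: fewer than 2 distinct values in mask")
  h <- cpp_joint_hist(as.numeric(a$data), as.numeric(b$data),
                      as.integer(mk), as.integer(bins),
                      min(av), max(av), min(bv), max(bv))
  mi_from_hist(h)
}

mi_from_hist <- function(h) {
  p <- h / sum(h)
  pa <- rowSums(p)
  pb <- colSums(p)
  nz <- which(p > 0, arr.ind = TRUE)
  sum(p[nz] * log(p[nz] / (pa[nz[, 1]] * pb[nz[, 2]])))
}

# MI of fixed vs moving pulled back through affine M (moving->fixed world),
# evaluated on the fixed-level grid; fast path used inside the optimizer.
# Moves that drop more than 20% of the masked voxels out of the moving
# field of view are rejected outright.
mi_affine_cost <- function(level, M, bins) {
  map <- solve(level$mov_affine) %*% solve(M) %*% level$fix_affine
  cpp_mi_affine(level$fix, level$fdim, level$mov, level$mdim, level$mask,
                map, as.integer(bins),
                level$frange[1], level$frange[2],
                level$mrange[1], level$mrange[2],
                0.8 * level$mask_total)
}

make_level <- function(moving, fixed, fixed_mask, moving_mask, shrink) {
  fx <- downsample_volume(fixed, shrink)
  mv <- downsample_volume(moving, shrink)
  mk <- downsample_mask(fixed_mask, shrink)
  fvals <- fx$data[mk$data == 1]
  list(fix = as.numeric(fx$data), fdim = dim(fx$data), fix_affine = fx$affine,
       mov = as.numeric(mv$data), mdim = dim(mv$data), mov_affine = mv$affine,
       mask = as.integer(mk$data), mask_total = sum(mk$data),
       frange = range(fvals), mrange = range(mv$data),
       fx = fx, mv = mv, mk = mk)
}

#' Affine registration by mutual-information maximisation
#'
#' Nine-parameter (translation, rotation, anisotropic scale) registration of
#' `moving` to `fixed`, maximising mutual information over voxels inside
#' `fixed_mask` with a deterministic multiresolution coordinate pattern
#' search. Rotation and scale act about the masked fixed-image centre of
#' mass.
#'
#' @param moving,fixed `bn_volume`s.
#' @param fixed_mask `bn_mask` on the fixed grid (non-empty).
#' @param moving_mask optional `bn_mask` on the moving grid; fixed voxels
#'   whose pull-back lands outside it are excluded from the histogram.
#' @param config a [bn_config()]; `affine_levels`, `affine_sweeps` and
#'   `mi_bins` are used.
#' @param init optional initial `bn_affine`.
#' @return the estimated `bn_affine` (moving to fixed) with attribute
#'   `mi_trace` holding the achieved MI per level.
#' @export
register_affine <- function(moving, fixed, fixed_mask, moving_mask = NULL,
                            config = bn_config(), init = NULL) {
  if (mask_count(fixed_mask) == 0) stop("fixed_mask is empty")
  if (!is.null(moving_mask)) {
    # moving-side masking: excluded moving voxels are zeroed so they merge
    # with the background bin instead of contributing artifact structure
    moving <- bn_volume(moving$data * moving_mask$data, moving$affine)
  }
  centre <- centre_of_mass(bn_volume(fixed$data * fixed_mask$data, fixed$affine))
  # parameters: tx ty tz (mm), rx ry rz (deg), sx sy sz
  par <- c(0, 0, 0, 0, 0, 0, 1, 1, 1)
  if (!is.null(init)) {
    d <- decompose_affine(init, centre)
    par <- c(d$translation, d$rotation, d$scale)
  }
  build <- function(p) make_affine(p[1:3], p[4:6], p[7:9], centre)
  # drop pyramid levels whose downsampled grid would be too small for a
  # usable joint histogram; the finest level always remains
  keep <- vapply(config$affine_levels,
                 function(sh) all(dim(fixed$data) / sh >= 24), TRUE)
  keep[length(keep)] <- TRUE
  levels <- config$affine_levels[keep]
  sweeps <- config$affine_sweeps[keep]
  trace <- numeric(0)
  for (li in seq_along(levels)) {
    shrink <- levels[li]
    lev <- make_level(moving, fixed, fixed_mask, moving_mask, shrink)
    bins <- max(8, round(config$mi_bins / shrink))
    steps <- c(rep(2 * shrink, 3), rep(1.5 * shrink, 3), rep(0.01 * shrink, 3))
    min_step <- c(rep(0.05, 3), rep(0.05, 3), rep(5e-4, 3))
    cost <- function(p) mi_affine_cost(lev, build(p)$mat, bins)
    cur <- cost(par)
    for (sw in seq_len(sweeps[li])) {
      improved <- FALSE
      for (pi in seq_along(par)) {
        for (sgn in c(1, -1)) {
          cand <- par
          cand[pi] <- cand[pi] + sgn * steps[pi]
          cc <- cost(cand)
          if (cc > cur + 1e-12) {
            par <- cand
            cur <- cc
            improved <- TRUE
            break
          }
        }
      }
      if (!improved) {
        steps <- steps / 2
        if (all(steps < min_step)) break
      }
    }
    trace <- c(trace, cur)
  }
  out <- build(par)
  attr(out, "mi_trace") <- trace
  out
}

#' Nonlinear registration (multiresolution demons with Gaussian regularisation)
#'
#' Starting from `init`, estimates a smooth deformation field on the fixed
#' grid by iterative demons updates: intensity-difference forces along the
#' warped-image gradient, a Gaussian-smoothed ("fluid") update, and Gaussian
#' ("diffusion") smoothing of the accumulated field. The field is
#' regularised until its analytic Jacobian determinant is positive
#' everywhere, and the result is kept only if it does not decrease mutual
#' information; otherwise the initial transform is returned with a zero
#' field.
#'
#' @param moving,fixed `bn_volume`s with comparable intensity scales (the
#'   demons force is intensity-difference driven; normalise first).
#' @param init initial `bn_affine` (moving to fixed).
#' @param fixed_mask `bn_mask` on the fixed grid; forces outside a slightly
#'   dilated copy are zeroed.
#' @param config a [bn_config()]; `nl_iters`, `nl_sigma_fluid`,
#'   `nl_sigma_diffusion`, `nl_max_step_voxels`, `mi_bins` are used.
#' @return a `bn_transform` (init affine + estimated field) with attributes
#'   `mi_before` / `mi_after`.
#' @export
register_nonlinear <- function(moving, fixed, init, fixed_mask,
                               config = bn_config()) {
  stopifnot(inherits(init, "bn_affine"))
  levels <- config$affine_levels
  iters <- config$nl_iters
  u <- NULL  # field at current level, dim c(level grid, 3), mm
  for (li in seq_along(levels)) {
    shrink <- levels[li]
    fx <- downsample_volume(fixed, shrink)
    mv <- downsample_volume(moving, shrink)
    mk <- mask_dilate(downsample_mask(fixed_mask, shrink), 2, 6)
    vs <- voxel_sizes(fx)
    dm <- dim(fx$data)
    if (is.null(u)) {
      u <- array(0, c(dm, 3))
    } else {
      u <- upsample_field(u, dm, levels[li - 1] / shrink)
    }
    maskv <- mk$data == 1
    for (it in seq_len(iters[li])) {
      warped <- cpp_resample(as.numeric(mv$data), dim(mv$data), dm,
                             fx$affine,
                             solve(mv$affine) %*% solve(init$mat),
                             as.numeric(u), 1L)
      warped <- array(warped, dm)
      e <- fx$data - warped
      gx <- array_deriv(warped, 1, vs[1])
      gy <- array_deriv(warped, 2, vs[2])
      gz <- array_deriv(warped, 3, vs[3])
      g2 <- gx^2 + gy^2 + gz^2
      # demons normalisation: alpha scales the intensity term so steps are
      # capped near nl_max_step_voxels
      alpha <- 1 / (config$nl_max_step_voxels * mean(vs))
      denom <- g2 + (alpha * e)^2
      fac <- ifelse(denom > 1e-12, e / denom, 0)
      fac[!maskv] <- 0
      dx <- fac * gx
      dy <- fac * gy
      dz <- fac * gz
      # fluid regularisation of the update
      sf <- config$nl_sigma_fluid * mean(vs)
      dx <- smooth3d(dx, sf, vs)
      dy <- smooth3d(dy, sf, vs)
      dz <- smooth3d(dz, sf, vs)
      # step cap (mm)
      cap <- config$nl_max_step_voxels * mean(vs)
      mag <- sqrt(dx^2 + dy^2 + dz^2)
      sc <- ifelse(mag > cap, cap / mag, 1)
      u[, , , 1] <- u[, , , 1] + dx * sc
      u[, , , 2] <- u[, , , 2] + dy * sc
      u[, , , 3] <- u[, , , 3] + dz * sc
      # diffusion regularisation of the total field
      sdiff <- config$nl_sigma_diffusion * mean(vs)
      for (cmp in 1:3) u[, , , cmp] <- smooth3d(u[, , , cmp], sdiff, vs)
    }
  }
  # ensure positive Jacobian
  ref <- fixed
  field <- bn_defield(u, ref$affine)
  for (try in 1:5) {
    jd <- jacobian_raw_det(field)
    if (min(jd) > 0) break
    for (cmp in 1:3)
      field$disp[, , , cmp] <- smooth3d(field$disp[, , , cmp], mean(voxel_sizes(ref)),
                                        voxel_sizes(ref))
  }
  if (min(jacobian_raw_det(field)) <= 0)
    stop("nonlinear regularisation failed: non-positive Jacobian after final smoothing")
  out <- bn_transform(init, field)
  # MI acceptance gate: never return a transform worse than the initialiser
  w0 <- resample(moving, init, fixed)
  w1 <- resample(moving, out, fixed)
  mi0 <- mutual_information(fixed, w0, fixed_mask, config$mi_bins)
  mi1 <- mutual_information(fixed, w1, fixed_mask, config$mi_bins)
  if (mi1 < mi0) {
    out <- bn_transform(init, bn_defield(array(0, c(dim(fixed$data), 3)),
                                         fixed$affine))
    mi1 <- mi0
  }
  attr(out, "mi_before") <- mi0
  attr(out, "mi_after") <- mi1
  out
}

# signed Jacobian determinant of phi(x)=x+u(x) (no abs), for invertibility
jacobian_raw_det <- function(field) {
  u <- field$disp
  dm <- dim(u)[1:3]
  vs <- sqrt(colSums(field$affine[1:3, 1:3]^2))
  J <- vector("list", 9)
  for (i in 1:3)
    for (j in 1:3)
      J[[(i - 1) * 3 + j]] <- array_deriv(u[, , , i], j, vs[j])
  a <- J[[1]] + 1; b <- J[[2]];     cc <- J[[3]]
  d <- J[[4]];     e <- J[[5]] + 1; f2 <- J[[6]]
  g <- J[[7]];     h <- J[[8]];     i9 <- J[[9]] + 1
  a * (e * i9 - f2 * h) - b * (d * i9 - f2 * g) + cc * (d * h - e * g)
}

# trilinear upsample of a per-voxel vector field onto a finer grid; levels
# were built by stride sampling from index 0, so fine index i maps to coarse
# index i / ratio exactly
upsample_field <- function(u, dm_out, ratio) {
  dm_in <- dim(u)[1:3]
  out <- array(0, c(dm_out, 3))
  m <- diag(c(1 / ratio, 1 / ratio, 1 / ratio, 1))
  for (cmp in 1:3) {
    out[, , , cmp] <- array(
      cpp_resample(as.numeric(u[, , , cmp]), dm_in, dm_out,
                   m, diag(4), NULL, 2L), dm_out)
  }
  out
}
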