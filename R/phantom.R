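#' Specification for the synthetic brain phantom
#'
#' Describes a nested-ellipsoid head (background, CSF shell, grey-matter
#' ribbon, white-matter core) with fissure-like CSF clefts, mildly gyrified
#' tissue boundaries, bright tubular vessel artifacts running along the
#' clefts and inferior surface, a smooth multiplicative bias field, additive
#' noise, and a known affine + smooth nonlinear misalignment per subject.
#'
#' @param grid_shape integer length-3 grid (default 96^3).
#' @param voxel_mm isotropic voxel size (mm).
#' @param csf,gm,wm tissue intensities (arbitrary units).
#' @param vessel_radius_mm tube radius of the vessel artifacts: a scalar or
#'   per-curve vector, or NULL (default) to use per-curve radii attached to
#'   the curve list (the built-in dural sinuses are 3 mm, fissure and cleft
#'   vessels 2-2.5 mm).
#' @param vessel_intensity artifact intensity; must exceed `wm` (artifacts
#'   are bright).
#' @param vessel_curves optional list of n-by-3 world-coordinate polylines;
#'   NULL uses the built-in tree (superior sagittal sinus riding the brain
#'   surface, a pericallosal arc in the longitudinal fissure, two
#'   Sylvian-cleft vessels, an inferior arc, and two transverse sinuses on
#'   the posterior-inferior surface).
#' @param bias_amplitude multiplicative bias amplitude (0.1 = +-10%),
#'   realised as a product of per-axis degree-2 polynomials.
#' @param noise_sigma additive Gaussian noise SD (intensity units).
#' @param rician if TRUE, Rician-like magnitude noise is used instead.
#' @param misalign_translation_mm,misalign_rotation_deg,misalign_scale
#'   per-subject misalignment amplitudes; parameters are drawn uniformly in
#'   +-amplitude (scale in 1 +- amplitude).
#' @param warp_amplitude_mm peak displacement of the smooth nonlinear
#'   misalignment.
#' @param mra_jitter_mm SD of the rigid per-curve jitter applied when
#'   simulating MR-angiography volumes.
#' @param rng_seed integer seed.
#' @return a validated list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 96), voxel_mm = 1,
                         csf = 30, gm = 65, wm = 100,
                         vessel_radius_mm = NULL, vessel_intensity = 140,
                         vessel_curves = NULL,
                         bias_amplitude = 0.1, noise_sigma = 2,
                         rician = FALSE,
                         misalign_translation_mm = 5,
                         misalign_rotation_deg = 5,
                         misalign_scale = 0.03,
                         warp_amplitude_mm = 3,
                         mra_jitter_mm = 0.5,
                         rng_seed = 1) {
  if (vessel_intensity <= wm)
    stop("vessel_intensity must exceed the white-matter intensity")
  if (!(csf < gm && gm < wm)) stop("tissue intensities must satisfy CSF < GM < WM")
  if (min(grid_shape * voxel_mm) < 48)
    stop("grid too small to contain all compartments (need >= 48 mm extent)")
  structure(list(grid_shape = as.integer(grid_shape), voxel_mm = voxel_mm,
                 csf = csf, gm = gm, wm = wm,
                 vessel_radius_mm = vessel_radius_mm,
                 vessel_intensity = vessel_intensity,
                 vessel_curves = vessel_curves,
                 bias_amplitude = bias_amplitude, noise_sigma = noise_sigma,
                 rician = rician,
                 misalign_translation_mm = misalign_translation_mm,
                 misalign_rotation_deg = misalign_rotation_deg,
                 misalign_scale = misalign_scale,
                 warp_amplitude_mm = warp_amplitude_mm,
                 mra_jitter_mm = mra_jitter_mm,
                 rng_seed = rng_seed),
            class = "phantom_spec")
}

phantom_geometry <- function(spec) {
  dm <- spec$grid_shape
  affine <- diag(c(rep(spec$voxel_mm, 3), 1))
  centre <- (dm - 1) / 2 * spec$voxel_mm
  radii <- c(0.36, 0.44, 0.34) * dm * spec$voxel_mm
  list(dm = dm, affine = affine, centre = centre, radii = radii)
}

# normalised ellipsoid radius of world points
ellipsoid_e <- function(x, y, z, geo) {
  sqrt(((x - geo$centre[1]) / geo$radii[1])^2 +
       ((y - geo$centre[2]) / geo$radii[2])^2 +
       ((z - geo$centre[3]) / geo$radii[3])^2)
}

#' Generate the phantom template
#'
#' Builds the artifact-free template volume, its brain mask, and ground-truth
#' tissue labels. Deterministic given `spec$rng_seed`.
#'
#' @param spec a [phantom_spec()].
#' @return a list of class `phantom_template` with elements `t1`
#'   ([bn_volume()]), `brain_mask` ([bn_mask()]), `labels` ([bn_labels()]),
#'   `curves` (vessel polylines, world mm), and `geometry`.
#' @export
generate_template <- function(spec = phantom_spec()) {
  geo <- phantom_geometry(spec)
  ref <- bn_volume(array(0, geo$dm), geo$affine)
  g <- world_grid(ref)
  e <- ellipsoid_e(g$x, g$y, g$z, geo)
  withr_seed(spec$rng_seed, {
    ph <- runif(2, 0, 2 * pi)
  })
  az <- atan2(g$y - geo$centre[2], g$x - geo$centre[1])
  el <- atan2(g$z - geo$centre[3],
              sqrt((g$x - geo$centre[1])^2 + (g$y - geo$centre[2])^2))
  ripple <- 0.035 * sin(6 * az + ph[1]) * cos(4 * el + ph[2])

  lab <- array(0L, geo$dm)
  lab[e <= 1] <- 1L                                  # CSF shell
  lab[e <= 0.88 * (1 + 0.5 * ripple)] <- 2L          # grey-matter ribbon
  lab[e <= 0.62 * (1 + ripple)] <- 3L                # white-matter core

  cx <- geo$centre[1]; cz <- geo$centre[3]
  rx <- geo$radii[1]; rz <- geo$radii[3]
  # longitudinal fissure: midline CSF cleft in the superior half; white
  # matter is kept off the midline above the callosum level so the two
  # hemispheres stay connected inferiorly
  # white matter is kept 6 mm clear of the clefts: fissure and cistern
  # vessels (up to 2-3 mm calibre) must not be bridged to the main
  # white-matter group by partial-volume voxels
  fissure <- abs(g$x - cx) <= 1.5 & g$z > cz & e <= 0.95
  lab[fissure & lab > 0] <- 1L
  wm_carve <- g$z > cz + 0.30 * rz & abs(g$x - cx) <= 6
  lab[wm_carve & lab == 3L] <- 2L
  # Sylvian-like lateral clefts at the mid-axial level
  syl <- abs(g$z - cz) <= 1.5 & abs(g$x - cx) >= 0.35 * rx & e <= 0.92
  lab[syl & lab > 0] <- 1L
  syl_carve <- abs(g$z - cz) <= 6 & abs(g$x - cx) >= 0.35 * rx
  lab[syl_carve & lab == 3L] <- 2L

  t1 <- array(0, geo$dm)
  t1[lab == 1L] <- spec$csf
  t1[lab == 2L] <- spec$gm
  t1[lab == 3L] <- spec$wm
  curves <- if (is.null(spec$vessel_curves)) default_vessel_curves(geo)
            else spec$vessel_curves
  check_curves_inside(curves, geo)
  out <- list(t1 = bn_volume(t1, geo$affine),
              brain_mask = bn_mask(array(as.integer(e <= 1), geo$dm), geo$affine),
              labels = bn_labels(lab, geo$affine),
              curves = curves, geometry = geo, spec = spec)
  class(out) <- "phantom_template"
  out
}

# built-in vessel tree: polylines in world mm, sampled ~1 mm apart. The
# dural sinuses (superior sagittal, transverse) ride the brain surface with
# half the tube protruding past the envelope -- the regime in which bright
# flow artifacts corrupt brain extraction; the remaining vessels run in the
# longitudinal fissure, the Sylvian clefts and along the inferior surface.
# Per-curve tube radii (mm) are attached as an attribute: dural sinuses are
# the thickest structures, fissure and cleft vessels thinner.
default_vessel_curves <- function(geo) {
  cx <- geo$centre[1]; cy <- geo$centre[2]; cz <- geo$centre[3]
  rx <- geo$radii[1]; ry <- geo$radii[2]; rz <- geo$radii[3]
  arc <- function(efrac, deg_from, deg_to, n = 80) {
    phi <- seq(deg_from, deg_to, length.out = n) * pi / 180
    cbind(cx, cy + efrac * ry * cos(phi), cz + efrac * rz * sin(phi))
  }
  # surface arc at constant normalised radius: azimuth sweep at fixed
  # elevation (degrees)
  surf_arc <- function(efrac, az_from, az_to, elev_deg, n = 50) {
    a <- seq(az_from, az_to, length.out = n) * pi / 180
    d <- elev_deg * pi / 180
    cbind(cx + efrac * rx * cos(d) * cos(a),
          cy + efrac * ry * cos(d) * sin(a),
          cz + efrac * rz * sin(d))
  }
  sylvian <- function(side, n = 40) {
    t <- seq(0, 1, length.out = n)
    cbind(cx + side * (0.40 + 0.42 * t) * rx,
          cy + 0.15 * ry * sin(pi * t) + 0.1 * ry * (t - 0.5),
          cz)
  }
  curves <- list(sss = arc(0.995, 30, 150),
                 pericallosal = arc(0.72, 40, 140),
                 sylvian_r = sylvian(1),
                 sylvian_l = sylvian(-1),
                 basilar = arc(0.90, 210, 330),
                 transverse_r = surf_arc(0.98, -90, -15, -32),
                 transverse_l = surf_arc(0.98, -90, -165, -32))
  attr(curves, "radius_mm") <- c(sss = 3, pericallosal = 2, sylvian_r = 2,
                                 sylvian_l = 2, basilar = 2.5,
                                 transverse_r = 3, transverse_l = 3)
  curves
}

check_curves_inside <- function(curves, geo) {
  for (cv in curves) {
    e <- ellipsoid_e(cv[, 1], cv[, 2], cv[, 3], geo)
    if (any(e > 1))
      stop("vessel curve leaves the brain envelope")
  }
  invisible(TRUE)
}

# per-curve tube radii: explicit spec value wins, then radii attached to
# the curve list, then 2 mm
vessel_radii <- function(curves, radius_mm = NULL) {
  if (!is.null(radius_mm)) return(rep(radius_mm, length.out = length(curves)))
  r <- attr(curves, "radius_mm")
  if (is.null(r)) r <- 2
  rep(unname(r), length.out = length(curves))
}

#' Rasterize tubes around polylines
#'
#' Marks every voxel whose centre lies within `radius_mm` (exact
#' point-to-segment distance) of any curve.
#'
#' @param curves list of n-by-3 matrices of world coordinates (mm).
#' @param radius_mm tube radius, scalar or per-curve.
#' @param reference volume defining the grid.
#' @return a [bn_mask()].
#' @export
rasterize_tubes <- function(curves, radius_mm, reference) {
  dm <- dim(reference$data)
  A <- reference$affine
  Ainv <- solve(A)
  mk <- array(FALSE, dm)
  vs <- voxel_sizes(reference)
  radius_mm <- rep(radius_mm, length.out = length(curves))
  for (ci in seq_along(curves)) {
    cv <- curves[[ci]]
    rad <- radius_mm[ci]
    n <- nrow(cv)
    for (s in seq_len(n - 1)) {
      p <- cv[s, ]; q <- cv[s + 1, ]
      lo <- pmin(p, q) - rad; hi <- pmax(p, q) + rad
      # world bbox -> voxel index ranges (axis-aligned affine assumed for
      # the bbox; distances themselves are computed in world coordinates)
      vlo <- floor(Ainv[1:3, 1:3] %*% (lo - A[1:3, 4]))
      vhi <- ceiling(Ainv[1:3, 1:3] %*% (hi - A[1:3, 4]))
      ir <- max(1, vlo[1] + 1):min(dm[1], vhi[1] + 1)
      jr <- max(1, vlo[2] + 1):min(dm[2], vhi[2] + 1)
      kr <- max(1, vlo[3] + 1):min(dm[3], vhi[3] + 1)
      if (length(ir) == 0 || length(jr) == 0 || length(kr) == 0) next
      gi <- expand.grid(i = ir, j = jr, k = kr)
      w <- t(A[1:3, 1:3] %*% t(cbind(gi$i - 1, gi$j - 1, gi$k - 1))) +
        matrix(A[1:3, 4], nrow(gi), 3, byrow = TRUE)
      d2 <- point_segment_dist2(w, p, q)
      hit <- which(d2 <= rad^2)
      if (length(hit) > 0)
        mk[cbind(gi$i[hit], gi$j[hit], gi$k[hit])] <- TRUE
    }
  }
  bn_mask(array(as.integer(mk), dm), A)
}

# squared distance of points (m x 3) to segment p-q
point_segment_dist2 <- function(w, p, q) {
  d <- q - p
  l2 <- sum(d^2)
  if (l2 == 0) {
    diff <- sweep(w, 2, p)
    return(rowSums(diff^2))
  }
  t <- ((w[, 1] - p[1]) * d[1] + (w[, 2] - p[2]) * d[2] +
        (w[, 3] - p[3]) * d[3]) / l2
  t <- pmin(1, pmax(0, t))
  px <- p[1] + t * d[1]; py <- p[2] + t * d[2]; pz <- p[3] + t * d[3]
  (w[, 1] - px)^2 + (w[, 2] - py)^2 + (w[, 3] - pz)^2
}

#' Generate one phantom subject
#'
#' Applies a random affine + smooth nonlinear misalignment, a multiplicative
#' bias field and noise to the template, and rasterizes bright vessel
#' artifacts along the template vessel tree. The subject is produced by
#' pulling the template back through the truth transform, so the returned
#' `truth_affine` / `truth_warp` align the template with the subject exactly
#' (up to interpolation).
#'
#' @param spec a [phantom_spec()].
#' @param template a `phantom_template` from [generate_template()].
#' @param seed per-subject seed (defaults to `spec$rng_seed`).
#' @return a list of class `phantom_subject`: `t1_bloody`, `t1_clean`
#'   (volumes), `truth_blood_mask`, `brain_mask` (masks), `truth_affine`
#'   ([bn_affine()], template to subject), `truth_warp` ([bn_defield()] on
#'   the subject grid), `truth_labels`, `truth_bias` (multiplicative field
#'   as applied), and `seed`.
#' @export
generate_subject <- function(spec, template, seed = spec$rng_seed) {
  geo <- template$geometry
  ref <- bn_volume(array(0, geo$dm), geo$affine)
  pars <- NULL
  withr_seed(seed, {
    pars <- list(
      tr = runif(3, -spec$misalign_translation_mm, spec$misalign_translation_mm),
      rot = runif(3, -spec$misalign_rotation_deg, spec$misalign_rotation_deg),
      sc = runif(3, 1 - spec$misalign_scale, 1 + spec$misalign_scale),
      warp = random_smooth_field(geo, spec$warp_amplitude_mm),
      bias = random_bias_field(geo, spec$bias_amplitude),
      noise = if (spec$noise_sigma > 0)
        array(rnorm(prod(geo$dm), 0, spec$noise_sigma), geo$dm) else 0,
      noise2 = if (spec$rician && spec$noise_sigma > 0)
        array(rnorm(prod(geo$dm), 0, spec$noise_sigma), geo$dm) else NULL)
  })
  truth_affine <- make_affine(pars$tr, pars$rot, pars$sc, geo$centre)
  truth_warp <- bn_defield(pars$warp, geo$affine)
  jd <- jacobian_raw_det(truth_warp)
  if (min(jd) <= 0)
    stop("warp_amplitude_mm too large: truth deformation is non-invertible")
  truth <- bn_transform(truth_affine, truth_warp)

  tube <- rasterize_tubes(template$curves,
                          vessel_radii(template$curves, spec$vessel_radius_mm),
                          ref)
  t1v <- template$t1$data
  t1v[tube$data == 1] <- spec$vessel_intensity

  clean <- resample(template$t1, truth, ref)
  bloody <- resample(bn_volume(t1v, geo$affine), truth, ref)
  add_noise <- function(a) {
    a <- a * pars$bias
    if (spec$rician && !is.null(pars$noise2))
      sqrt((a + pars$noise)^2 + pars$noise2^2)
    else
      a + pars$noise
  }
  out <- list(t1_bloody = bn_volume(add_noise(bloody$data), geo$affine),
              t1_clean = bn_volume(add_noise(clean$data), geo$affine),
              truth_blood_mask = resample(tube, truth, ref),
              brain_mask = resample(template$brain_mask, truth, ref),
              truth_labels = resample(template$labels, truth, ref),
              truth_affine = truth_affine, truth_warp = truth_warp,
              truth_bias = pars$bias, seed = seed)
  class(out) <- "phantom_subject"
  out
}

#' Simulate an MR-angiography cohort in template space
#'
#' Each volume is bright along a rigidly jittered copy of the template
#' vessel tree (Gaussian per-curve offsets, SD `spec$mra_jitter_mm`), lightly
#' blurred, and dark elsewhere. Input for
#' [build_blood_probability_map()].
#'
#' @param spec a [phantom_spec()].
#' @param template a `phantom_template`.
#' @param n number of volumes (>= 1).
#' @param seed cohort seed.
#' @return list of `n` [bn_volume()]s on the template grid, values >= 0.
#' @export
generate_mra_cohort <- function(spec, template, n, seed = spec$rng_seed) {
  if (n < 1) stop("n must be >= 1")
  geo <- template$geometry
  ref <- bn_volume(array(0, geo$dm), geo$affine)
  out <- vector("list", n)
  withr_seed(seed, {
    for (i in seq_len(n)) {
      curves <- lapply(template$curves, function(cv) {
        off <- rnorm(3, 0, spec$mra_jitter_mm)
        sweep(cv, 2, -off)
      })
      tube <- rasterize_tubes(curves,
                              vessel_radii(template$curves, spec$vessel_radius_mm),
                              ref)
      v <- smooth3d(100 * tube$data, fwhm_to_sigma(1), voxel_sizes(ref))
      out[[i]] <- bn_volume(v, geo$affine)
    }
  })
  out
}

#' Simulate a phantom study cohort
#'
#' Generates `n` subjects from one template with per-subject seeds
#' `seed + 1, ..., seed + n`.
#'
#' @param spec a [phantom_spec()].
#' @param template a `phantom_template`.
#' @param n cohort size.
#' @param seed base seed.
#' @return named list of `phantom_subject`s.
#' @export
simulate_cohort <- function(spec, template, n, seed = spec$rng_seed) {
  out <- lapply(seq_len(n), function(i)
    generate_subject(spec, template, seed = seed + i))
  names(out) <- sprintf("phantom%02d", seq_len(n))
  out
}

# smooth random vector field with peak magnitude amp_mm: low-resolution
# Gaussian noise upsampled and smoothed, rescaled to the target amplitude
random_smooth_field <- function(geo, amp_mm) {
  dm <- geo$dm
  if (amp_mm <= 0) return(array(0, c(dm, 3)))
  u <- array(0, c(dm, 3))
  coarse_dm <- c(5L, 5L, 5L)
  for (cmp in 1:3) {
    coarse <- array(rnorm(prod(coarse_dm)), coarse_dm)
    m <- diag(c((coarse_dm - 1) / (dm - 1), 1))
    fine <- array(cpp_resample(as.numeric(coarse), coarse_dm, dm, m, diag(4),
                               NULL, 2L), dm)
    u[, , , cmp] <- smooth3d(fine, 6, rep(geo$affine[1, 1], 3))
  }
  peak <- max(sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2))
  if (peak > 0) u <- u * (amp_mm / peak)
  u
}

# multiplicative bias: product of per-axis degree-2 polynomials, each scaled
# to +-(amplitude/3) so the product stays near +-amplitude
random_bias_field <- function(geo, amplitude) {
  dm <- geo$dm
  if (amplitude <= 0) return(array(1, dm))
  axis_poly <- function(n) {
    t <- seq(-1, 1, length.out = n)
    cf <- rnorm(3)
    p <- cf[1] + cf[2] * t + cf[3] * t^2
    p <- p - mean(p)
    m <- max(abs(p))
    if (m > 0) p <- p / m
    1 + (amplitude / 3) * p
  }
  px <- axis_poly(dm[1]); py <- axis_poly(dm[2]); pz <- axis_poly(dm[3])
  outer(outer(px, py), pz)
}

# run code with a local RNG state
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(code))
}
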