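test_that("template generation is deterministic and contains all compartments", {
  spec <- small_spec()
  t1 <- generate_template(spec)
  t2 <- generate_template(spec)
  expect_identical(t1$t1$data, t2$t1$data)
  expect_identical(t1$labels$data, t2$labels$data)
  counts <- table(factor(t1$labels$data, levels = 0:3))
  expect_true(all(counts > 0))
  # WM voxels carry the specified WM intensity (template is noise-free)
  expect_equal(mean(t1$t1$data[t1$labels$data == 3L]), 100)
  expect_error(phantom_spec(grid_shape = c(20, 20, 20)), "too small")
  expect_error(phantom_spec(vessel_intensity = 90), "exceed")
})

test_that("identity configuration reproduces the template exactly", {
  spec <- identity_spec()
  tpl <- generate_template(spec)
  s <- generate_subject(spec, tpl, seed = 1)
  expect_identical(s$t1_clean$data, tpl$t1$data)
  # bloody differs from clean exactly on the truth blood mask support
  diffsupp <- which(s$t1_bloody$data != s$t1_clean$data)
  expect_identical(sort(diffsupp), which(s$truth_blood_mask$data == 1L))
})

test_that("tube rasterisation matches a brute-force distance oracle", {
  ref <- bn_volume(array(0, c(16, 16, 16)))
  curve <- cbind(c(3, 8, 12), c(4, 8, 11), c(5, 8, 10))
  got <- rasterize_tubes(list(curve), 1.6, ref)
  oracle <- array(0L, c(16, 16, 16))
  for (k in 0:15) for (j in 0:15) for (i in 0:15) {
    p <- c(i, j, k)
    dmin <- Inf
    for (s in 1:2) {
      a <- curve[s, ]; b <- curve[s + 1, ]
      t <- sum((p - a) * (b - a)) / sum((b - a)^2)
      t <- min(1, max(0, t))
      dmin <- min(dmin, sqrt(sum((p - a - t * (b - a))^2)))
    }
    if (dmin <= 1.6) oracle[i + 1, j + 1, k + 1] <- 1L
  }
  expect_identical(got$data, oracle)
})

test_that("subject generation is deterministic and returns exact truth transforms", {
  spec <- small_spec(noise_sigma = 0)
  tpl <- generate_template(spec)
  s1 <- generate_subject(spec, tpl, seed = 9)
  s2 <- generate_subject(spec, tpl, seed = 9)
  expect_identical(s1$t1_bloody$data, s2$t1_bloody$data)
  expect_identical(s1$truth_affine$mat, s2$truth_affine$mat)
  # applying the truth transform to the template matches the clean subject
  realigned <- resample(tpl$t1, bn_transform(s1$truth_affine, s1$truth_warp),
                        tpl$t1)
  ncc <- cor(as.numeric(realigned$data), as.numeric(s1$t1_clean$data))
  expect_gte(ncc, 0.98)
  # the truth warp is invertible by construction
  expect_gt(min(deblood:::jacobian_raw_det(s1$truth_warp)), 0)
  expect_error(
    generate_subject(small_spec(warp_amplitude_mm = 60, noise_sigma = 0),
                     tpl, seed = 1),
    "non-invertible")
})

test_that("MRA cohort volumes are bright on the jittered tree, dark elsewhere", {
  spec <- small_spec()
  tpl <- generate_template(spec)
  expect_error(generate_mra_cohort(spec, tpl, 0), ">= 1")
  # jitter 0 -> identical volumes
  spec0 <- small_spec(mra_jitter_mm = 0)
  tpl0 <- generate_template(spec0)
  m0 <- generate_mra_cohort(spec0, tpl0, 3, seed = 2)
  expect_identical(m0[[1]]$data, m0[[2]]$data)
  expect_identical(m0[[2]]$data, m0[[3]]$data)
  # n = 1: averaging reproduces it up to normalisation
  one <- generate_mra_cohort(spec, tpl, 1, seed = 3)
  bpm <- build_blood_probability_map(one)
  expect_lt(max(abs(bpm$data - one[[1]]$data / max(one[[1]]$data))), 1e-12)
  # union of bright supports contains the unjittered tree
  mras <- generate_mra_cohort(spec, tpl, 4, seed = 4)
  tube <- rasterize_tubes(tpl$curves,
                          deblood:::vessel_radii(tpl$curves,
                                                 spec$vessel_radius_mm),
                          tpl$t1)
  bright <- Reduce(`|`, lapply(mras, function(v) v$data > 20))
  expect_gte(mean(bright[tube$data == 1]), 0.95)
})

test_that("truth blood mask equals the tube rasterisation under identity alignment", {
  spec <- identity_spec()
  tpl <- generate_template(spec)
  s <- generate_subject(spec, tpl, seed = 1)
  tube <- rasterize_tubes(tpl$curves,
                          deblood:::vessel_radii(tpl$curves,
                                                 spec$vessel_radius_mm),
                          tpl$t1)
  expect_identical(s$truth_blood_mask$data, tube$data)
})

test_that("vessel curves stay inside the brain envelope", {
  spec <- small_spec()
  tpl <- generate_template(spec)
  geo <- tpl$geometry
  for (cv in tpl$curves) {
    e <- deblood:::ellipsoid_e(cv[, 1], cv[, 2], cv[, 3], geo)
    expect_lte(max(e), 1)
  }
  bad <- list(cbind(c(0, 1), c(0, 1), c(0, 1)))
  expect_error(generate_template(small_spec(vessel_curves = bad)),
               "envelope")
})
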