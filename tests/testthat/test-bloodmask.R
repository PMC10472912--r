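test_that("gradient magnitude matches constants, ramps and a convolution oracle", {
  const <- bn_volume(array(7, c(10, 10, 10)))
  expect_equal(max(gradient_magnitude(const, 1)$data), 0)
  # linear ramp of slope k along x: interior gradient ~ k
  k <- 2.5
  ramp <- bn_volume(array(rep(k * (0:15), times = 16 * 16), c(16, 16, 16)))
  g <- gradient_magnitude(ramp, 1)
  expect_lt(max(abs(g$data[5:12, 5:12, 5:12] - k) / k), 0.01)
  # random volume vs explicit convolution + central difference oracle
  set.seed(13)
  v <- random_volume(c(16, 16, 16), seed = 13)
  got <- gradient_magnitude(v, 1)$data
  sm <- deblood:::smooth3d(v$data, deblood:::fwhm_to_sigma(1), c(1, 1, 1))
  d1 <- deblood:::array_deriv(sm, 1, 1)
  d2 <- deblood:::array_deriv(sm, 2, 1)
  d3 <- deblood:::array_deriv(sm, 3, 1)
  oracle <- sqrt(d1^2 + d2^2 + d3^2)
  expect_lt(max(abs(got - oracle)), 1e-12)
  expect_error(gradient_magnitude(const, 0), "positive")
})

test_that("gradient difference map highlights vessels on the phantom", {
  id <- random_volume(c(10, 10, 10), seed = 14)
  g <- bn_volume(abs(id$data), id$affine)
  zero_diff <- gradient_difference_map(g, g, 2)
  expect_lt(max(abs(zero_diff$data)), 1e-12)
  z <- bn_volume(array(0, dim(g$data)))
  blur_only <- gradient_difference_map(g, z, 2)
  expect_equal(blur_only$data,
               deblood:::smooth3d(g$data, deblood:::fwhm_to_sigma(2), c(1, 1, 1)))
  # phantom: mean over the truth blood mask exceeds mean over true WM interior
  s <- small_subject(5)
  tpl <- small_template()
  sg <- gradient_magnitude(s$t1_bloody, 1)
  tg <- resample(gradient_magnitude(tpl$t1, 1),
                 bn_transform(s$truth_affine, s$truth_warp), tpl$t1)
  gd <- gradient_difference_map(sg, tg, 2)
  tube <- s$truth_blood_mask$data == 1
  wm_interior <- deblood:::mask_erode(truth_main_wm(s), 2, 6)$data == 1
  expect_gt(mean(gd$data[tube]), mean(gd$data[wm_interior]))
})

test_that("white-matter grouping finds the largest component with stable tie-breaks", {
  dm <- c(12, 12, 12)
  lab <- bn_labels(array(0L, dm))
  lab$data[2:6, 2:6, 2:6] <- 3L           # 125-voxel blob
  g1 <- group_white_matter(lab, 26)
  expect_equal(length(g1$counts), 1)
  expect_equal(g1$main_group_id, 1)
  lab$data[10:11, 10:11, 10] <- 3L        # second, smaller blob
  g2 <- group_white_matter(lab, 26)
  expect_equal(sort(g2$counts, decreasing = TRUE), c(125, 4))
  expect_equal(g2$counts[g2$main_group_id], 125)
  # flood-fill oracle on a random sprinkle
  set.seed(15)
  lab3 <- bn_labels(array(3L * rbinom(prod(dm), 1, 0.2), dm))
  if (sum(lab3$data) > 0) {
    g3 <- group_white_matter(lab3, 26)
    expect_equal(sum(g3$counts), sum(lab3$data == 3L))
    expect_equal(max(g3$counts), g3$counts[g3$main_group_id])
  }
  # equal blobs: main is the one containing the smallest linear index
  lab4 <- bn_labels(array(0L, dm))
  lab4$data[2:3, 2, 2] <- 3L
  lab4$data[8:9, 8, 8] <- 3L
  g4 <- group_white_matter(lab4, 26)
  expect_equal(g4$main_group_id, 1)
  expect_true(g4$component[2, 2, 2] == g4$main_group_id)
  expect_error(group_white_matter(bn_labels(array(0L, dm))), "no white-matter")
})

test_that("seeding requires all four pieces of evidence", {
  # study-scale subject: at smoke scale partial-volume bridges join the
  # cleft vessels to the main white-matter group, which is exactly the case
  # the recovery stage (not seeding) is for
  s <- study_subject(5)
  tpl <- study_template()
  cfg <- bn_config()
  labels <- classify_tissue(s$t1_bloody, s$brain_mask)
  grouping <- group_white_matter(labels, cfg$wm_connectivity)
  sg <- gradient_magnitude(s$t1_bloody, 1)
  tg <- resample(gradient_magnitude(tpl$t1, 1),
                 bn_transform(s$truth_affine, s$truth_warp), tpl$t1)
  gd <- gradient_difference_map(sg, tg, 2)
  # perfectly aligned blood probability: the truth tube blurred a little
  dmv <- dim(s$truth_blood_mask$data)
  bpm <- bn_probmap(array(pmin(1, deblood:::smooth3d(
    array(as.numeric(s$truth_blood_mask$data), dmv),
    1, c(1, 1, 1)) * 3), dmv), s$t1_bloody$affine)
  seeds <- seed_blood_voxels(labels, grouping, gd, bpm, s$brain_mask, cfg)
  tube <- s$truth_blood_mask$data == 1
  expect_gte(sum(seeds$data == 1 & tube) / sum(tube), 0.5)
  # heuristic (i): zero blood probability gates everything
  bpm0 <- bn_probmap(array(0, dim(bpm$data)), bpm$affine)
  expect_equal(sum(seed_blood_voxels(labels, grouping, gd, bpm0,
                                     s$brain_mask, cfg)$data), 0)
  # main-group WM voxels are never seeded
  main <- grouping$component == grouping$main_group_id
  expect_equal(sum(seeds$data == 1 & main), 0)
  ex <- expand_blood_mask(seeds, labels, grouping, gd, bpm, s$brain_mask, cfg)
  expect_true(all(ex$data >= seeds$data))
  expect_gte(sum(ex$data == 1 & tube), sum(seeds$data == 1 & tube))
  expect_equal(sum(ex$data == 1 & main), 0)
})

test_that("expansion fixed points behave as documented", {
  s <- small_subject(5)
  cfg <- bn_config()
  empty <- bn_mask(array(0L, dim(s$t1_bloody$data)), s$t1_bloody$affine)
  labels <- classify_tissue(s$t1_bloody, s$brain_mask)
  grouping <- group_white_matter(labels)
  gd <- bn_volume(array(0, dim(s$t1_bloody$data)), s$t1_bloody$affine)
  bpm0 <- bn_probmap(array(0, dim(gd$data)), gd$affine)
  out <- expand_blood_mask(empty, labels, grouping, gd, bpm0, s$brain_mask, cfg)
  expect_equal(sum(out$data), 0)
  # nothing eligible: expansion returns the seed unchanged
  seed1 <- empty
  seed1$data[24, 24, 24] <- 1L
  out1 <- expand_blood_mask(seed1, labels, grouping, gd, bpm0, s$brain_mask, cfg)
  expect_identical(out1$data, seed1$data)
})

test_that("main-group recovery adds only qualified main-group voxels", {
  s <- small_subject(5)
  cfg <- bn_config()
  labels <- classify_tissue(s$t1_bloody, s$brain_mask)
  grouping <- group_white_matter(labels)
  gd <- bn_volume(array(1, dim(s$t1_bloody$data)), s$t1_bloody$affine)
  cur <- bn_mask(array(0L, dim(gd$data)), gd$affine)
  # probability below threshold everywhere: unchanged
  low <- bn_probmap(array(0.1, dim(gd$data)), gd$affine)
  r1 <- recover_main_group_blood(grouping, low, gd, cur, s$brain_mask, cfg)
  expect_identical(r1$data, cur$data)
  # high probability on a main-group voxel: recovered; output is a superset
  hi <- bn_probmap(array(0, dim(gd$data)), gd$affine)
  mg <- which(grouping$component == grouping$main_group_id)[1]
  hi$data[mg] <- 0.9
  r2 <- recover_main_group_blood(grouping, hi, gd, cur, s$brain_mask, cfg)
  expect_equal(r2$data[mg], 1L)
  expect_true(all(r2$data >= cur$data))
})

test_that("refine and trim obey their mask algebra", {
  dm <- c(24, 24, 24)
  brain <- bn_mask(array(0L, dm))
  brain$data[2:23, 2:23, 2:23] <- 1L
  blood <- bn_mask(array(0L, dm))
  expect_identical(refine_brain_mask(brain, blood)$data, brain$data)
  blood$data[12, 12, 12] <- 1L
  r <- refine_brain_mask(brain, blood)
  expect_equal(r$data[12, 12, 12], 0L)
  expect_equal(sum(r$data), sum(brain$data) - 1)
  expect_error(refine_brain_mask(brain, brain), "empty")
  # random masks vs a boolean oracle
  set.seed(16)
  for (i in 1:3) {
    a <- random_mask(c(10, 10, 10), seed = 300 + i, p = 0.9)
    b <- random_mask(c(10, 10, 10), seed = 400 + i, p = 0.2)
    r2 <- refine_brain_mask(a, b)
    expect_identical(r2$data,
                     array(as.integer(a$data == 1 & b$data == 0), c(10, 10, 10)))
  }
  # interior blood never changes the trimmed mask; output is a subset
  t1 <- trim_brain_mask_periphery(brain, blood)
  expect_identical(t1$data, brain$data)
  expect_true(all(trim_brain_mask_periphery(brain, blood)$data <= brain$data))
})

test_that("a blood bump protruding through the brain surface is trimmed away", {
  # sphere with a tube sticking 5 voxels out of the surface plus an
  # interior blood blob: the protruding part must go, interior blood and
  # the smooth surface must stay
  dm <- c(64, 64, 64)
  g <- expand.grid(i = 0:63, j = 0:63, k = 0:63)
  sph <- array((g$i - 32)^2 + (g$j - 32)^2 + (g$k - 32)^2 <= 22^2, dm)
  bump <- array((g$i - 32)^2 + (g$j - 32)^2 <= 9 & g$k >= 32 &
                (g$k - 32) <= 27, dm)
  brain <- bn_mask(array(as.integer(sph | bump), dm))
  blood <- bn_mask(array(as.integer(bump & !sph), dm))
  blood$data[31:33, 31:33, 31:33] <- 1L
  tr <- trim_brain_mask_periphery(brain, blood)
  protr <- bump & !sph
  expect_lt(sum(tr$data == 1 & protr) / sum(protr), 0.25)
  expect_equal(sum(tr$data[31:33, 31:33, 31:33]), 27)  # interior blood kept
  expect_equal(sum(sph & tr$data == 0), 0)             # surface untouched
})
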