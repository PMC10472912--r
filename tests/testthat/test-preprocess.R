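test_that("brain extraction recovers the phantom envelope", {
  s <- small_subject(5)
  m <- extract_brain_mask(s$t1_bloody)
  expect_gte(dice(m, s$brain_mask), 0.95)
  # one 26-connected component
  lab <- deblood:::mask_components(m, 26)
  expect_equal(max(lab), 1)
  expect_error(extract_brain_mask(bn_volume(array(0, c(8, 8, 8)))),
               "empty foreground")
})

test_that("nonuniformity correction leaves unbiased data untouched and removes known bias", {
  spec <- small_spec(bias_amplitude = 0, noise_sigma = 0)
  tpl <- generate_template(spec)
  subj0 <- generate_subject(spec, tpl, seed = 3)
  mask <- subj0$brain_mask
  out0 <- correct_nonuniformity(subj0$t1_clean, mask)
  inm <- mask$data == 1 & subj0$t1_clean$data > 0
  rel <- abs(out0$data[inm] - subj0$t1_clean$data[inm]) /
    subj0$t1_clean$data[inm]
  expect_lt(max(rel), 0.01)
  # +-10% degree-2 bias: the estimated field matches the generator's truth
  # field within 3% over the white matter (up to a global scale)
  specb <- small_spec(bias_amplitude = 0.1, noise_sigma = 0)
  subb <- generate_subject(specb, generate_template(specb), seed = 4)
  outb <- correct_nonuniformity(subb$t1_bloody, subb$brain_mask)
  wm <- subb$truth_labels$data == 3L
  ratio <- attr(outb, "bias_field")[wm] / subb$truth_bias[wm]
  expect_lt(max(abs(ratio / mean(ratio) - 1)), 0.03)
  # corrected WM is at least as uniform as the input WM
  cv <- function(x) sd(x) / mean(x)
  expect_lte(cv(outb$data[wm]), cv(subb$t1_bloody$data[wm]))
  # idempotence within tolerance
  out2 <- correct_nonuniformity(outb, subb$brain_mask)
  expect_lt(max(abs(out2$data[wm] - outb$data[wm]) / outb$data[wm]), 0.01)
})

test_that("intensity normalisation matches percentiles and preserves ordering", {
  s <- small_subject(5)
  mask <- s$brain_mask
  t1 <- s$t1_bloody
  # reference = input -> identity
  idn <- normalize_intensity(t1, mask, t1, mask)
  expect_lt(max(abs(idn$data - t1$data)), 1e-9)
  # input scaled by 2 -> percentiles restored
  doubled <- bn_volume(2 * t1$data, t1$affine)
  nrm <- normalize_intensity(doubled, mask, t1, mask)
  sp <- quantile(nrm$data[mask$data == 1], c(0.1, 0.9))
  rp <- quantile(t1$data[mask$data == 1], c(0.1, 0.9))
  expect_lt(max(abs(sp - rp)), 1e-6)
  # linear map preserves intensity ordering
  o1 <- order(t1$data[mask$data == 1])
  o2 <- order(nrm$data[mask$data == 1])
  expect_identical(o1, o2)
  flat <- bn_volume(array(1, dim(t1$data)), t1$affine)
  expect_error(normalize_intensity(flat, mask, t1), "zero intensity spread")
})

test_that("tissue classification recovers the phantom labels and is deterministic", {
  spec <- identity_spec()
  tpl <- generate_template(spec)
  s <- generate_subject(spec, tpl, seed = 2)
  lab <- classify_tissue(s$t1_bloody, s$brain_mask, seed = 1)
  # tissue accuracy is judged away from the vessels: bright artifact voxels
  # deliberately classify as WM whatever tissue they overlie
  inm <- s$brain_mask$data == 1
  novessel <- inm & s$truth_blood_mask$data == 0
  acc <- mean(lab$data[novessel] == s$truth_labels$data[novessel])
  expect_gte(acc, 0.99)
  # bright vessel voxels land in the top (WM) component
  tube <- s$truth_blood_mask$data == 1 & inm
  expect_gte(mean(lab$data[tube] == 3L), 0.95)
  # component means strictly increasing
  fit <- attr(lab, "fit")
  expect_true(all(diff(fit$means) > 0))
  lab2 <- classify_tissue(s$t1_bloody, s$brain_mask, seed = 1)
  expect_identical(lab$data, lab2$data)
  expect_error(classify_tissue(bn_volume(array(1, c(4, 4, 4))),
                               bn_mask(array(1L, c(4, 4, 4)))),
               "distinct intensity levels")
})

test_that("csf_mean is the arithmetic mean over CSF labels", {
  dm <- c(4, 4, 4)
  lab <- bn_labels(array(0L, dm))
  t1 <- bn_volume(array(0, dm))
  lab$data[1:2, 1, 1] <- 1L
  t1$data[1, 1, 1] <- 20; t1$data[2, 1, 1] <- 40
  expect_equal(csf_mean(t1, lab), 30)
  t1$data[1:2, 1, 1] <- 30
  expect_equal(csf_mean(t1, lab), 30)
  lab$data[] <- 0L
  expect_error(csf_mean(t1, lab), "no CSF")
  # phantom CSF mean within sampling error of the specification value
  # (aligned noisy phantom: no partial-volume mixing to bias the estimate)
  spec <- phantom_spec(grid_shape = c(48, 48, 48), vessel_radius_mm = 1.5,
                       noise_sigma = 2, bias_amplitude = 0,
                       misalign_translation_mm = 0, misalign_rotation_deg = 0,
                       misalign_scale = 0, warp_amplitude_mm = 0)
  s <- generate_subject(spec, generate_template(spec), seed = 7)
  labs <- classify_tissue(s$t1_bloody, s$brain_mask)
  est <- csf_mean(s$t1_bloody, labs)
  n_csf <- sum(labs$data == 1L)
  expect_lt(abs(est - 30), 1)
  expect_gt(n_csf, 1000)
})
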