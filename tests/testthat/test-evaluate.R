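test_that("dice matches the direct count formula", {
  dm <- c(8, 8, 8)
  m <- random_mask(dm, seed = 1)
  expect_equal(dice(m, m), 1)
  a <- bn_mask(array(0L, dm)); a$data[1:2, 1, 1] <- 1L
  b <- bn_mask(array(0L, dm)); b$data[5:6, 5, 5] <- 1L
  expect_equal(dice(a, b), 0)
  # |a|=4, |b|=6, |intersection|=3 -> 0.6
  a2 <- bn_mask(array(0L, dm)); a2$data[1:4, 1, 1] <- 1L
  b2 <- bn_mask(array(0L, dm)); b2$data[2:7, 1, 1] <- 1L
  expect_equal(dice(a2, b2), 0.6)
  # both empty -> 1 by definition
  e <- bn_mask(array(0L, dm))
  expect_equal(dice(e, e), 1)
  # random pairs vs the formula, and symmetry
  for (s in 1:5) {
    x <- random_mask(dm, seed = 100 + s)
    y <- random_mask(dm, seed = 200 + s)
    expected <- 2 * sum(x$data & y$data) / (sum(x$data) + sum(y$data))
    expect_identical(dice(x, y), expected)
    expect_identical(dice(x, y), dice(y, x))
  }
})

test_that("mutual information matches an explicit joint-histogram oracle", {
  dm <- c(8, 8, 8)
  set.seed(31)
  a <- random_volume(dm, seed = 31)
  b <- random_volume(dm, seed = 32)
  mask <- random_mask(dm, seed = 33, p = 0.8)
  for (bins in c(8, 16, 64)) {
    got <- mutual_information(a, b, mask, bins)
    av <- a$data[mask$data == 1]; bv <- b$data[mask$data == 1]
    cut_idx <- function(x, bins) {
      i <- 1L + as.integer((x - min(x)) / (max(x) - min(x)) * bins)
      pmin(i, bins)
    }
    h <- table(factor(cut_idx(av, bins), levels = 1:bins),
               factor(cut_idx(bv, bins), levels = 1:bins))
    p <- h / sum(h)
    pa <- rowSums(p); pb <- colSums(p)
    expected <- 0
    for (i in 1:bins) for (j in 1:bins)
      if (p[i, j] > 0)
        expected <- expected + p[i, j] * log(p[i, j] / (pa[i] * pb[j]))
    expect_equal(got, as.numeric(expected), tolerance = 1e-12)
  }
})

test_that("MI of a volume with itself equals its histogram entropy", {
  a <- random_volume(c(8, 8, 8), seed = 41)
  bins <- 16
  got <- mutual_information(a, a, bins = bins)
  x <- as.numeric(a$data)
  i <- pmin(1L + as.integer((x - min(x)) / (max(x) - min(x)) * bins), bins)
  p <- tabulate(i, bins) / length(x)
  expect_equal(got, -sum(p[p > 0] * log(p[p > 0])), tolerance = 1e-12)
})

test_that("MI of independently shuffled volumes is near zero and MI is symmetric", {
  set.seed(51)
  n <- 64^3
  a <- bn_volume(array(runif(n), c(64, 64, 64)))
  b <- bn_volume(array(runif(n), c(64, 64, 64)))
  expect_lte(mutual_information(a, b, bins = 64), 0.02)
  s <- random_volume(c(8, 8, 8), seed = 52)
  t <- random_volume(c(8, 8, 8), seed = 53)
  expect_equal(mutual_information(s, t, bins = 8),
               mutual_information(t, s, bins = 8), tolerance = 1e-12)
  expect_error(mutual_information(bn_volume(array(1, c(8, 8, 8))), s),
               "distinct")
})

test_that("paired t-test matches the closed form and its limits", {
  # d = (1, 2, 3): t = 2 * sqrt(3)
  r <- paired_t_test(c(0, 0, 0), c(1, 2, 3))
  expect_equal(r$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$p, 2 * stats::pt(-2 * sqrt(3), df = 2), tolerance = 1e-12)
  # x == y -> t = 0, p = 1
  r0 <- paired_t_test(1:4, 1:4)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  # constant non-zero differences: the zero-variance limit
  rc <- paired_t_test(c(0, 0, 0, 0), c(1, 1, 1, 1))
  expect_identical(rc$t, Inf)
  expect_identical(rc$p, 0)
  # antisymmetry
  set.seed(61)
  x <- rnorm(10); y <- rnorm(10)
  f <- paired_t_test(x, y); g <- paired_t_test(y, x)
  expect_equal(f$t, -g$t)
  expect_equal(f$p, g$p)
  expect_error(paired_t_test(1, 1), "at least 2")
  expect_error(paired_t_test(1:3, 1:4), "equal length")
})

test_that("max_map is the voxelwise maximum", {
  v <- random_volume(c(6, 6, 6), seed = 71)
  expect_identical(max_map(list(v))$data, v$data)
  neg <- bn_volume(-v$data, v$affine)
  expect_identical(max_map(list(v, neg))$data, abs(v$data))
  vs <- lapply(1:4, function(i) random_volume(c(6, 6, 6), seed = 80 + i))
  oracle <- array(apply(simplify2array(lapply(vs, `[[`, "data")), 1:3, max),
                  c(6, 6, 6))
  expect_identical(max_map(vs)$data, oracle)
})

test_that("cohort summary has the four-metric structure", {
  evals <- data.frame(
    subject_id = c("a", "b", "c"),
    dice_lin_bloody = c(0.93, 0.94, 0.935),
    dice_lin_deblooded = c(0.95, 0.955, 0.952),
    mi_lin_bloody = c(0.014, 0.015, 0.013),
    mi_lin_deblooded = c(0.019, 0.02, 0.018),
    dice_nl_bloody = c(0.96, 0.965, 0.962),
    dice_nl_deblooded = c(0.979, 0.98, 0.978),
    mi_nl_bloody = c(0.05, 0.055, 0.052),
    mi_nl_deblooded = c(0.07, 0.071, 0.069))
  s <- cohort_summary(evals)
  expect_equal(nrow(s), 4)
  expect_equal(s$metric, c("linear_mask_dice", "linear_similarity_mi",
                           "nonlinear_mask_dice", "nonlinear_similarity_mi"))
  expect_true(all(c("bloody_mean", "bloody_var", "deblooded_mean",
                    "deblooded_var", "t", "p") %in% names(s)))
  expect_true(all(s$deblooded_mean > s$bloody_mean))
  expect_error(cohort_summary(evals[1, ]), "at least 2")
})
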