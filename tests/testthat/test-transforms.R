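test_that("resampling matches a brute-force pull-back oracle on random affines", {
  set.seed(11)
  v <- random_volume(c(8, 8, 8), seed = 11)
  t <- make_affine(translation = runif(3, -2, 2), rotation = runif(3, -10, 10),
                   scale = runif(3, 0.9, 1.1), centre = c(3.5, 3.5, 3.5))
  out <- resample(v, t, v)
  # independent per-voxel oracle: invert, map, trilinear by hand
  Minv <- solve(t$mat)
  oracle <- array(0, c(8, 8, 8))
  for (k in 0:7) for (j in 0:7) for (i in 0:7) {
    p <- Minv %*% c(i, j, k, 1)
    x <- p[1]; y <- p[2]; z <- p[3]
    if (x < 0 || y < 0 || z < 0 || x > 7 || y > 7 || z > 7) next
    x0 <- min(floor(x), 6); y0 <- min(floor(y), 6); z0 <- min(floor(z), 6)
    fx <- x - x0; fy <- y - y0; fz <- z - z0
    acc <- 0
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
           (if (dz) fz else 1 - fz)
      acc <- acc + w * v$data[x0 + dx + 1, y0 + dy + 1, z0 + dz + 1]
    }
    oracle[i + 1, j + 1, k + 1] <- acc
  }
  expect_lt(max(abs(out$data - oracle)), 1e-6)
})

test_that("identity resampling is exact and integer shifts move a delta", {
  m <- random_mask(c(8, 8, 8), seed = 2)
  expect_identical(resample(m, bn_affine(), m)$data, m$data)
  d <- bn_volume(array(0, c(8, 8, 8)))
  d$data[4, 4, 4] <- 1
  moved <- resample(d, make_affine(c(1, 0, 0)), d, interp = "nearest")
  expect_equal(moved$data[5, 4, 4], 1)
  expect_equal(sum(moved$data), 1)
  expect_error(resample(m, bn_affine(), m, interp = "linear"),
               "not allowed")
})

test_that("composition behaves as sequential application", {
  t <- make_affine(c(1, 2, 3), c(5, 0, -5), c(1.02, 1, 0.97), centre = c(4, 4, 4))
  idc <- compose_transforms(bn_affine(), t)
  expect_equal(idc$affine$mat, t$mat)
  inv <- compose_transforms(t, invert_affine(t))
  expect_lt(max(abs(inv$affine$mat - diag(4))), 1e-10)
  net <- compose_transforms(make_affine(c(1, 0, 0)), make_affine(c(0, 2, 0)))
  expect_equal(net$affine$mat[1:3, 4], c(1, 2, 0))
})

test_that("jacobian determinant map matches analytic and oracle values", {
  ref <- bn_volume(array(0, c(12, 12, 12)))
  # zero field -> 1 everywhere
  zero <- bn_defield(array(0, c(12, 12, 12, 3)))
  expect_lt(max(abs(jacobian_determinant_map(zero, ref)$data - 1)), 1e-6)
  # uniform scale about the origin: u = (s-1) x -> det = s^3
  g <- deblood:::world_grid(ref)
  u <- array(0, c(12, 12, 12, 3))
  u[, , , 1] <- 0.2 * g$x; u[, , , 2] <- 0.2 * g$y; u[, , , 3] <- 0.2 * g$z
  jm <- jacobian_determinant_map(bn_defield(u), ref)
  expect_lt(max(abs(jm$data[2:11, 2:11, 2:11] - 1.2^3)), 1e-3)
  # random smooth field vs an explicit finite-difference loop
  set.seed(9)
  coarse <- array(rnorm(4^3 * 3), c(4, 4, 4, 3))
  us <- array(0, c(12, 12, 12, 3))
  for (cmp in 1:3)
    us[, , , cmp] <- deblood:::smooth3d(
      array(rep(coarse[, , , cmp], each = 27)[seq_len(12^3)], c(12, 12, 12)), 2)
  jmap <- jacobian_determinant_map(bn_defield(us), ref)$data
  oracle <- array(NA_real_, c(12, 12, 12))
  dget <- function(a, i, j, k, ax) {
    n <- 12
    idx <- c(i, j, k)
    if (idx[ax] == 1) {
      lo <- idx; hi <- idx; hi[ax] <- 2
      a[hi[1], hi[2], hi[3]] - a[lo[1], lo[2], lo[3]]
    } else if (idx[ax] == n) {
      lo <- idx; lo[ax] <- n - 1
      a[idx[1], idx[2], idx[3]] - a[lo[1], lo[2], lo[3]]
    } else {
      lo <- idx; lo[ax] <- idx[ax] - 1; hi <- idx; hi[ax] <- idx[ax] + 1
      (a[hi[1], hi[2], hi[3]] - a[lo[1], lo[2], lo[3]]) / 2
    }
  }
  for (k in 1:12) for (j in 1:12) for (i in 1:12) {
    J <- diag(3)
    for (ci in 1:3) for (cj in 1:3)
      J[ci, cj] <- J[ci, cj] + dget(us[, , , ci], i, j, k, cj)
    oracle[i, j, k] <- abs(det(J))
  }
  expect_lt(max(abs(jmap - oracle)), 1e-6)
})

test_that("displacement magnitude is the per-voxel Euclidean norm", {
  ref <- bn_volume(array(0, c(6, 6, 6)))
  zero <- bn_defield(array(0, c(6, 6, 6, 3)))
  expect_identical(unique(as.numeric(
    displacement_magnitude_map(zero, ref)$data)), 0)
  cst <- bn_defield(array(rep(c(3, 4, 0), each = 6^3), c(6, 6, 6, 3)))
  expect_equal(unique(as.numeric(displacement_magnitude_map(cst, ref)$data)), 5)
  set.seed(3)
  u <- array(rnorm(6^3 * 3), c(6, 6, 6, 3))
  m <- displacement_magnitude_map(bn_defield(u), ref)$data
  expect_lt(max(abs(m - sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2))),
            1e-12)
})

test_that("affine build/decompose round-trips parameters", {
  set.seed(21)
  for (i in 1:5) {
    tr <- runif(3, -5, 5); ro <- runif(3, -20, 20); sc <- runif(3, 0.9, 1.1)
    ctr <- runif(3, 0, 50)
    d <- decompose_affine(make_affine(tr, ro, sc, ctr), ctr)
    expect_equal(d$translation, tr, tolerance = 1e-8)
    expect_equal(d$rotation, ro, tolerance = 1e-8)
    expect_equal(d$scale, sc, tolerance = 1e-8)
  }
})
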