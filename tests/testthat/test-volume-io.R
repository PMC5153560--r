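test_that("NIfTI write/read round-trip preserves data and spacing", {
  v <- volume(array(7, dim = c(4, 4, 4)), spacing = c(2, 2, 2))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  v2 <- read_volume(f)
  expect_identical(dim(v2$data), c(4L, 4L, 4L))
  expect_equal(v2$data, v$data, tolerance = 1e-12)
  expect_equal(v2$spacing, v$spacing)

  set.seed(1)
  v3 <- volume(array(rnorm(4 * 5 * 6), dim = c(4, 5, 6)), spacing = c(1, 2, 3))
  f3 <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v3, f3)
  v4 <- read_volume(f3)
  expect_equal(v4$data, v3$data, tolerance = 1e-6)
  expect_equal(v4$spacing, v3$spacing)
})

test_that("reading rejects missing files, 4D images and non-finite voxels", {
  expect_error(read_volume("no/such/file.nii"), "not found")

  f4 <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(1, dim = c(3, 3, 3, 2))), f4)
  expect_error(read_volume(f4), "expected 3D")

  fna <- withr::local_tempfile(fileext = ".nii.gz")
  a <- array(1, dim = c(3, 3, 3)); a[c(1, 5, 9)] <- NaN
  RNifti::writeNifti(RNifti::asNifti(a), fna)
  expect_error(read_volume(fna), "3 non-finite")
})

test_that("volume constructor enforces its invariants", {
  expect_error(volume(matrix(1, 2, 2)), "3D")
  expect_error(volume(array(1, dim = c(2, 2, 2)), spacing = c(1, -1, 1)),
               "positive")
  expect_error(volume(array(c(1, NA), dim = c(2, 1, 1))), "non-finite")
})

test_that("mask sets load from binary files and from a label image", {
  d <- c(6, 6, 6)
  m1 <- array(0, dim = d); m1[2:3, 2:3, 2:3] <- 1
  m2 <- array(0, dim = d); m2[5, 5, 5] <- 1
  f1 <- withr::local_tempfile(fileext = ".nii.gz")
  f2 <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(volume(m1), f1); write_volume(volume(m2), f2)
  ms <- read_mask_set(c(caudate_L = f1, caudate_R = f2))
  expect_s3_class(ms, "striatex_masks")
  expect_equal(sum(ms$masks$caudate_L), 8)

  lab <- array(0, dim = d); lab[2:3, 2:3, 2:3] <- 4; lab[5, 5, 5] <- 9
  fl <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(volume(lab), fl)
  ms2 <- read_mask_set(fl, labels = c(caudate_L = 4, caudate_R = 9))
  expect_identical(ms2$masks$caudate_L, ms$masks$caudate_L)
  expect_identical(ms2$masks$caudate_R, ms$masks$caudate_R)
})

test_that("mask validation rejects overlap, emptiness and shape mismatch", {
  d <- c(4, 4, 4)
  a <- array(FALSE, dim = d); a[1:2, 1, 1] <- TRUE
  b <- array(FALSE, dim = d); b[2:3, 1, 1] <- TRUE
  expect_error(region_mask_set(list(putamen_L = a, putamen_R = b)), "overlap")
  expect_error(region_mask_set(list(caudate_L = array(FALSE, dim = d))),
               "empty")
  expect_error(region_mask_set(list(caudate_L = a,
                                    caudate_R = array(TRUE, dim = c(3, 3, 3)))),
               "shape")
})

test_that("identity resampling returns the input bitwise", {
  set.seed(2)
  v <- volume(array(rnorm(5 * 6 * 7), dim = c(5, 6, 7)), spacing = c(2, 2, 2))
  out <- resample_rigid(v, v, rigid_transform())
  expect_identical(out$data, v$data)
})

test_that("one-voxel translation shifts indices with a zero-filled border", {
  set.seed(3)
  d <- c(6, 5, 4)
  v <- volume(array(rnorm(prod(d)), dim = d), spacing = c(2, 2, 2))
  # pull-back convention: sampling point moves +1 voxel in x
  tr <- rigid_transform(translation = c(2, 0, 0))
  out <- resample_rigid(v, v, tr)
  expect_equal(out$data[1:(d[1] - 1), , ], v$data[2:d[1], , ],
               tolerance = 1e-12)
  expect_true(all(out$data[d[1], , ] == 0))
})

test_that("trilinear interpolation of a constant stays constant inside", {
  v <- volume(array(7, dim = c(10, 10, 10)), spacing = c(2, 2, 2))
  th <- 20 * pi / 180
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
                byrow = TRUE)
  out <- resample_rigid(v, v, rigid_transform(rot, c(1, -1, 0.5)))
  interior <- out$data[4:7, 4:7, 4:7]
  expect_true(all(abs(interior - 7) < 1e-9))
})

test_that("resampling composed with the inverse transform round-trips", {
  # smooth test field: trilinear error scales with curvature, so the bound
  # is meaningful only for signals without sharp edges
  d <- c(48, 48, 40)
  ix <- seq_len(d[1]); iy <- seq_len(d[2]); iz <- seq_len(d[3])
  blob <- outer(exp(-((ix - 24)^2) / 72),
                outer(exp(-((iy - 24)^2) / 72), exp(-((iz - 20)^2) / 72)))
  v <- volume(100 * blob + 20, spacing = c(2, 2, 2))
  th <- 5 * pi / 180
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
                byrow = TRUE)
  t1 <- rigid_transform(rot, c(3, -2, 1))
  t2 <- rigid_transform(t(rot), -t(rot) %*% c(3, -2, 1))
  back <- resample_rigid(resample_rigid(v, v, t1), v, t2)
  core <- function(a) a[8:40, 8:40, 8:32]
  expect_lt(max(abs(core(back$data) - core(v$data))) / diff(range(v$data)),
            0.02)
})

test_that("non-orthonormal rotations are rejected", {
  expect_error(rigid_transform(matrix(1:9, 3, 3)), "orthonormal")
  refl <- diag(c(-1, 1, 1))
  expect_error(rigid_transform(refl), "determinant")
})

test_that("rigid transform text files round-trip", {
  th <- 10 * pi / 180
  rot <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)), 3, 3,
                byrow = TRUE)
  m <- rbind(cbind(rot, c(1, 2, 3)), c(0, 0, 0, 1))
  f <- withr::local_tempfile(fileext = ".txt")
  write.table(m, f, row.names = FALSE, col.names = FALSE)
  tr <- read_rigid_transform(f)
  expect_equal(tr$rotation, rot, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(tr$translation, c(1, 2, 3), tolerance = 1e-12)
})
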