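test_that("quantization follows the min-max binning rule", {
  d <- c(4, 1, 1)
  v <- volume(array(c(0, 1, 2, 3), dim = d))
  mask <- array(TRUE, dim = d)
  q <- quantize_roi(v, mask, Q = 4)
  expect_equal(as.vector(q$levels), 1:4)

  # in-mask maximum maps to Q, never Q+1
  set.seed(10)
  v2 <- volume(array(runif(64), dim = c(4, 4, 4)))
  q2 <- quantize_roi(v2, array(TRUE, dim = c(4, 4, 4)), Q = 7)
  expect_equal(max(q2$levels), 7)
  expect_equal(q2$levels[which.max(v2$data)], 7L)

  # constant ROI collapses to level 1
  q3 <- quantize_roi(volume(array(5, dim = d)), mask, Q = 32)
  expect_true(all(q3$levels == 1))

  expect_error(quantize_roi(v, mask, Q = 1), "at least 2")
  expect_error(quantize_roi(v, array(FALSE, dim = d)), "empty")
})

test_that("a single co-occurring pair gives the hand-computed GLCM", {
  d <- c(1, 1, 2)
  v <- volume(array(c(0, 1), dim = d))
  q <- quantize_roi(v, array(TRUE, dim = d), Q = 2)
  g <- build_glcm(q)
  expect_equal(g$p[1, 2], 0.5)
  expect_equal(g$p[2, 1], 0.5)
  expect_equal(g$p[1, 1] + g$p[2, 2], 0)
  expect_equal(sum(g$n_pairs_per_direction), 1)
})

test_that("a constant ROI concentrates all mass at p(1,1)", {
  d <- c(3, 3, 3)
  v <- volume(array(2.5, dim = d))
  g <- build_glcm(quantize_roi(v, array(TRUE, dim = d), Q = 32))
  expect_equal(g$p[1, 1], 1)
  expect_equal(sum(g$p), 1)
})

test_that("a single-voxel ROI is a degenerate error, carried as NA features", {
  d <- c(5, 5, 5)
  v <- volume(array(runif(125), dim = d))
  lone <- array(FALSE, dim = d); lone[3, 3, 3] <- TRUE
  expect_error(build_glcm(quantize_roi(v, lone)), "degenerate")
  ms <- tiny_mask_set(d, cbind(3, 3, 3))
  tx <- texture_for_region(v, ms, "caudate_L")
  expect_true(tx$degenerate)
  expect_true(all(is.na(tx$features)))
})

test_that("GLCM construction matches brute-force pair enumeration", {
  set.seed(11)
  for (rep in 1:50) {
    d <- c(5, 5, 5)
    a <- array(rnorm(prod(d)), dim = d)
    mask <- if (rep %% 2 == 0) array(TRUE, dim = d) else
      array(runif(prod(d)) < 0.7, dim = d)
    if (sum(mask) < 3) mask[1:3] <- TRUE
    v <- volume(a)
    g <- build_glcm(quantize_roi(v, mask, Q = 4))
    o <- oracle_glcm(a, mask, Q = 4)
    expect_lt(max(abs(g$p - o)), 1e-12)
  }
})

test_that("distance-2 offsets skip one voxel", {
  d <- c(1, 1, 5)
  v <- volume(array(c(0, 9, 1, 9, 0), dim = d))
  mask <- array(c(TRUE, FALSE, TRUE, FALSE, TRUE), dim = d)
  g <- build_glcm(quantize_roi(v, mask, Q = 2), distance = 2)
  o <- oracle_glcm(v$data, mask, Q = 2, distance = 2)
  expect_lt(max(abs(g$p - o)), 1e-12)
  expect_equal(sum(g$n_pairs_per_direction), 2)  # (1,3) and (3,5)
})

test_that("features of degenerate and two-cell matrices match closed forms", {
  f1 <- haralick_features(matrix(1, 1, 1))
  expect_equal(f1[["energy"]], 1)
  expect_equal(f1[["entropy"]], 0)
  expect_equal(f1[["contrast"]], 0)
  expect_equal(f1[["dissimilarity"]], 0)
  expect_equal(f1[["homogeneity"]], 1)
  expect_equal(f1[["max_probability"]], 1)
  expect_equal(f1[["variance"]], 0)
  expect_equal(f1[["inverse_variance"]], 0)
  expect_equal(f1[["sum_mean"]], 1)
  expect_equal(f1[["correlation"]], 0)   # degenerate rule
  expect_equal(f1[["agreement"]], 1)     # degenerate rule

  p2 <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  f2 <- haralick_features(p2)
  expect_equal(f2[["entropy"]], 1)
  expect_equal(f2[["contrast"]], 1)
  expect_equal(f2[["dissimilarity"]], 1)
  expect_equal(f2[["homogeneity"]], 0.5)
  expect_equal(f2[["energy"]], 0.5)
  expect_equal(f2[["agreement"]], -1)
  expect_equal(f2[["sum_mean"]], 1.5)
  expect_equal(f2[["correlation"]], -1)
})

test_that("all 13 features match the literal-summation oracle", {
  set.seed(12)
  for (rep in 1:200) {
    p <- random_sym_glcm(8)
    got <- haralick_features(p)
    want <- oracle_haralick(p)
    expect_lt(max(abs(got[names(want)] - want)), 1e-10)
  }
})

test_that("feature ranges respect their analytic bounds", {
  set.seed(13)
  for (rep in 1:25) {
    f <- haralick_features(random_sym_glcm(sample(2:12, 1)))
    expect_true(f[["energy"]] > 0 && f[["energy"]] <= 1)
    expect_gte(f[["entropy"]], 0)
    expect_true(f[["homogeneity"]] > 0 && f[["homogeneity"]] <= 1)
    expect_true(f[["max_probability"]] > 0 && f[["max_probability"]] <= 1)
    expect_gte(f[["contrast"]], 0)
    expect_gte(f[["dissimilarity"]], 0)
    expect_gte(f[["variance"]], 0)
    expect_gte(f[["inverse_variance"]], 0)
    expect_true(abs(f[["correlation"]]) <= 1 + 1e-12)
    expect_true(f[["agreement"]] >= -1 - 1e-12 && f[["agreement"]] <= 1 + 1e-12)
  }
})

test_that("unnormalized matrices are rejected", {
  expect_error(haralick_features(matrix(0.3, 2, 2)), "not normalized")
})

test_that("texture features are invariant to positive affine intensity maps", {
  p <- phantom_params(seed = 21)
  m <- make_masks(p)
  v <- simulate_subject(p, list(latent_severity = 0.4, noise_seed = 77), m)
  base <- texture_for_region(v, m, "caudate_L")$features
  shift <- texture_for_region(
    volume(v$data + 11.3, spacing = v$spacing), m, "caudate_L")$features
  scale <- texture_for_region(
    volume(2.7 * v$data + 5, spacing = v$spacing), m, "caudate_L")$features
  expect_equal(base, shift, tolerance = 1e-12)
  expect_equal(base, scale, tolerance = 1e-12)
})

test_that("striping raises contrast and lowers homogeneity", {
  d <- c(8, 8, 8)
  stripes <- array(rep(c(0, 1), length.out = prod(d)), dim = d)  # period 2 in x
  near_const <- array(0, dim = d); near_const[1, 1, 1] <- 1e-3
  ms <- region_mask_set(list(caudate_L = array(TRUE, dim = d)))
  f_s <- texture_for_region(volume(stripes), ms, "caudate_L", Q = 2)$features
  f_c <- texture_for_region(volume(near_const), ms, "caudate_L", Q = 2)$features
  expect_gt(f_s[["contrast"]], f_c[["contrast"]])
  expect_lt(f_s[["homogeneity"]], f_c[["homogeneity"]])
})

test_that("variant switches change only their targeted feature", {
  set.seed(14)
  p <- random_sym_glcm(6)
  a <- haralick_features(p)
  b <- haralick_features(p, homogeneity_form = "inverse_difference_squared")
  expect_false(isTRUE(all.equal(a[["homogeneity"]], b[["homogeneity"]])))
  expect_equal(a[setdiff(names(a), "homogeneity")],
               b[setdiff(names(b), "homogeneity")])
  d2 <- haralick_features(p, cluster_tendency_exponent = 2)
  expect_false(isTRUE(all.equal(a[["cluster_tendency"]],
                                d2[["cluster_tendency"]])))
})
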