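test_that("masks are mirror-symmetric, disjoint and complete", {
  m <- make_masks(phantom_params())
  expect_setequal(names(m$masks), ALL_REGIONS)
  expect_equal(sum(m$masks$putamen_L), sum(m$masks$putamen_R))
  expect_equal(sum(m$masks$caudate_L), sum(m$masks$caudate_R))
  nm <- STRIATAL_REGIONS
  for (i in 1:3) for (j in (i + 1):4)
    expect_false(any(m$masks[[nm[i]]] & m$masks[[nm[j]]]))
  for (s in nm)
    expect_false(any(m$masks[[s]] & m$masks$occipital))
  # region sizes near the anatomical targets (2 mm voxels)
  expect_gt(sum(m$masks$caudate_L) * 8 / 1000, 1.0)   # > 1.0 cm^3
  expect_lt(sum(m$masks$caudate_L) * 8 / 1000, 2.0)
  expect_gt(sum(m$masks$putamen_L) * 8 / 1000, 3.0)
  expect_lt(sum(m$masks$putamen_L) * 8 / 1000, 5.0)
})

test_that("severity 0 gives a left-right symmetric noise-free phantom", {
  p <- phantom_params(noise_sd = 0)
  m <- make_masks(p)
  f <- phantom_field(p, list(latent_severity = 0), m)
  for (region in c("putamen", "caudate")) {
    mL <- mean(f$data[m$masks[[paste0(region, "_L")]]])
    mR <- mean(f$data[m$masks[[paste0(region, "_R")]]])
    expect_lt(abs(mL - mR), 1e-9)
  }
})

test_that("the asymmetry factor scales the more-affected putamen mean", {
  p <- phantom_params(noise_sd = 0, asymmetry = 0.3)
  m <- make_masks(p)
  f <- phantom_field(p, list(latent_severity = 1, affected_side = "L"), m)
  more <- mean(f$data[m$masks$putamen_L])
  less <- mean(f$data[m$masks$putamen_R])
  # ramp terms are zero-mean only up to voxelization; compare to the exact
  # per-voxel model ratio instead of the idealized integral
  expect_equal(more / less, 0.7, tolerance = 0.01)
})

test_that("masked means match an independent evaluation of the uptake model", {
  p <- phantom_params(noise_sd = 0)
  m <- make_masks(p)
  rec <- list(latent_severity = 0.6, uptake_scale = 1.1, affected_side = "L")
  gt <- phantom_ground_truth(p, rec, m)
  # independent reconstruction of the stated model for the less-affected
  # (right) putamen: side factor 1, effective severity 1.5*sev
  msk <- m$masks$putamen_R
  idx <- which(msk, arr.ind = TRUE)
  sev_p <- min(1, p$putamen_gain * 0.6)
  yr <- range(idx[, 2])
  ramp <- 2 * (idx[, 2] - mean(yr)) / diff(yr)
  amp <- p$gradient_steepness * diff(yr) * p$spacing_mm / 2 *
    p$striatal_base * (1 - p$gradient_erosion_less * sev_p)
  expected <- mean(1.1 * (p$striatal_base * (1 - p$putamen_mean_loss * sev_p) +
                            amp * ramp))
  expect_equal(unname(gt[["putamen_R"]]), expected, tolerance = 1e-6)
  # and the occipital reference is untouched by severity
  expect_equal(unname(gt[["occipital"]]), p$reference_level)
  # measured masked means agree with the analytic ground truth pre-smoothing
  up <- mean_roi_uptake(phantom_field(p, rec, m), m)
  expect_equal(up$mean_raw, gt, tolerance = 1e-9)
})

test_that("within-ROI variance grows with gradient steepness", {
  rec <- list(latent_severity = 0.2)
  vars <- vapply(c(0.01, 0.025, 0.05), function(s) {
    p <- phantom_params(noise_sd = 0, gradient_steepness = s)
    m <- make_masks(p)
    f <- phantom_field(p, rec, m)
    var(f$data[m$masks$caudate_L])
  }, 0)
  expect_true(all(diff(vars) > 0))
})

test_that("clinical tables are reproducible and severity-linked", {
  p <- phantom_params(seed = 123)
  a <- simulate_clinical(p, 85, 56)
  b <- simulate_clinical(p, 85, 56)
  expect_identical(a, b)
  expect_equal(nrow(a), 141)
  expect_equal(sum(a$group == "PD"), 85)
  expect_equal(sum(a$group == "HC"), 56)
  pd <- a[a$group == "PD", ]
  hc <- a[a$group == "HC", ]
  expect_true(all(hc$latent_severity == 0))
  expect_true(all(pd$dd_sympt_months >= pd$dd_diag_months))
  expect_true(all(a$moca >= 0 & a$moca <= 30))
  expect_true(all(a$updrs3 >= 0))
  expect_gt(cor(pd$latent_severity, pd$updrs3), 0.8)
  expect_gt(cor(pd$latent_severity, pd$dd_diag_months), 0.8)
  expect_lt(cor(pd$latent_severity, pd$moca), -0.5)
})

test_that("cohort volume generation is deterministic under the seed", {
  p <- phantom_params(seed = 31, grid_shape = c(64, 64, 48))
  c1 <- simulate_cohort(p, n_pd = 2, n_hc = 1)
  c2 <- simulate_cohort(p, n_pd = 2, n_hc = 1)
  expect_identical(c1$clinical, c2$clinical)
  for (id in names(c1$volumes))
    expect_identical(c1$volumes[[id]]$data, c2$volumes[[id]]$data)
})

test_that("written cohorts round-trip through the manifest", {
  p <- phantom_params(seed = 9)
  coh <- simulate_cohort(p, n_pd = 3, n_hc = 2)
  dir <- withr::local_tempdir()
  man <- write_cohort(coh, dir)
  expect_true(file.exists(man))
  back <- read_cohort(man)
  expect_equal(nrow(back$clinical), 5)
  expect_true(all(c("subject_id", "group", "updrs3", "dd_diag_months",
                    "dd_sympt_months", "moca", "age") %in%
                    names(back$clinical)))
  expect_setequal(names(back$volumes), coh$clinical$subject_id)
  for (id in names(back$volumes)) {
    m1 <- mean_roi_uptake(coh$volumes[[id]], coh$masks)$mean_raw
    m2 <- mean_roi_uptake(back$volumes[[id]], back$masks)$mean_raw
    expect_equal(m1, m2, tolerance = 1e-6)
  }
})

test_that("caudate heterogeneity features rise with severity", {
  # the eroding-gradient model: higher severity leaves less structured
  # contrast against the constant noise floor, so entropy and contrast of
  # the quantized caudate increase
  p <- phantom_params(seed = 55)
  m <- make_masks(p)
  feat_at <- function(sev, seeds) {
    rowMeans(vapply(seeds, function(s) {
      v <- simulate_subject(p, list(latent_severity = sev, noise_seed = s), m)
      tx <- texture_for_region(v, m, "caudate_L")
      tx$features[c("entropy", "contrast")]
    }, c(entropy = 0, contrast = 0)))
  }
  lo <- feat_at(0.1, 1:4)
  hi <- feat_at(0.9, 1:4)
  expect_gt(hi[["entropy"]], lo[["entropy"]])
  expect_gt(hi[["contrast"]], lo[["contrast"]])
})

test_that("severity outside [0,1] is rejected", {
  p <- phantom_params()
  expect_error(phantom_field(p, list(latent_severity = 1.2)), "0, 1")
  expect_error(phantom_field(p, list(latent_severity = -0.1)), "0, 1")
})

test_that("parameter validation enforces the stated orderings", {
  expect_error(phantom_params(background_level = 120), "striatal_base")
  expect_error(phantom_params(asymmetry = 1), "asymmetry")
  expect_error(phantom_params(noise_sd = -1), ">= 0")
})
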