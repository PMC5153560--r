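#' Phantom generator parameters
#'
#' Settings for the synthetic striatal DAT SPECT cohort. The phantom places
#' mirrored caudate and putamen ellipsoids and a posterior occipital
#' reference slab on an isotropic grid, fills them according to a
#' severity-linked uptake model, then adds Gaussian noise and applies
#' post-reconstruction smoothing.
#'
#' The uptake model: striatal intensity is
#' `striatal_base * subject_scale * side_factor * (1 - mean_loss * sev_r) +
#'  ramp(position) * (1 - erosion * sev_r)`,
#' where `sev_r` is the region's effective severity (putamen responds
#' `putamen_gain` times more strongly than the latent severity; the caudate
#' mean response is deliberately weak), `side_factor = 1 - asymmetry *
#' severity` on the more affected putamen, and `ramp` is a fixed zero-mean
#' rostrocaudal gradient whose amplitude shrinks ("erodes") with severity.
#' Because the ramp is zero-mean it leaves regional mean uptake untouched
#' while its erosion — against a constant noise floor — makes the region's
#' relative fine-scale heterogeneity grow with disease severity, the pattern
#' texture features are designed to detect.
#'
#' @param grid_shape integer length-3 grid size (voxels).
#' @param spacing_mm isotropic voxel size, mm.
#' @param background_level nonspecific uptake outside all regions.
#' @param reference_level occipital reference uptake.
#' @param striatal_base healthy striatal specific uptake.
#' @param gradient_steepness rostrocaudal gradient slope, fraction of
#'   `striatal_base` per mm.
#' @param gradient_erosion_more,gradient_erosion_less fraction of the ramp
#'   amplitude lost at full severity on the more / less affected side.
#' @param asymmetry fractional extra putamen loss on the more affected side
#'   at full severity, in \[0,1).
#' @param putamen_gain severity multiplier for the putamen response.
#' @param putamen_mean_loss,caudate_mean_loss fractional mean uptake loss at
#'   full effective severity.
#' @param subject_scale_sd SD of log-normal between-subject striatal uptake
#'   scatter.
#' @param noise_sd additive Gaussian voxel noise SD (pre-smoothing).
#' @param fwhm_mm post-reconstruction Gaussian smoothing FWHM, mm.
#' @param affected_side side carrying the greater loss for simulated
#'   patients ("L" unless `randomize_side`).
#' @param randomize_side if TRUE, each patient's affected side is drawn at
#'   random instead of fixed.
#' @param seed integer RNG seed for cohort generation.
#' @return A `striatex_phantom_params` list.
#' @export
phantom_params <- function(grid_shape = c(64, 64, 48),
                           spacing_mm = 2,
                           background_level = 50,
                           reference_level = 50,
                           striatal_base = 100,
                           gradient_steepness = 0.025,
                           gradient_erosion_more = 0.85,
                           gradient_erosion_less = 0.6,
                           asymmetry = 0.3,
                           putamen_gain = 1.5,
                           putamen_mean_loss = 0.5,
                           caudate_mean_loss = 0,
                           subject_scale_sd = 0.12,
                           noise_sd = 15,
                           fwhm_mm = 6,
                           affected_side = "L",
                           randomize_side = FALSE,
                           seed = 1L) {
  p <- list(grid_shape = as.integer(grid_shape), spacing_mm = spacing_mm,
            background_level = background_level,
            reference_level = reference_level,
            striatal_base = striatal_base,
            gradient_steepness = gradient_steepness,
            gradient_erosion_more = gradient_erosion_more,
            gradient_erosion_less = gradient_erosion_less,
            asymmetry = asymmetry, putamen_gain = putamen_gain,
            putamen_mean_loss = putamen_mean_loss,
            caudate_mean_loss = caudate_mean_loss,
            subject_scale_sd = subject_scale_sd,
            noise_sd = noise_sd, fwhm_mm = fwhm_mm,
            affected_side = match.arg(affected_side, c("L", "R")),
            randomize_side = isTRUE(randomize_side),
            seed = as.integer(seed))
  if (length(p$grid_shape) != 3L || any(p$grid_shape < 1))
    stop("grid_shape must be three positive integers")
  if (!(p$striatal_base > p$background_level && p$background_level > 0))
    stop("require striatal_base > background_level > 0")
  if (p$reference_level <= 0) stop("reference_level must be positive")
  if (p$noise_sd < 0 || p$gradient_steepness < 0 || p$subject_scale_sd < 0)
    stop("noise/steepness/scatter parameters must be >= 0")
  if (p$asymmetry < 0 || p$asymmetry >= 1)
    stop("asymmetry must lie in [0, 1)")
  class(p) <- "striatex_phantom_params"
  p
}

# Region geometry in mm, relative to the mid-sagittal plane and grid center.
phantom_geometry <- function(params) {
  list(
    caudate = list(offset_x = 12, center_y_frac = 0.60, center_z_frac = 0.54,
                   semi_mm = c(5, 11, 6)),
    putamen = list(offset_x = 26, center_y_frac = 0.47, center_z_frac = 0.50,
                   semi_mm = c(7, 15, 9)),
    occipital = list(y_mm = c(8, 20), half_x_mm = 26, z_frac = c(0.33, 0.67))
  )
}

#' Build the phantom region masks
#'
#' Two mirrored ellipsoid pairs (caudate about 1.4 cm^3, putamen about
#' 4 cm^3 at 2 mm spacing) placed symmetrically about the mid-sagittal
#' plane, plus a posterior occipital reference slab. Deterministic given the
#' parameters.
#'
#' @param params a [phantom_params()].
#' @return A `striatex_masks` with regions
#'   `caudate_L/R`, `putamen_L/R`, `occipital`.
#' @export
make_masks <- function(params = phantom_params()) {
  d <- params$grid_shape; sp <- params$spacing_mm
  geo <- phantom_geometry(params)
  ix <- seq_len(d[1]); iy <- seq_len(d[2]); iz <- seq_len(d[3])
  x0 <- (d[1] + 1) / 2
  # mm distance from the mid-sagittal plane (symmetric by construction)
  xm <- abs(ix - x0) * sp
  ym <- iy * sp; zm <- iz * sp
  ellip_pair <- function(g) {
    cy <- g$center_y_frac * d[2] * sp; cz <- g$center_z_frac * d[3] * sp
    a <- g$semi_mm
    inside <- outer(((xm - g$offset_x) / a[1])^2,
                    outer(((ym - cy) / a[2])^2, ((zm - cz) / a[3])^2, "+"),
                    "+") <= 1
    left <- array(inside & (ix < x0), dim = d)
    right <- array(inside & (ix > x0), dim = d)
    list(L = left, R = right)
  }
  ca <- ellip_pair(geo$caudate); pu <- ellip_pair(geo$putamen)
  occ <- array(FALSE, dim = d)
  oy <- which(ym >= geo$occipital$y_mm[1] & ym <= geo$occipital$y_mm[2])
  ox <- which(abs(ix - x0) * sp <= geo$occipital$half_x_mm)
  oz <- which(iz >= geo$occipital$z_frac[1] * d[3] &
              iz <= geo$occipital$z_frac[2] * d[3])
  if (!length(oy) || !length(ox) || !length(oz))
    stop("grid too small to place the occipital reference slab")
  occ[ox, oy, oz] <- TRUE
  masks <- list(caudate_L = ca$L, caudate_R = ca$R,
                putamen_L = pu$L, putamen_R = pu$R, occipital = occ)
  if (any(vapply(masks, sum, 0) == 0))
    stop("grid too small: a region mask came out empty")
  region_mask_set(masks)  # validates disjointness
}

#' Simulate one subject's clinical record set
#'
#' Draws latent severities and severity-linked clinical scores for a cohort:
#' PD severity ~ Uniform(0.1, 1); UPDRS-III = 5 + 45*sev + N(0,6), clipped at
#' 0; disease duration from diagnosis = 60*sev + N(0,8) months, clipped at 0;
#' duration from symptoms adds |N(12,6)| months; MoCA = 28 - 6*sev + N(0,1.5)
#' clipped to \[0,30\]; age ~ N(61,9) independent of severity. Controls have
#' severity 0, UPDRS-III = |N(1,1)|, MoCA = 28 + N(0,1) and missing disease
#' durations. A log-normal per-subject striatal uptake scale (ground truth
#' for the imaging model) is stored alongside.
#'
#' @param params a [phantom_params()]; `params$seed` fixes the draw.
#' @param n_pd,n_hc group sizes (defaults 85 PD, 56 HC).
#' @return data.frame, one row per subject.
#' @export
simulate_clinical <- function(params = phantom_params(), n_pd = 85, n_hc = 56) {
  stopifnot(n_pd >= 0, n_hc >= 0, n_pd + n_hc > 0)
  with_seed(params$seed, {
    n <- n_pd + n_hc
    grp <- rep(c("PD", "HC"), c(n_pd, n_hc))
    sev <- c(stats::runif(n_pd, 0.1, 1), rep(0, n_hc))
    updrs <- ifelse(grp == "PD",
                    clip(5 + 45 * sev + stats::rnorm(n, 0, 6), lo = 0),
                    abs(stats::rnorm(n, 1, 1)))
    dd_diag <- ifelse(grp == "PD",
                      clip(60 * sev + stats::rnorm(n, 0, 8), lo = 0), NA_real_)
    dd_sympt <- dd_diag + ifelse(grp == "PD",
                                 abs(stats::rnorm(n, 12, 6)), NA_real_)
    moca <- ifelse(grp == "PD",
                   clip(28 - 6 * sev + stats::rnorm(n, 0, 1.5), 0, 30),
                   clip(28 + stats::rnorm(n, 0, 1), 0, 30))
    age <- stats::rnorm(n, 61, 9)
    scale <- exp(stats::rnorm(n, 0, params$subject_scale_sd))
    side <- if (params$randomize_side) {
      ifelse(grp == "PD", sample(c("L", "R"), n, replace = TRUE),
             params$affected_side)
    } else rep(params$affected_side, n)
    data.frame(
      subject_id = sprintf("%s%03d", grp, c(seq_len(n_pd), seq_len(n_hc))),
      group = grp, updrs3 = updrs, dd_diag_months = dd_diag,
      dd_sympt_months = dd_sympt, moca = moca, age = age,
      latent_severity = sev, uptake_scale = scale, affected_side = side,
      noise_seed = (params$seed + 7919L * seq_len(n)) %% 2147483647L,
      stringsAsFactors = FALSE)
  })
}

# Zero-mean rostrocaudal ramp over one region's voxels: -1 at the caudal
# pole, +1 at the rostral pole of the mask's anterior-posterior extent.
region_ramp <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  yr <- range(idx[, 2])
  if (diff(yr) == 0) return(rep(0, nrow(idx)))
  2 * (idx[, 2] - mean(yr)) / diff(yr)
}

#' Noise-free phantom intensity field
#'
#' Evaluates the deterministic uptake model for one subject (no noise, no
#' smoothing). Used internally by [simulate_subject()] and directly by tests
#' as the analytic ground truth for masked means.
#'
#' @param params a [phantom_params()].
#' @param record one row of a [simulate_clinical()] table (list or
#'   single-row data.frame).
#' @param masks optional precomputed [make_masks()] output.
#' @return A `striatex_volume`.
#' @export
phantom_field <- function(params, record, masks = NULL) {
  record <- as.list(record)
  sev <- record$latent_severity
  if (is.null(sev) || sev < 0 || sev > 1)
    stop("latent_severity must lie in [0, 1]")
  scale <- record$uptake_scale %||% 1
  more <- record$affected_side %||% params$affected_side
  if (is.null(masks)) masks <- make_masks(params)
  d <- params$grid_shape
  arr <- array(params$background_level, dim = d)
  arr[masks$masks$occipital] <- params$reference_level
  for (region in c("caudate", "putamen")) {
    sev_r <- if (region == "putamen") min(1, params$putamen_gain * sev) else sev
    mean_loss <- if (region == "putamen") params$putamen_mean_loss else
      params$caudate_mean_loss
    for (s in c("L", "R")) {
      m <- masks$masks[[paste0(region, "_", s)]]
      is_more <- identical(s, more)
      side_factor <- if (region == "putamen" && is_more)
        1 - params$asymmetry * sev else 1
      erosion <- if (is_more) params$gradient_erosion_more else
        params$gradient_erosion_less
      half_len_mm <- diff(range(which(m, arr.ind = TRUE)[, 2])) *
        params$spacing_mm / 2
      amp <- params$gradient_steepness * half_len_mm * params$striatal_base *
        (1 - erosion * sev_r)
      arr[m] <- scale * side_factor *
        (params$striatal_base * (1 - mean_loss * sev_r) +
           amp * region_ramp(m))
    }
  }
  volume(arr, spacing = rep(params$spacing_mm, 3))
}

#' Analytic region means of the noise-free phantom
#'
#' @inheritParams phantom_field
#' @return named numeric: mean model intensity over each region mask.
#' @export
phantom_ground_truth <- function(params, record, masks = NULL) {
  if (is.null(masks)) masks <- make_masks(params)
  f <- phantom_field(params, record, masks)
  vapply(masks$masks, function(m) mean(f$data[m]), 0)
}

#' Simulate one subject's emission volume
#'
#' Evaluates the noise-free uptake model, adds voxelwise Gaussian noise
#' (`noise_sd`) and applies the post-reconstruction Gaussian smoothing
#' (`fwhm_mm`). If the record carries a `noise_seed`, the noise draw is made
#' under that seed (restoring the caller's RNG state), which makes cohort
#' generation order-independent.
#'
#' @inheritParams phantom_field
#' @return A `striatex_volume`.
#' @export
simulate_subject <- function(params, record, masks = NULL) {
  if (is.null(masks)) masks <- make_masks(params)
  f <- phantom_field(params, record, masks)
  record <- as.list(record)
  add_noise <- function() {
    if (params$noise_sd > 0)
      f$data <- f$data +
        array(stats::rnorm(length(f$data), 0, params$noise_sd), dim = dim(f$data))
    f
  }
  f <- if (!is.null(record$noise_seed)) with_seed(record$noise_seed, add_noise())
       else add_noise()
  if (params$fwhm_mm > 0) gaussian_smooth(f, params$fwhm_mm) else f
}

#' Simulate a full synthetic cohort
#'
#' @param params a [phantom_params()].
#' @param n_pd,n_hc group sizes (defaults: 85 patients, 56 controls).
#' @param keep_volumes if FALSE, volumes are not retained (clinical table and
#'   masks only); use [cohort_features()] to stream feature extraction
#'   without holding the whole image set in memory.
#' @return list with `clinical` (data.frame), `masks`, `params`, and
#'   `volumes` (named list of `striatex_volume`, unless dropped).
#' @export
simulate_cohort <- function(params = phantom_params(), n_pd = 85, n_hc = 56,
                            keep_volumes = TRUE) {
  clinical <- simulate_clinical(params, n_pd, n_hc)
  masks <- make_masks(params)
  volumes <- NULL
  if (keep_volumes) {
    volumes <- lapply(seq_len(nrow(clinical)), function(i)
      simulate_subject(params, clinical[i, ], masks))
    names(volumes) <- clinical$subject_id
  }
  list(clinical = clinical, masks = masks, params = params, volumes = volumes)
}

#' Write a cohort to disk
#'
#' Writes one NIfTI volume per subject, one NIfTI mask per region, the
#' clinical table as CSV, and a JSON manifest recording paths, the generator
#' seed and parameters.
#'
#' @param cohort output of [simulate_cohort()] (with volumes).
#' @param out_dir writable output directory (created if needed).
#' @return path to the manifest file, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  if (is.null(cohort$volumes)) stop("cohort has no volumes to write")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  vol_paths <- character(0)
  for (id in names(cohort$volumes)) {
    p <- file.path(out_dir, paste0("vol_", id, ".nii.gz"))
    write_volume(cohort$volumes[[id]], p)
    vol_paths[id] <- basename(p)
  }
  mask_paths <- character(0)
  for (nm in names(cohort$masks$masks)) {
    p <- file.path(out_dir, paste0("mask_", nm, ".nii.gz"))
    write_volume(volume(array(as.numeric(cohort$masks$masks[[nm]]),
                              dim = dim(cohort$masks$masks[[nm]])),
                        spacing = rep(cohort$params$spacing_mm, 3)), p)
    mask_paths[nm] <- basename(p)
  }
  clin_path <- file.path(out_dir, "clinical.csv")
  utils::write.csv(cohort$clinical, clin_path, row.names = FALSE)
  manifest <- list(seed = cohort$params$seed,
                   params = unclass(cohort$params),
                   volumes = as.list(vol_paths),
                   masks = as.list(mask_paths),
                   clinical = basename(clin_path))
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}

#' Read a written cohort back from its manifest
#'
#' @param manifest_path path to a `manifest.json` written by [write_cohort()].
#' @return list with `clinical`, `masks`, `params`, `volumes` as in
#'   [simulate_cohort()].
#' @export
read_cohort <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  base <- dirname(manifest_path)
  masks <- read_mask_set(vapply(man$masks, function(p) file.path(base, p), ""))
  volumes <- lapply(man$volumes, function(p) read_volume(file.path(base, p)))
  names(volumes) <- names(man$volumes)
  clinical <- utils::read.csv(file.path(base, man$clinical),
                              stringsAsFactors = FALSE)
  params <- do.call(phantom_params,
                    man$params[names(man$params) %in%
                                 names(formals(phantom_params))])
  list(clinical = clinical, masks = masks, params = params, volumes = volumes)
}
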