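#' Extract the per-subject feature rows
#'
#' For one subject's volume and mask set, computes the conventional
#' quantification (raw and occipital-normalized regional means, imaging-based
#' more-affected side, laterality index per structure) and the 13 texture
#' features per striatal region, and lays the result out as one row per
#' structure (caudate, putamen) x side (more, less affected).
#'
#' @param v a `striatex_volume`.
#' @param masks a `striatex_masks` with the five canonical regions.
#' @param Q,distance GLCM settings (defaults 32 levels, distance 1).
#' @param ... feature-variant switches passed to [haralick_features()].
#' @return data.frame with columns `region`, `side`, `hemisphere`,
#'   `n_voxels`, `mean_raw`, `uptake` (normalized), `laterality`,
#'   `reference_mean`, `more_affected_side` and the 13 texture features.
#' @export
extract_subject_features <- function(v, masks, Q = 32L, distance = 1L, ...) {
  up <- normalize_to_reference(mean_roi_uptake(v, masks))
  more <- assign_affected_sides(up)
  less <- if (more == "L") "R" else "L"
  rows <- list()
  for (region in c("caudate", "putamen")) {
    lat <- laterality_index(up$mean_normalized[[paste0(region, "_R")]],
                            up$mean_normalized[[paste0(region, "_L")]])
    for (side in c("more", "less")) {
      hemi <- if (side == "more") more else less
      rn <- paste0(region, "_", hemi)
      tx <- texture_for_region(v, masks, rn, Q = Q, distance = distance, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        region = region, side = side, hemisphere = hemi,
        n_voxels = up$n_voxels[[rn]],
        mean_raw = up$mean_raw[[rn]],
        uptake = up$mean_normalized[[rn]],
        laterality = lat,
        reference_mean = up$reference_mean,
        more_affected_side = more,
        t(tx$features),
        glcm_Q = tx$Q, glcm_distance = tx$distance,
        glcm_pairs = tx$n_pairs,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Stream feature extraction over a synthetic cohort
#'
#' Generates (or takes) each subject's volume in turn and accumulates the
#' feature table, so a full cohort never needs to be held in memory.
#'
#' @param params a [phantom_params()].
#' @param clinical optional precomputed [simulate_clinical()] table.
#' @param volumes optional named list of volumes (e.g. a read-back cohort);
#'   if NULL they are simulated from `params` and `clinical`.
#' @param masks optional mask set (made from `params` if NULL).
#' @param n_pd,n_hc cohort sizes used when `clinical` is NULL.
#' @param Q,distance,... GLCM settings, see [extract_subject_features()].
#' @param progress print a dot per subject.
#' @return data.frame: subject rows from [extract_subject_features()] keyed
#'   by `subject_id`.
#' @export
cohort_features <- function(params = phantom_params(), clinical = NULL,
                            volumes = NULL, masks = NULL,
                            n_pd = 85, n_hc = 56,
                            Q = 32L, distance = 1L, ..., progress = FALSE) {
  if (is.null(clinical)) clinical <- simulate_clinical(params, n_pd, n_hc)
  if (is.null(masks)) masks <- make_masks(params)
  out <- vector("list", nrow(clinical))
  for (i in seq_len(nrow(clinical))) {
    id <- clinical$subject_id[i]
    v <- if (!is.null(volumes)) volumes[[id]] else
      simulate_subject(params, clinical[i, ], masks)
    f <- extract_subject_features(v, masks, Q = Q, distance = distance, ...)
    f <- cbind(subject_id = id, f, stringsAsFactors = FALSE)
    out[[i]] <- f
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  do.call(rbind, out)
}
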