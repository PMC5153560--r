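#' Mean ROI uptake
#'
#' Arithmetic mean of voxel intensities inside each region mask.
#'
#' @param v a `striatex_volume`.
#' @param masks a `striatex_masks` on the same grid.
#' @return list of class `striatex_uptake` with `mean_raw` (named numeric)
#'   and `n_voxels`.
#' @export
mean_roi_uptake <- function(v, masks) {
  stopifnot(is_volume(v), inherits(masks, "striatex_masks"))
  stopifnot_same_grid(v, masks)
  means <- vapply(masks$masks, function(m) {
    if (!any(m)) stop("empty mask")
    mean(v$data[m])
  }, 0)
  structure(list(mean_raw = means,
                 n_voxels = vapply(masks$masks, sum, 0L)),
            class = "striatex_uptake")
}

#' Normalize region means to the reference region
#'
#' Divides each regional mean by the reference-region mean, giving the
#' distribution-volume-ratio-like quantity used as the conventional outcome.
#' The plain ratio is returned; subtract 1 for a specific binding ratio.
#'
#' @param summary output of [mean_roi_uptake()].
#' @param reference_region region used as denominator (default `occipital`).
#' @return the summary with `mean_normalized` and `reference_mean` added.
#' @export
normalize_to_reference <- function(summary, reference_region = "occipital") {
  stopifnot(inherits(summary, "striatex_uptake"))
  if (!reference_region %in% names(summary$mean_raw))
    stop("reference region '", reference_region, "' not present")
  ref <- summary$mean_raw[[reference_region]]
  if (!is.finite(ref) || ref <= 0)
    stop("reference region mean must be positive, got ", ref)
  summary$reference_mean <- ref
  summary$mean_normalized <- summary$mean_raw / ref
  summary
}

#' Laterality index
#'
#' `|R - L| / ((R + L) / 2)`: normalized left-right asymmetry of uptake,
#' symmetric in its arguments, 0 iff the two sides agree, bounded by 2.
#' The same value results from raw or reference-normalized means, since the
#' normalization cancels in the ratio.
#'
#' @param right,left uptake on the two sides (same units; `right + left > 0`).
#' @return nonnegative real in \[0, 2\].
#' @export
laterality_index <- function(right, left) {
  if (!is.finite(right) || !is.finite(left) || right + left <= 0)
    stop("laterality index requires R + L > 0")
  abs(right - left) / ((right + left) / 2)
}

#' Assign the more affected side
#'
#' The more affected hemisphere is taken as the one with the lower
#' normalized putamen mean (dopaminergic loss is expressed earliest and most
#' strongly in the putamen); ties go to the left. The same side label is
#' then applied to the caudate.
#'
#' @param summary output of [normalize_to_reference()] containing
#'   `putamen_L` and `putamen_R`.
#' @return `"L"` or `"R"`.
#' @export
assign_affected_sides <- function(summary) {
  stopifnot(inherits(summary, "striatex_uptake"))
  vals <- summary$mean_normalized %||% summary$mean_raw
  if (!all(c("putamen_L", "putamen_R") %in% names(vals)))
    stop("both putamen regions are required to assign the affected side")
  if (vals[["putamen_L"]] <= vals[["putamen_R"]]) "L" else "R"
}
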