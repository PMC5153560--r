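#' Construct a 3D scalar volume
#'
#' A `striatex_volume` is the package's in-memory representation of a
#' reconstructed emission image: a 3D numeric array together with its voxel
#' spacing (mm) and a 4x4 voxel-to-world affine. Voxel indices are 1-based in
#' R; the affine follows the NIfTI convention and maps 0-based indices to
#' world mm, as stored in the file header.
#'
#' @param data 3D numeric array of intensities (arbitrary activity units).
#' @param spacing numeric length-3, strictly positive voxel size in mm.
#' @param affine 4x4 voxel-to-world matrix; default diagonal from `spacing`.
#' @return An object of class `striatex_volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("expected 3D volume, got ", length(dim(data)), " dimensions")
  # plain double array, shedding any foreign attributes (e.g. NIfTI headers)
  data <- array(as.double(data), dim = dim(data))
  n_bad <- sum(!is.finite(data))
  if (n_bad > 0L)
    stop("volume contains ", n_bad, " non-finite voxel(s)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values (mm)")
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  affine <- unclass(as.matrix(affine))[seq_len(4), seq_len(4)]
  attributes(affine) <- list(dim = c(4L, 4L))
  structure(list(data = data, spacing = spacing, affine = affine),
            class = "striatex_volume")
}

#' @export
print.striatex_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<striatex_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x ")))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.striatex_volume <- function(x) dim(x$data)

is_volume <- function(x) inherits(x, "striatex_volume")

stopifnot_same_grid <- function(v, masks) {
  for (nm in names(masks$masks)) {
    if (!identical(dim(masks$masks[[nm]]), dim(v$data)))
      stop("mask '", nm, "' is not on the volume grid (",
           paste(dim(masks$masks[[nm]]), collapse = "x"), " vs ",
           paste(dim(v$data), collapse = "x"), ")")
  }
  invisible(TRUE)
}

#' Region mask set
#'
#' Named binary masks on a common grid. The five canonical DAT SPECT analysis
#' regions are the left/right caudate and putamen plus an occipital reference
#' slab; additional names are tolerated but the canonical five are validated
#' when present: striatal masks must be non-empty and pairwise disjoint, and
#' the occipital mask disjoint from all of them.
#'
#' @param masks named list of logical 3D arrays, all the same shape.
#' @return Object of class `striatex_masks`.
#' @export
region_mask_set <- function(masks) {
  if (is.null(names(masks)) || any(!nzchar(names(masks))))
    stop("masks must be a named list")
  shp <- dim(masks[[1]])
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!is.array(m) || length(dim(m)) != 3L)
      stop("mask '", nm, "' is not a 3D array")
    if (!identical(dim(m), shp))
      stop("mask '", nm, "' shape differs from the others")
    if (!is.logical(m)) {
      u <- unique(as.vector(m))
      if (!all(u %in% c(0, 1)))
        stop("mask '", nm, "' has values outside {0,1}")
      masks[[nm]] <- array(as.logical(m), dim = shp)
    }
    if (!any(masks[[nm]]))
      stop("mask '", nm, "' is empty")
  }
  striatal <- intersect(names(masks), STRIATAL_REGIONS)
  if (length(striatal) > 1) {
    for (i in seq_len(length(striatal) - 1L))
      for (j in seq(i + 1L, length(striatal)))
        if (any(masks[[striatal[i]]] & masks[[striatal[j]]]))
          stop("striatal masks '", striatal[i], "' and '", striatal[j],
               "' overlap")
  }
  if ("occipital" %in% names(masks)) {
    for (s in striatal)
      if (any(masks[[s]] & masks[["occipital"]]))
        stop("occipital reference mask overlaps striatal mask '", s, "'")
  }
  structure(list(masks = masks), class = "striatex_masks")
}

#' Canonical striatal region names
#' @export
STRIATAL_REGIONS <- c("caudate_L", "caudate_R", "putamen_L", "putamen_R")

#' All canonical region names (striatal + occipital reference)
#' @export
ALL_REGIONS <- c(STRIATAL_REGIONS, "occipital")

#' @export
print.striatex_masks <- function(x, ...) {
  cat("<striatex_masks>\n")
  for (nm in names(x$masks))
    cat(sprintf("  %-12s %6d voxels\n", nm, sum(x$masks[[nm]])))
  invisible(x)
}
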