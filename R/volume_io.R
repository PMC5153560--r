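#' Read a NIfTI-1 volume
#'
#' Loads a 3D NIfTI-1 image into a [volume()], taking voxel spacing and the
#' voxel-to-world affine from the header and leaving intensities untouched.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A `striatex_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img2 <- array(as.array(img), dim = d[1:3])
  } else if (length(d) != 3L) {
    stop("expected 3D volume, got shape ", paste(d, collapse = "x"))
  } else {
    img2 <- as.array(img)
  }
  sp <- RNifti::pixdim(img)[1:3]
  aff <- tryCatch(unclass(RNifti::xform(img)), error = function(e) NULL)
  if (is.null(aff) || !all(dim(aff)[1:2] == c(4, 4))) aff <- diag(c(sp, 1))
  attributes(aff) <- list(dim = c(4L, 4L))
  volume(img2, spacing = sp, affine = aff)
}

#' Write a volume to NIfTI-1
#'
#' @param v a `striatex_volume`.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(is_volume(v))
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a set of region masks
#'
#' Two layouts are accepted: one binary NIfTI per region (`paths` a named
#' character vector), or a single integer label image plus a name-to-label
#' table (`labels` a named integer vector).
#'
#' @param paths named character vector of per-region mask files, or a single
#'   label-image path when `labels` is given.
#' @param labels optional named integer vector mapping region name to label
#'   value in the label image.
#' @return A `striatex_masks` object.
#' @export
read_mask_set <- function(paths, labels = NULL) {
  if (is.null(labels)) {
    masks <- lapply(paths, function(p) {
      v <- read_volume(p)
      u <- unique(as.vector(v$data))
      if (!all(u %in% c(0, 1)))
        stop("mask file ", p, " has values outside {0,1}")
      array(v$data > 0.5, dim = dim(v$data))
    })
    names(masks) <- names(paths)
  } else {
    stopifnot(length(paths) == 1L, !is.null(names(labels)))
    lab <- read_volume(paths)$data
    masks <- lapply(labels, function(l) array(abs(lab - l) < 0.5, dim = dim(lab)))
    names(masks) <- names(labels)
  }
  region_mask_set(masks)
}

#' Rigid-body transform
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 vector in mm.
#' @return Object of class `striatex_rigid`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3)))
    stop("rotation must be 3x3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation matrix is not orthonormal")
  if (det(rotation) < 0)
    stop("rotation matrix must have determinant +1 (no reflection)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "striatex_rigid")
}

#' Read a rigid transform stored as a 4x4 row-major text matrix
#'
#' @param path text file with four rows of four numbers (world-mm convention).
#' @return A `striatex_rigid`.
#' @export
read_rigid_transform <- function(path) {
  m <- as.matrix(utils::read.table(path))
  if (!all(dim(m) == c(4, 4))) stop("expected a 4x4 matrix in ", path)
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

#' Resample a volume onto a target grid under a rigid transform
#'
#' For each target voxel, its world coordinate is mapped into the moving
#' volume's world space by `x_mov = R x_tgt + t` and the moving image is
#' sampled there by trilinear interpolation; voxels that land outside the
#' moving field of view are set to 0. With the identity transform and
#' identical grids the input values are returned exactly.
#'
#' @param moving `striatex_volume` to be resampled.
#' @param target_grid `striatex_volume` supplying the output grid.
#' @param transform a [rigid_transform()].
#' @return A `striatex_volume` on the target grid.
#' @export
resample_rigid <- function(moving, target_grid, transform = rigid_transform()) {
  stopifnot(is_volume(moving), is_volume(target_grid),
            inherits(transform, "striatex_rigid"))
  dt <- dim(target_grid$data)
  # world coordinates of all target voxels (0-based index convention)
  idx <- as.matrix(expand.grid(i = seq_len(dt[1]) - 1L,
                               j = seq_len(dt[2]) - 1L,
                               k = seq_len(dt[3]) - 1L))
  wt <- cbind(idx, 1) %*% t(target_grid$affine)
  wm <- sweep(wt[, 1:3, drop = FALSE] %*% t(transform$rotation), 2,
              transform$translation, "+")
  # continuous 0-based indices into the moving grid
  inv_aff <- solve(moving$affine)
  cm <- cbind(wm, 1) %*% t(inv_aff)
  out <- trilinear_sample(moving$data, cm[, 1:3, drop = FALSE])
  volume(array(out, dim = dt), spacing = target_grid$spacing,
         affine = target_grid$affine)
}

# Trilinear interpolation at continuous 0-based coordinates; 0 outside.
trilinear_sample <- function(a, xyz) {
  d <- dim(a)
  x <- xyz[, 1]; y <- xyz[, 2]; z <- xyz[, 3]
  inb <- x >= 0 & x <= d[1] - 1 & y >= 0 & y <= d[2] - 1 & z >= 0 & z <= d[3] - 1
  out <- numeric(length(x))
  if (!any(inb)) return(out)
  x <- x[inb]; y <- y[inb]; z <- z[inb]
  x0 <- pmin(floor(x), d[1] - 2); y0 <- pmin(floor(y), d[2] - 2)
  z0 <- pmin(floor(z), d[3] - 2)
  x0 <- pmax(x0, 0); y0 <- pmax(y0, 0); z0 <- pmax(z0, 0)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  at <- function(ix, iy, iz) a[cbind(ix + 1L, iy + 1L, iz + 1L)]
  v <- (1 - fx) * (1 - fy) * (1 - fz) * at(x0,     y0,     z0) +
       fx       * (1 - fy) * (1 - fz) * at(x0 + 1, y0,     z0) +
       (1 - fx) * fy       * (1 - fz) * at(x0,     y0 + 1, z0) +
       fx       * fy       * (1 - fz) * at(x0 + 1, y0 + 1, z0) +
       (1 - fx) * (1 - fy) * fz       * at(x0,     y0,     z0 + 1) +
       fx       * (1 - fy) * fz       * at(x0 + 1, y0,     z0 + 1) +
       (1 - fx) * fy       * fz       * at(x0,     y0 + 1, z0 + 1) +
       fx       * fy       * fz       * at(x0 + 1, y0 + 1, z0 + 1)
  out[inb] <- v
  out
}

#' Isotropic Gaussian smoothing
#'
#' Separable Gaussian filter with `sigma = fwhm_mm / (2 sqrt(2 ln 2))` in mm,
#' converted per axis to voxel units through the volume's spacing. The kernel
#' is renormalized at the array boundary (zero-flux), so constant volumes are
#' preserved exactly and total intensity is conserved in the interior sense.
#'
#' @param v a `striatex_volume`.
#' @param fwhm_mm full width at half maximum in mm (> 0).
#' @return Smoothed `striatex_volume` on the same grid.
#' @export
gaussian_smooth <- function(v, fwhm_mm) {
  stopifnot(is_volume(v))
  if (!is.finite(fwhm_mm) || fwhm_mm <= 0) stop("fwhm_mm must be positive")
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  a <- v$data
  ones <- array(1, dim = dim(a))
  for (axis in 1:3) {
    sig <- sigma_mm / v$spacing[axis]
    r <- max(1L, ceiling(4 * sig))
    w <- exp(-((-r:r)^2) / (2 * sig^2))
    w <- w / sum(w)
    a <- convolve_axis(a, w, axis)
    ones <- convolve_axis(ones, w, axis)
  }
  volume(a / ones, spacing = v$spacing, affine = v$affine)
}

# 1D convolution along one axis with zero padding, vectorized over the array.
convolve_axis <- function(a, w, axis) {
  d <- dim(a)
  r <- (length(w) - 1L) / 2L
  out <- array(0, dim = d)
  n <- d[axis]
  for (k in seq_along(w)) {
    off <- k - 1L - r           # source index offset
    src_lo <- max(1L, 1L + off); src_hi <- min(n, n + off)
    if (src_lo > src_hi) next
    dst_lo <- src_lo - off; dst_hi <- src_hi - off
    idx_src <- switch(axis,
      list(src_lo:src_hi, TRUE, TRUE),
      list(TRUE, src_lo:src_hi, TRUE),
      list(TRUE, TRUE, src_lo:src_hi))
    idx_dst <- switch(axis,
      list(dst_lo:dst_hi, TRUE, TRUE),
      list(TRUE, dst_lo:dst_hi, TRUE),
      list(TRUE, TRUE, dst_lo:dst_hi))
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] +
      w[k] * a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  }
  out
}
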