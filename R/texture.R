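#' Quantize a region of interest to Q gray levels
#'
#' Per-ROI min-max quantization:
#' `level(x) = min(Q, floor((v(x) - vmin) / (vmax - vmin) * Q) + 1)` with
#' `vmin`/`vmax` the in-mask extremes, so the levels (and therefore every
#' downstream texture feature) are invariant under positive affine intensity
#' transforms of the volume. A constant ROI maps entirely to level 1.
#'
#' @param v a `striatex_volume`.
#' @param mask logical 3D array on the volume grid.
#' @param Q number of gray levels (default 32, minimum 2).
#' @return list of class `striatex_quantized`: `levels` (integer array, NA
#'   outside the mask), `Q`, `vmin`, `vmax`, `mask`.
#' @export
quantize_roi <- function(v, mask, Q = 32L) {
  stopifnot(is_volume(v))
  if (Q < 2) stop("Q must be at least 2")
  if (!identical(dim(mask), dim(v$data))) stop("mask is not on the volume grid")
  if (!any(mask)) stop("empty mask")
  vals <- v$data[mask]
  vmin <- min(vals); vmax <- max(vals)
  lev <- array(NA_integer_, dim = dim(v$data))
  if (vmax == vmin) {
    lev[mask] <- 1L
  } else {
    lev[mask] <- pmin(Q, floor((vals - vmin) / (vmax - vmin) * Q) + 1L)
  }
  structure(list(levels = lev, Q = as.integer(Q), vmin = vmin, vmax = vmax,
                 mask = mask),
            class = "striatex_quantized")
}

#' The 13 unique 3D unit-neighborhood directions
#'
#' The 26-connected neighborhood of a voxel contains 13 direction pairs up
#' to central symmetry; one representative of each is used, scaled by the
#' co-occurrence distance.
#'
#' @param distance integer voxel separation (default 1).
#' @return 13 x 3 integer matrix of offsets.
#' @export
glcm_directions <- function(distance = 1L) {
  d <- rbind(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0),
             c(0, 1, 1), c(0, 1, -1), c(1, 0, 1), c(1, 0, -1),
             c(1, 1, 0), c(1, -1, 0),
             c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  d * as.integer(distance)
}

#' Build the masked 3D gray-level co-occurrence matrix
#'
#' For each of the 13 directions, ordered level pairs are counted over voxel
#' pairs with both endpoints inside the mask, symmetrized by adding the
#' transpose; the 13 raw count matrices are averaged and the average
#' normalized to sum 1.
#'
#' @param q a [quantize_roi()] result.
#' @param distance voxel separation between co-occurring voxels (default 1).
#' @return list of class `striatex_glcm`: `p` (QxQ joint probabilities),
#'   `n_pairs_per_direction` (13 ordered-pair counts), `directions`, `Q`,
#'   `distance`.
#' @export
build_glcm <- function(q, distance = 1L) {
  stopifnot(inherits(q, "striatex_quantized"))
  Q <- q$Q
  dirs <- glcm_directions(distance)
  d <- dim(q$levels)
  acc <- matrix(0, Q, Q)
  n_pairs <- integer(nrow(dirs))
  for (k in seq_len(nrow(dirs))) {
    off <- dirs[k, ]
    # overlapping index ranges of the array and its shifted copy
    rng <- lapply(1:3, function(ax) {
      o <- off[ax]
      lo <- max(1L, 1L - o); hi <- min(d[ax], d[ax] - o)
      if (lo > hi) integer(0) else lo:hi
    })
    if (any(lengths(rng) == 0)) next
    a <- q$levels[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    b <- q$levels[rng[[1]] + off[1], rng[[2]] + off[2], rng[[3]] + off[3],
                  drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    av <- a[ok]; bv <- b[ok]
    n_pairs[k] <- length(av)
    cnt <- matrix(tabulate((av - 1L) * Q + bv, nbins = Q * Q), Q, Q,
                  byrow = TRUE)
    acc <- acc + cnt + t(cnt)
  }
  if (sum(n_pairs) == 0)
    stop("degenerate ROI: no in-mask voxel pair in any direction")
  avg <- acc / nrow(dirs)
  structure(list(p = avg / sum(avg), n_pairs_per_direction = n_pairs,
                 directions = dirs, Q = Q, distance = as.integer(distance)),
            class = "striatex_glcm")
}

#' Haralick texture features of a co-occurrence matrix
#'
#' Computes the 13 scalar texture statistics from a normalized symmetric
#' GLCM `p(i,j)`, `i,j = 1..Q`, with marginals `px(i) = sum_j p(i,j)`,
#' `mu = sum_i i px(i)` and `sigma^2 = sum_i (i-mu)^2 px(i)` (row and column
#' marginals coincide by symmetry):
#' energy `sum p^2`; entropy `-sum_{p>0} p log2 p`; correlation
#' `(sum ij p - mu^2)/sigma^2`; contrast `sum (i-j)^2 p`; variance
#' `sum (i-mu)^2 p`; sum mean `0.5 sum (i+j) p`; agreement (Cohen's kappa)
#' `(Po-Pe)/(1-Pe)` with `Po = sum_i p(i,i)`, `Pe = sum_i px(i)^2`; cluster
#' shade `sum (i+j-2mu)^3 p`; cluster tendency (prominence)
#' `sum (i+j-2mu)^4 p`; homogeneity `sum p/(1+|i-j|)`; max probability
#' `max p`; inverse variance `sum_{i != j} p/(i-j)^2`; dissimilarity
#' `sum |i-j| p`.
#'
#' Degenerate cases: a zero marginal variance gives correlation 0; if
#' `Pe = 1` agreement is 1 when `Po = 1` and 0 otherwise.
#'
#' @param m a `striatex_glcm` (or a plain normalized symmetric matrix).
#' @param homogeneity_form `"inverse_difference"` (default, `1/(1+|i-j|)`)
#'   or `"inverse_difference_squared"` (`1/(1+(i-j)^2)`).
#' @param cluster_tendency_exponent 4 (prominence, default) or 2.
#' @return named numeric vector of the 13 features.
#' @export
haralick_features <- function(m, homogeneity_form =
                                c("inverse_difference",
                                  "inverse_difference_squared"),
                              cluster_tendency_exponent = 4) {
  homogeneity_form <- match.arg(homogeneity_form)
  p <- if (inherits(m, "striatex_glcm")) m$p else as.matrix(m)
  if (abs(sum(p) - 1) > 1e-6)
    stop("co-occurrence matrix is not normalized (sum = ", sum(p), ")")
  if (any(p < 0)) stop("co-occurrence matrix has negative entries")
  Q <- nrow(p)
  i <- seq_len(Q)
  ii <- matrix(i, Q, Q); jj <- t(ii)
  px <- rowSums(p)
  mu <- sum(i * px)
  sig2 <- sum((i - mu)^2 * px)
  corr <- if (sig2 > 0) (sum(ii * jj * p) - mu^2) / sig2 else 0
  po <- sum(diag(p)); pe <- sum(px^2)
  agreement <- if (abs(1 - pe) < .Machine$double.eps * 8) {
    if (abs(1 - po) < 1e-12) 1 else 0
  } else (po - pe) / (1 - pe)
  hom_w <- switch(homogeneity_form,
                  inverse_difference = 1 / (1 + abs(ii - jj)),
                  inverse_difference_squared = 1 / (1 + (ii - jj)^2))
  offd <- ii != jj
  c(energy = sum(p^2),
    entropy = { pp <- p[p > 0]; -sum(pp * log2(pp)) },
    correlation = corr,
    contrast = sum((ii - jj)^2 * p),
    variance = sum((ii - mu)^2 * p),
    sum_mean = 0.5 * sum((ii + jj) * p),
    agreement = agreement,
    cluster_shade = sum((ii + jj - 2 * mu)^3 * p),
    cluster_tendency = sum((ii + jj - 2 * mu)^cluster_tendency_exponent * p),
    homogeneity = sum(hom_w * p),
    max_probability = max(p),
    inverse_variance = sum(p[offd] / (ii - jj)[offd]^2),
    dissimilarity = sum(abs(ii - jj) * p))
}

#' Quantize, build the GLCM and compute texture features for one region
#'
#' Composition of [quantize_roi()], [build_glcm()] and
#' [haralick_features()], with provenance (Q, distance, pair counts)
#' attached. A degenerate ROI (no valid voxel pair) yields all-NA features
#' with `degenerate = TRUE` rather than an error, so cohort runs can carry
#' the missingness forward.
#'
#' @param v a `striatex_volume`.
#' @param masks a `striatex_masks`.
#' @param region region name present in `masks`.
#' @param Q gray levels (default 32).
#' @param distance co-occurrence distance in voxels (default 1).
#' @param ... feature-variant switches passed to [haralick_features()].
#' @return list: `features` (named numeric), `Q`, `distance`, `n_directions`,
#'   `n_pairs`, `degenerate`.
#' @export
texture_for_region <- function(v, masks, region, Q = 32L, distance = 1L, ...) {
  stopifnot(inherits(masks, "striatex_masks"))
  if (!region %in% names(masks$masks))
    stop("region '", region, "' not in mask set (have: ",
         paste(names(masks$masks), collapse = ", "), ")")
  q <- quantize_roi(v, masks$masks[[region]], Q = Q)
  g <- tryCatch(build_glcm(q, distance = distance), error = function(e) e)
  if (inherits(g, "error")) {
    feats <- stats::setNames(rep(NA_real_, length(HARALICK_FEATURES)),
                             HARALICK_FEATURES)
    return(list(features = feats, Q = as.integer(Q),
                distance = as.integer(distance), n_directions = 13L,
                n_pairs = 0L, degenerate = TRUE))
  }
  list(features = haralick_features(g, ...), Q = as.integer(Q),
       distance = as.integer(distance), n_directions = nrow(g$directions),
       n_pairs = sum(g$n_pairs_per_direction), degenerate = FALSE)
}
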