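# Independent brute-force oracles, written as literal transcriptions of the
# definitions. They share no code with the package implementation.

oracle_quantize <- function(vals, Q) {
  vmin <- min(vals); vmax <- max(vals)
  if (vmax == vmin) return(rep(1L, length(vals)))
  pmin(Q, floor((vals - vmin) / (vmax - vmin) * Q) + 1L)
}

oracle_directions <- function() {
  list(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0),
       c(0, 1, 1), c(0, 1, -1), c(1, 0, 1), c(1, 0, -1),
       c(1, 1, 0), c(1, -1, 0),
       c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
}

# Literal enumeration: every voxel, every direction, both orders.
oracle_glcm <- function(arr, mask, Q, distance = 1L) {
  d <- dim(arr)
  lev <- array(NA_integer_, dim = d)
  lev[mask] <- oracle_quantize(arr[mask], Q)
  dirs <- oracle_directions()
  acc <- matrix(0, Q, Q)
  total <- 0
  for (dir in dirs) {
    off <- dir * distance
    cnt <- matrix(0, Q, Q)
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
      x2 <- x + off[1]; y2 <- y + off[2]; z2 <- z + off[3]
      if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] || z2 < 1 || z2 > d[3])
        next
      a <- lev[x, y, z]; b <- lev[x2, y2, z2]
      if (is.na(a) || is.na(b)) next
      cnt[a, b] <- cnt[a, b] + 1
      cnt[b, a] <- cnt[b, a] + 1
    }
    acc <- acc + cnt
    total <- total + sum(cnt)
  }
  if (total == 0) stop("oracle: degenerate ROI")
  avg <- acc / length(dirs)
  avg / sum(avg)
}

# Literal double-loop summation of each feature definition.
oracle_haralick <- function(p) {
  Q <- nrow(p)
  px <- numeric(Q)
  for (i in 1:Q) for (j in 1:Q) px[i] <- px[i] + p[i, j]
  mu <- 0; for (i in 1:Q) mu <- mu + i * px[i]
  sig2 <- 0; for (i in 1:Q) sig2 <- sig2 + (i - mu)^2 * px[i]
  energy <- 0; entropy <- 0; sumij <- 0; contrast <- 0; variance <- 0
  sum_mean <- 0; shade <- 0; tend <- 0; hom <- 0; invvar <- 0; dissim <- 0
  po <- 0; pe <- 0; maxp <- 0
  for (i in 1:Q) for (j in 1:Q) {
    pij <- p[i, j]
    energy <- energy + pij^2
    if (pij > 0) entropy <- entropy - pij * log2(pij)
    sumij <- sumij + i * j * pij
    contrast <- contrast + (i - j)^2 * pij
    variance <- variance + (i - mu)^2 * pij
    sum_mean <- sum_mean + 0.5 * (i + j) * pij
    shade <- shade + (i + j - 2 * mu)^3 * pij
    tend <- tend + (i + j - 2 * mu)^4 * pij
    hom <- hom + pij / (1 + abs(i - j))
    if (i != j) invvar <- invvar + pij / (i - j)^2
    dissim <- dissim + abs(i - j) * pij
    if (pij > maxp) maxp <- pij
  }
  for (i in 1:Q) { po <- po + p[i, i]; pe <- pe + px[i]^2 }
  corr <- if (sig2 > 0) (sumij - mu^2) / sig2 else 0
  agreement <- if (abs(1 - pe) < 1e-15) { if (abs(1 - po) < 1e-12) 1 else 0 }
    else (po - pe) / (1 - pe)
  c(energy = energy, entropy = entropy, correlation = corr,
    contrast = contrast, variance = variance, sum_mean = sum_mean,
    agreement = agreement, cluster_shade = shade, cluster_tendency = tend,
    homogeneity = hom, max_probability = maxp, inverse_variance = invvar,
    dissimilarity = dissim)
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# Exhaustive scan over all m candidate step-up thresholds.
oracle_bh <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k_star <- 0
  for (k in 1:m) if (ps[k] <= k / m * alpha) k_star <- k
  sig <- logical(m)
  if (k_star > 0) sig[o[1:k_star]] <- TRUE
  sig
}

# random symmetric normalized matrix
random_sym_glcm <- function(Q) {
  a <- matrix(stats::runif(Q * Q), Q, Q)
  a <- a + t(a)
  a / sum(a)
}
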