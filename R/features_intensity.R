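#' Fixed-bin-width discretisation of ROI intensities
#'
#' Quantises intensities into integer grey levels with fixed bin width,
#' anchored at the ROI minimum, as required by the co-occurrence features.
#' A constant ROI maps to a single level; shifting all intensities by a
#' constant leaves the level array unchanged (min-anchored binning).
#'
#' @param x Numeric vector of intensities inside the ROI (non-empty).
#' @param n_bins Number of bins used to derive the width (`range / n_bins`);
#'   ignored when `bin_width` is given.
#' @param bin_width Explicit bin width (same units as `x`).
#' @return List with `levels` (integers in `1:n_levels`) and `n_levels`.
#' @export
discretise <- function(x, n_bins = 32L, bin_width = NULL) {
  if (length(x) == 0L) stop("empty ROI", call. = FALSE)
  rng <- max(x) - min(x)
  if (rng == 0) return(list(levels = rep(1L, length(x)), n_levels = 1L))
  if (is.null(bin_width)) bin_width <- rng / n_bins
  if (!is.finite(bin_width) || bin_width <= 0) {
    stop("bin width must be positive", call. = FALSE)
  }
  lev <- floor((x - min(x)) / bin_width) + 1L
  lev <- pmin(lev, max(lev))  # top edge closed
  nl <- max(lev)
  list(levels = as.integer(lev), n_levels = as.integer(nl))
}

first_order_names <- c(
  "mean", "median", "minimum", "maximum", "range", "variance", "sd",
  "skewness", "kurtosis", "energy", "rms", "entropy", "uniformity",
  "p10", "p25", "p75", "p90", "iqr"
)

#' First-order (histogram) features of an ROI
#'
#' Standard moment and order statistics of the intensities in an ROI.
#' Variance and SD are population moments.  Entropy and uniformity are
#' computed on the min-anchored fixed-bin-width histogram (`n_bins`).
#' For a single-voxel ROI, skewness and kurtosis are undefined and returned
#' as `NA` (explicit missing), never silently.
#'
#' @param x Numeric vector of ROI intensities (>= 1 voxel).
#' @param n_bins Histogram bins for entropy/uniformity.
#' @return Named numeric vector of the 18 first-order features.
#' @export
first_order_features <- function(x, n_bins = 32L) {
  if (length(x) == 0L) stop("empty ROI", call. = FALSE)
  n <- length(x)
  mu <- mean(x)
  v <- mean((x - mu)^2)
  s <- sqrt(v)
  q <- unname(stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), type = 7))
  skew <- if (n > 1 && s > 0) mean((x - mu)^3) / s^3 else NA_real_
  kurt <- if (n > 1 && s > 0) mean((x - mu)^4) / s^4 else NA_real_
  disc <- discretise(x, n_bins = n_bins)
  p <- tabulate(disc$levels, disc$n_levels) / n
  p <- p[p > 0]
  c(mean = mu, median = q[3], minimum = min(x), maximum = max(x),
    range = max(x) - min(x), variance = v, sd = s,
    skewness = skew, kurtosis = kurt,
    energy = sum(x^2), rms = sqrt(mean(x^2)),
    entropy = -sum(p * log2(p)), uniformity = sum(p^2),
    p10 = q[1], p25 = q[2], p75 = q[4], p90 = q[5], iqr = q[4] - q[2])
}

# The 13 unique 3D co-occurrence directions (offsets with first non-zero
# component positive), at voxel distance 1.
glcm_directions <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- apply(g, 1, function(v) {
    nz <- which(v != 0)
    length(nz) > 0 && v[nz[1]] > 0
  })
  g[keep, , drop = FALSE]
}

glcm_feature_names <- c(
  "autocorrelation", "cluster_prominence", "cluster_shade", "contrast",
  "correlation", "difference_entropy", "difference_variance", "dissimilarity",
  "energy", "entropy", "homogeneity", "inverse_difference", "joint_average",
  "joint_variance", "max_probability", "sum_average", "sum_entropy",
  "sum_variance"
)

# Index geometry of an nl x nl GLCM, cached per matrix size.
glcm_geom_cache <- new.env(parent = emptyenv())
glcm_geometry <- function(nl) {
  key <- as.character(nl)
  g <- glcm_geom_cache[[key]]
  if (is.null(g)) {
    i <- matrix(seq_len(nl), nl, nl)
    j <- t(i)
    g <- list(i = i, j = j, d_ij = abs(i - j), s_ij = i + j)
    glcm_geom_cache[[key]] <- g
  }
  g
}

# Features of one normalised symmetric GLCM.
glcm_matrix_features <- function(P) {
  nl <- nrow(P)
  geom <- glcm_geometry(nl)
  i <- geom$i; j <- geom$j; d_ij <- geom$d_ij; s_ij <- geom$s_ij
  pij <- P
  mu <- sum(i * pij)  # symmetric: row mean = col mean
  sig2 <- sum((i - mu)^2 * pij)
  pd <- P[pij > 0]
  # diagonal / cross-diagonal distributions (all levels 0..nl-1 / 2..2nl occur)
  pdiff <- as.vector(rowsum(as.vector(pij), as.vector(d_ij)))
  psum <- as.vector(rowsum(as.vector(pij), as.vector(s_ij)))
  kd <- 0:(nl - 1); ks <- 2:(2 * nl)
  mud <- sum(kd * pdiff)
  mus <- sum(ks * psum)
  pd2 <- pdiff[pdiff > 0]; ps2 <- psum[psum > 0]
  correlation <- if (sig2 > 0) sum((i - mu) * (j - mu) * pij) / sig2 else 1
  c(autocorrelation = sum(i * j * pij),
    cluster_prominence = sum((i + j - 2 * mu)^4 * pij),
    cluster_shade = sum((i + j - 2 * mu)^3 * pij),
    contrast = sum((i - j)^2 * pij),
    correlation = correlation,
    difference_entropy = -sum(pd2 * log2(pd2)),
    difference_variance = sum((kd - mud)^2 * pdiff),
    dissimilarity = sum(d_ij * pij),
    energy = sum(pij^2),
    entropy = -sum(pd * log2(pd)),
    homogeneity = sum(pij / (1 + (i - j)^2)),
    inverse_difference = sum(pij / (1 + d_ij)),
    joint_average = mu,
    joint_variance = sig2,
    max_probability = max(pij),
    sum_average = mus,
    sum_entropy = -sum(ps2 * log2(ps2)),
    sum_variance = sum((ks - mus)^2 * psum))
}

# Precompute, for a grid of dimensions `d`, the linear-index pairs of every
# in-grid voxel pair for each co-occurrence direction.  Reused across ROIs
# and image types of one case.
glcm_pair_index <- function(d, dirs = glcm_directions()) {
  ix <- seq_len(d[1]); iy <- seq_len(d[2]); iz <- seq_len(d[3])
  lin <- function(x, y, z) x + (y - 1L) * d[1] + (z - 1L) * d[1] * d[2]
  lapply(seq_len(nrow(dirs)), function(k) {
    dx <- dirs[k, 1]; dy <- dirs[k, 2]; dz <- dirs[k, 3]
    vx <- ix[ix + dx >= 1L & ix + dx <= d[1]]
    vy <- iy[iy + dy >= 1L & iy + dy <= d[2]]
    vz <- iz[iz + dz >= 1L & iz + dz <= d[3]]
    g <- expand.grid(x = vx, y = vy, z = vz)
    list(from = lin(g$x, g$y, g$z), to = lin(g$x + dx, g$y + dy, g$z + dz))
  })
}

#' Grey-level co-occurrence features of an ROI
#'
#' Builds one symmetric, normalised co-occurrence matrix per direction
#' (default: the 13 unique 3D directions at voxel distance 1) from the
#' discretised intensities inside the mask, computes the standard GLCM
#' features on each, and averages over directions.  On a single-grey-level
#' ROI, correlation is defined as 1 and all difference-based features are 0.
#'
#' @param levels Integer 3D array of grey levels (only values inside `mask`
#'   are used).
#' @param mask Logical 3D array, the ROI.
#' @param n_levels Number of grey levels in `levels`.
#' @param pair_index Optional precomputed [glcm_pair_index()] for `dim(mask)`.
#' @param directions Optional integer matrix of offset rows `(dx, dy, dz)`
#'   replacing the default 13-direction set (ignored when `pair_index` is
#'   given).
#' @return Named numeric vector of the 18 direction-averaged GLCM features.
#' @export
glcm_features <- function(levels, mask, n_levels, pair_index = NULL,
                          directions = NULL) {
  if (sum(mask) < 2) stop("GLCM needs >= 2 voxels", call. = FALSE)
  if (is.null(pair_index)) {
    dirs <- if (is.null(directions)) glcm_directions() else as.matrix(directions)
    pair_index <- glcm_pair_index(dim(mask), dirs)
  }
  glcm_features_pairs(levels, roi_pair_index(mask, pair_index), n_levels)
}

# Restrict the full-grid pair index to pairs with both endpoints in the ROI;
# reusable across all image types of one case.
roi_pair_index <- function(mask, pair_index) {
  lapply(pair_index, function(p) {
    sel <- mask[p$from] & mask[p$to]
    list(from = p$from[sel], to = p$to[sel])
  })
}

glcm_features_pairs <- function(levels, roi_pairs, n_levels) {
  nl <- as.integer(n_levels)
  acc <- matrix(0, length(roi_pairs), length(glcm_feature_names),
                dimnames = list(NULL, glcm_feature_names))
  used <- 0L
  for (k in seq_along(roi_pairs)) {
    pi_k <- roi_pairs[[k]]
    if (length(pi_k$from) == 0L) next
    a <- levels[pi_k$from]
    b <- levels[pi_k$to]
    counts <- tabulate((a - 1L) * nl + b, nl * nl) +
      tabulate((b - 1L) * nl + a, nl * nl)  # symmetrise
    P <- matrix(counts / sum(counts), nl, nl)
    used <- used + 1L
    acc[used, ] <- glcm_matrix_features(P)
  }
  if (used == 0L) stop("no co-occurring voxel pairs in ROI", call. = FALSE)
  colMeans(acc[seq_len(used), , drop = FALSE])
}
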