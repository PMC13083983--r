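shape_feature_names <- c(
  "volume_mm3", "surface_area_mm2", "surface_to_volume_ratio", "sphericity",
  "compactness1", "compactness2", "spherical_disproportion",
  "maximum_3d_diameter_mm", "major_axis_length_mm", "minor_axis_length_mm",
  "least_axis_length_mm", "elongation", "flatness", "extent"
)

#' Shape features of a binary ROI mask
#'
#' Spacing-aware morphological descriptors computed from the mask alone
#' (intensity filters never change them): voxel volume, exposed-face surface
#' area, sphericity and related compactness measures, the maximum pairwise
#' surface-voxel distance, PCA axis lengths (4 sd of the voxel-centre
#' point cloud per principal axis), elongation, flatness, and bounding-box
#' extent.
#'
#' @param mask Logical 3D array (non-empty).
#' @param spacing_mm Voxel spacing in mm.
#' @return Named numeric vector of 14 shape features.
#' @export
shape_features <- function(mask, spacing_mm) {
  if (!any(mask)) stop("empty ROI mask", call. = FALSE)
  d <- dim(mask)
  vv <- prod(spacing_mm)
  n <- sum(mask)
  volume <- n * vv

  # surface area: faces exposed to background (or the grid boundary)
  face_area <- c(spacing_mm[2] * spacing_mm[3],
                 spacing_mm[1] * spacing_mm[3],
                 spacing_mm[1] * spacing_mm[2])
  surface <- 0
  exposed_any <- array(FALSE, d)
  for (ax in 1:3) for (dir in c(-1L, 1L)) {
    idx <- seq_len(d[ax]) + dir
    outside <- idx < 1L | idx > d[ax]
    idx[outside] <- 1L
    nb <- index_axis(mask, ax, idx)
    dim(nb) <- d
    if (any(outside)) {
      edge <- array(FALSE, d)
      edge_idx <- which(outside)
      edge <- index_assign_axis(edge, ax, edge_idx, TRUE)
      nb[edge] <- FALSE
    }
    exp_face <- mask & !nb
    surface <- surface + sum(exp_face) * face_area[ax]
    exposed_any <- exposed_any | exp_face
  }

  # maximum 3D diameter over surface voxels (subsampled deterministically if
  # very large; error < one voxel is acceptable at radiomics scale)
  pts <- which(exposed_any, arr.ind = TRUE)
  if (nrow(pts) > 2500L) {
    pts <- pts[seq(1L, nrow(pts), length.out = 2500L), , drop = FALSE]
  }
  w <- sweep(pts - 1, 2, spacing_mm, "*")
  max_diam <- if (nrow(w) > 1) max(stats::dist(w)) else 0

  # PCA axis lengths of the voxel-centre cloud
  allpts <- which(mask, arr.ind = TRUE)
  wc <- sweep(allpts - 1, 2, spacing_mm, "*")
  if (nrow(wc) > 1) {
    ev <- sort(eigen(stats::cov(wc), symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, 0)
  } else ev <- c(0, 0, 0)
  axes <- 4 * sqrt(ev)

  bb <- apply(allpts, 2, range)
  bb_vol <- prod((bb[2, ] - bb[1, ] + 1) * spacing_mm)

  sph <- (pi^(1 / 3)) * (6 * volume)^(2 / 3) / surface
  c(volume_mm3 = volume,
    surface_area_mm2 = surface,
    surface_to_volume_ratio = surface / volume,
    sphericity = sph,
    compactness1 = volume / (sqrt(pi) * surface^(3 / 2)),
    compactness2 = 36 * pi * volume^2 / surface^3,
    spherical_disproportion = 1 / sph,
    maximum_3d_diameter_mm = max_diam,
    major_axis_length_mm = axes[1],
    minor_axis_length_mm = axes[2],
    least_axis_length_mm = axes[3],
    elongation = if (axes[1] > 0) sqrt(ev[2] / ev[1]) else NA_real_,
    flatness = if (axes[1] > 0) sqrt(ev[3] / ev[1]) else NA_real_,
    extent = volume / bb_vol)
}

# assign `value` to a whole slab of `a` along `axis` at indices `idx`
index_assign_axis <- function(a, axis, idx, value) {
  switch(axis,
    { a[idx, , ] <- value; a },
    { a[, idx, ] <- value; a },
    { a[, , idx] <- value; a }
  )
}
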