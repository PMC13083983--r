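#' Metric dilation of a binary mask
#'
#' Dilates a mask by a Euclidean metric ball of the given physical radius,
#' respecting anisotropic voxel spacing: the result is exactly the set of
#' voxels whose centre lies within `radius_mm` of some mask voxel centre
#' (the distance-transform threshold).  Implemented as an FFT convolution of
#' the mask with the ellipsoidal structuring element, which is exact for the
#' integer-valued counts being thresholded.
#'
#' @param mask Logical 3D array.
#' @param spacing_mm Voxel spacing (mm) per axis.
#' @param radius_mm Positive dilation radius in mm.
#' @return Logical array of the same dimensions.
#' @export
dilate_mask <- function(mask, spacing_mm, radius_mm) {
  stopifnot_scalar_pos(radius_mm, "radius_mm")
  d <- dim(mask)
  rv <- pmin(ceiling(radius_mm / spacing_mm), d)  # kernel half-width in voxels
  off <- expand.grid(x = -rv[1]:rv[1], y = -rv[2]:rv[2], z = -rv[3]:rv[3])
  keep <- sqrt((off$x * spacing_mm[1])^2 + (off$y * spacing_mm[2])^2 +
                 (off$z * spacing_mm[3])^2) <= radius_mm + 1e-9
  off <- off[keep, , drop = FALSE]

  pd <- d + 2 * rv
  mp <- array(0, pd)
  mp[rv[1] + seq_len(d[1]), rv[2] + seq_len(d[2]), rv[3] + seq_len(d[3])] <-
    as.numeric(mask)
  kp <- array(0, pd)
  kp[cbind((off$x %% pd[1]) + 1L, (off$y %% pd[2]) + 1L, (off$z %% pd[3]) + 1L)] <- 1
  conv <- Re(fft(fft(mp) * fft(kp), inverse = TRUE)) / prod(pd)
  out <- conv[rv[1] + seq_len(d[1]), rv[2] + seq_len(d[2]), rv[3] + seq_len(d[3])] > 0.5
  array(out, d)
}

#' Derive the perilesional annulus from a lesion mask
#'
#' Returns the shell of fixed physical thickness around the lesion: the
#' lesion dilated by `thickness_mm` (metric ball, anisotropy-aware) minus
#' the lesion itself.
#'
#' @param lesion_mask Logical 3D lesion mask (non-empty).
#' @param spacing_mm Voxel spacing (mm).
#' @param thickness_mm Shell thickness in mm; the analysis default is 5.
#' @return Logical annulus mask, disjoint from the lesion by construction.
#' @export
derive_annulus <- function(lesion_mask, spacing_mm, thickness_mm = 5) {
  if (!any(lesion_mask)) stop("lesion mask is empty", call. = FALSE)
  if (!is.numeric(thickness_mm) || thickness_mm <= 0) {
    stop("`thickness_mm` must be positive", call. = FALSE)
  }
  dilate_mask(lesion_mask, spacing_mm, thickness_mm) & !lesion_mask
}

#' Place a spherical parenchymal patch
#'
#' Finds a centre for a metric ball of the requested diameter (default 2 cm)
#' that lies entirely inside the allowed background region, fully inside the
#' grid, and disjoint from both the lesion and its perilesional annulus; the
#' centre is drawn uniformly from all feasible voxels under `seed`.
#'
#' @param background_mask Logical array of voxels available for the patch
#'   (e.g. aerated lung).
#' @param lesion_mask Logical lesion mask on the same grid.
#' @param spacing_mm Voxel spacing (mm).
#' @param diameter_mm Patch diameter in mm (default 20).
#' @param annulus_thickness_mm Thickness of the exclusion annulus (mm).
#' @param seed Integer seed making the placement deterministic.
#' @return Logical patch mask.
#' @export
place_parenchymal_patch <- function(background_mask, lesion_mask, spacing_mm,
                                    diameter_mm = 20, annulus_thickness_mm = 5,
                                    seed = 1L) {
  stopifnot_scalar_pos(diameter_mm, "diameter_mm")
  r <- diameter_mm / 2
  d <- dim(background_mask)
  annulus <- derive_annulus(lesion_mask, spacing_mm, annulus_thickness_mm)
  forbidden <- !background_mask | lesion_mask | annulus

  # feasible centres: >= r from every grid face and no forbidden voxel within r
  coords_ok <- lapply(1:3, function(ax) {
    w <- (seq_len(d[ax]) - 1) * spacing_mm[ax]
    w >= r & w <= (d[ax] - 1) * spacing_mm[ax] - r
  })
  margin <- outer(outer(coords_ok[[1]], coords_ok[[2]], "&"), coords_ok[[3]], "&")
  feasible <- margin & !dilate_mask(forbidden, spacing_mm, r)
  idx <- which(feasible)
  if (length(idx) == 0L) {
    stop("no feasible centre: background cannot host a ", diameter_mm,
         " mm patch disjoint from lesion and annulus", call. = FALSE)
  }
  centre_lin <- with_seed(seed, idx[sample.int(length(idx), 1L)])
  centre <- arrayInd(centre_lin, d)[1, ]
  metric_ball_mask(d, spacing_mm, centre, r)
}

# Ball of physical radius r_mm centred on voxel `centre` (1-based indices).
metric_ball_mask <- function(dims, spacing_mm, centre, r_mm) {
  dx2 <- ((seq_len(dims[1]) - centre[1]) * spacing_mm[1])^2
  dy2 <- ((seq_len(dims[2]) - centre[2]) * spacing_mm[2])^2
  dz2 <- ((seq_len(dims[3]) - centre[3]) * spacing_mm[3])^2
  array(outer(outer(dx2, dy2, "+"), dz2, "+") <= r_mm^2 + 1e-9, dims)
}
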