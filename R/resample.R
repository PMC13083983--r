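#' Resample a volume or mask to a target voxel spacing
#'
#' Interpolates the volume onto a uniform grid with the requested spacing
#' (the analysis default is 1 x 1 x 2 mm).  Images are interpolated
#' trilinearly; masks use nearest-neighbour interpolation so binarity is
#' preserved.  The physical extent of the volume is preserved to within one
#' voxel: the new grid has `round(n * spacing / target)` voxels per axis.
#'
#' @param volume An [image_volume()], or a logical 3D array when
#'   `is_mask = TRUE` (then `spacing_mm` must be supplied).
#' @param target_spacing_mm Numeric length-3 target spacing in mm.
#' @param is_mask Logical; nearest-neighbour resampling of a binary mask.
#' @param spacing_mm Spacing of `volume` when it is a bare mask array.
#' @return An `image_volume`, or a logical array when `is_mask = TRUE`.
#' @export
resample <- function(volume, target_spacing_mm, is_mask = FALSE,
                     spacing_mm = NULL) {
  target_spacing_mm <- as.numeric(target_spacing_mm)
  if (length(target_spacing_mm) == 1L) target_spacing_mm <- rep(target_spacing_mm, 3L)
  if (any(!is.finite(target_spacing_mm)) || any(target_spacing_mm <= 0)) {
    stop("target spacing must be strictly positive", call. = FALSE)
  }
  if (is_mask) {
    a <- array(as.numeric(volume), dim(volume))
    sp <- if (!is.null(spacing_mm)) as.numeric(spacing_mm) else attr(volume, "spacing_mm")
    if (is.null(sp)) stop("mask resampling needs `spacing_mm`", call. = FALSE)
  } else {
    a <- volume$intensities
    sp <- volume$spacing_mm
  }
  if (length(a) == 0L) stop("empty volume", call. = FALSE)
  d <- dim(a)
  nd <- pmax(1L, as.integer(round(d * sp / target_spacing_mm)))

  # continuous source index (0-based voxel centres) for each target centre
  src <- lapply(1:3, function(ax) {
    (seq_len(nd[ax]) - 1) * target_spacing_mm[ax] / sp[ax]
  })

  if (is_mask) {
    idx <- lapply(1:3, function(ax) pmin(pmax(round(src[[ax]]) + 1, 1), d[ax]))
    out <- a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    dim(out) <- nd
    out <- array(out > 0.5, nd)
    attr(out, "spacing_mm") <- target_spacing_mm
    return(out)
  }

  lo <- lapply(1:3, function(ax) pmin(pmax(floor(src[[ax]]), 0), d[ax] - 1))
  fr <- lapply(1:3, function(ax) pmin(pmax(src[[ax]] - lo[[ax]], 0), 1))
  hi <- lapply(1:3, function(ax) pmin(lo[[ax]] + 1, d[ax] - 1))

  gx <- list(lo[[1]] + 1, hi[[1]] + 1)
  gy <- list(lo[[2]] + 1, hi[[2]] + 1)
  gz <- list(lo[[3]] + 1, hi[[3]] + 1)
  wx <- list(1 - fr[[1]], fr[[1]])
  wy <- list(1 - fr[[2]], fr[[2]])
  wz <- list(1 - fr[[3]], fr[[3]])

  out <- array(0, nd)
  for (ix in 1:2) for (iy in 1:2) for (iz in 1:2) {
    w <- outer(outer(wx[[ix]], wy[[iy]]), wz[[iz]])
    if (all(w == 0)) next
    corner <- a[gx[[ix]], gy[[iy]], gz[[iz]], drop = FALSE]
    dim(corner) <- nd
    out <- out + w * corner
  }
  image_volume(out, target_spacing_mm, origin = volume$origin)
}
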