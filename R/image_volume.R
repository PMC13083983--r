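#' Construct a 3D image volume
#'
#' A minimal container for a 3D intensity array with anisotropic voxel
#' spacing.  Voxel indices are 0-based in world-coordinate computations:
#' the centre of voxel `(i, j, k)` sits at `origin + c(i, j, k) * spacing_mm`.
#'
#' @param intensities 3D numeric array of voxel intensities (finite).
#' @param spacing_mm Numeric length-3, voxel spacing in mm per axis
#'   (strictly positive).
#' @param origin Numeric length-3 world coordinate of voxel `(0, 0, 0)`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(intensities, spacing_mm, origin = c(0, 0, 0)) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L) {
    stop("`intensities` must be a 3D array", call. = FALSE)
  }
  if (length(intensities) == 0L) stop("empty volume", call. = FALSE)
  if (!all(is.finite(intensities))) stop("intensities must be finite", call. = FALSE)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0)) {
    stop("`spacing_mm` must be 3 strictly positive numbers", call. = FALSE)
  }
  structure(
    list(intensities = intensities, spacing_mm = spacing_mm,
         origin = as.numeric(origin)),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$intensities), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing_mm, 4), collapse = " x "), " mm\n",
      sep = "")
  invisible(x)
}

#' Construct a three-region ROI set
#'
#' Holds the three aligned binary analysis masks per case: the lesion, its
#' perilesional annulus, and a parenchymal reference patch.  The three masks
#' must live on the same voxel grid, be non-empty, and be pairwise disjoint.
#'
#' @param lesion,annulus,parenchyma Logical 3D arrays on a common grid.
#' @param spacing_mm Voxel spacing of the common grid (mm).
#' @return An object of class `roi_set` with elements `lesion`, `annulus`,
#'   `parenchyma` and `spacing_mm`.
#' @export
roi_set <- function(lesion, annulus, parenchyma, spacing_mm) {
  masks <- list(lesion = lesion, annulus = annulus, parenchyma = parenchyma)
  dims <- lapply(masks, dim)
  if (!all(vapply(masks, function(m) is.array(m) && length(dim(m)) == 3L, TRUE))) {
    stop("all masks must be 3D arrays", call. = FALSE)
  }
  if (!all(vapply(dims, identical, TRUE, dims[[1]]))) {
    stop("masks must share one voxel grid", call. = FALSE)
  }
  masks <- lapply(masks, function(m) array(as.logical(m), dim(m)))
  empty <- names(masks)[vapply(masks, function(m) !any(m), TRUE)]
  if (length(empty)) {
    stop("empty ROI mask(s): ", paste(empty, collapse = ", "), call. = FALSE)
  }
  if (any(masks$lesion & masks$annulus) ||
      any(masks$parenchyma & (masks$lesion | masks$annulus))) {
    stop("ROI masks must be pairwise disjoint", call. = FALSE)
  }
  structure(c(masks, list(spacing_mm = as.numeric(spacing_mm))), class = "roi_set")
}

#' Write / read a volume or mask as NIfTI
#'
#' Thin wrappers around \pkg{RNifti} preserving the voxel spacing.  Masks are
#' written as 0/1 integer volumes and read back with a 0.5 threshold.
#'
#' @param volume An `image_volume`, or a logical array for `write_mask_nifti`.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `read_volume_nifti` returns an `image_volume`; `read_mask_nifti`
#'   a logical array with a `spacing_mm` attribute.
#' @export
write_volume_nifti <- function(volume, path) {
  img <- RNifti::asNifti(volume$intensities)
  RNifti::pixdim(img) <- volume$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  image_volume(array(as.numeric(img), dim(img)[1:3]),
               spacing_mm = RNifti::pixdim(img)[1:3])
}

#' @rdname write_volume_nifti
#' @param mask Logical 3D array.
#' @param spacing_mm Voxel spacing in mm.
#' @export
write_mask_nifti <- function(mask, spacing_mm, path) {
  img <- RNifti::asNifti(array(as.integer(mask), dim(mask)))
  RNifti::pixdim(img) <- spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  m <- array(as.numeric(img) > 0.5, dim(img)[1:3])
  attr(m, "spacing_mm") <- RNifti::pixdim(img)[1:3]
  m
}
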