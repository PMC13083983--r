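#' Box-counting fractal dimension of a binary object
#'
#' Overlays grids of varying box edge `eps` (in voxels, anchored at the
#' object's bounding-box corner) on the object and counts the boxes
#' `N(eps)` containing at least one object voxel.  The fractal dimension is
#' the negative slope of the least-squares line of `log N(eps)` on
#' `log eps` (equivalently the positive slope against `log(1/eps)`), with
#' the fit's R-squared reported.
#'
#' @param mask Logical 3D array, the object (non-empty).
#' @param box_sizes Integer box edges in voxels; at least 3.  Default:
#'   powers of two from 1 to `floor(min bounding-box axis / 4)` (extended to
#'   `c(1, 2, 4)` for small objects).
#' @return An object of class `fractal_estimate`: list with `fd`,
#'   `box_sizes`, `counts`, `r_squared`.
#' @export
fractal_dimension <- function(mask, box_sizes = NULL) {
  if (!any(mask)) stop("empty object", call. = FALSE)
  pts <- which(mask, arr.ind = TRUE)
  bb_lo <- apply(pts, 2, min)
  side <- apply(pts, 2, max) - bb_lo + 1L
  if (is.null(box_sizes)) {
    top <- max(2L, floor(min(side) / 4))
    box_sizes <- 2^(0:floor(log2(top)))
    if (length(box_sizes) < 3L) box_sizes <- c(1L, 2L, 4L)
  }
  box_sizes <- sort(unique(as.integer(box_sizes)))
  if (length(box_sizes) < 3L) stop("need >= 3 box sizes", call. = FALSE)

  rel <- sweep(pts, 2, bb_lo, "-")  # 0-based within bounding box
  counts <- vapply(box_sizes, function(eps) {
    box <- rel %/% eps
    nrow(unique(box))
  }, 0L)

  lx <- log(box_sizes)
  ly <- log(counts)
  fit <- stats::lm.fit(cbind(1, lx), ly)
  slope <- fit$coefficients[2]
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else 1
  structure(list(fd = unname(-slope), box_sizes = box_sizes,
                 counts = counts, r_squared = r2),
            class = "fractal_estimate")
}

#' @export
print.fractal_estimate <- function(x, ...) {
  cat("<fractal_estimate> FD =", signif(x$fd, 4),
      " (R^2 =", signif(x$r_squared, 4), ")\n")
  invisible(x)
}

# The four per-ROI fractal features: FD of the mask itself, and FD of the
# supra-threshold voxel set at the 25/50/75% intensity quantiles within the
# ROI (degenerate thresholded sets fall back to the mask FD).
fractal_feature_set <- function(mask, intensities) {
  fd_of <- function(m) {
    if (sum(m) < 2) return(NA_real_)
    fractal_dimension(m)$fd
  }
  x <- intensities[mask]
  qs <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7)
  out <- c(fd_mask = fd_of(mask))
  for (i in seq_along(qs)) {
    m <- mask & (intensities >= qs[i])
    out[paste0("fd_intensity_q", c(25, 50, 75)[i])] <- fd_of(m)
  }
  out
}
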