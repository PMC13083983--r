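#' The per-ROI feature catalogue
#'
#' Enumerates the 666 features computed for every ROI: 18 image types (the
#' original image, 8 undecimated wavelet subbands, one Laplacian-of-Gaussian
#' response, and the 8 wavelet subbands of the LoG response) times 36
#' intensity features (18 first-order + 18 grey-level co-occurrence) = 648,
#' plus 14 mask-only shape features and 4 box-counting fractal-dimension
#' features (mask FD and intensity-threshold FD at three quantiles).  Three
#' ROIs per case give 1,998 features per scan.
#'
#' @param n_bins Discretisation bins for histogram/GLCM features.
#' @param log_sigma_mm LoG scale in mm.
#' @return An object of class `feature_catalogue`: list with `entries` (a
#'   data.frame with columns `feature`, `image_type`, `class`, `name`),
#'   `n_bins`, `log_sigma_mm`.
#' @export
feature_catalogue <- function(n_bins = 32L, log_sigma_mm = 2) {
  image_types <- c("original",
                   paste0("wavelet_", c("LLL", "LLH", "LHL", "LHH",
                                        "HLL", "HLH", "HHL", "HHH")),
                   "log",
                   paste0("wavelet_log_", c("LLL", "LLH", "LHL", "LHH",
                                            "HLL", "HLH", "HHL", "HHH")))
  rows <- list()
  for (it in image_types) {
    rows[[length(rows) + 1L]] <- data.frame(
      feature = first_order_names, image_type = it, class = "first-order",
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      feature = glcm_feature_names, image_type = it, class = "texture",
      stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    feature = shape_feature_names, image_type = "mask", class = "shape",
    stringsAsFactors = FALSE)
  rows[[length(rows) + 1L]] <- data.frame(
    feature = c("fd_mask", "fd_intensity_q25", "fd_intensity_q50",
                "fd_intensity_q75"),
    image_type = "original", class = "fractal", stringsAsFactors = FALSE)
  entries <- do.call(rbind, rows)
  entries$name <- ifelse(entries$class %in% c("shape", "fractal"),
                         paste(entries$class, entries$feature, sep = "_"),
                         paste(entries$image_type,
                               ifelse(entries$class == "first-order",
                                      "firstorder", "glcm"),
                               entries$feature, sep = "_"))
  stopifnot(nrow(entries) == 666L, !anyDuplicated(entries$name))
  structure(list(entries = entries, n_bins = as.integer(n_bins),
                 log_sigma_mm = log_sigma_mm),
            class = "feature_catalogue")
}

#' @export
print.feature_catalogue <- function(x, ...) {
  cat("<feature_catalogue>", nrow(x$entries), "features per ROI (",
      paste(names(table(x$entries$class)), table(x$entries$class),
            collapse = ", "), ")\n")
  invisible(x)
}

#' Extract the full feature vector of one case
#'
#' Runs the filter bank once, then computes every catalogue feature for each
#' of the three ROIs: 666 values per ROI, 1,998 per case, with provenance
#' (ROI, image type, feature class) carried per value.  Deterministic given
#' its inputs; an empty ROI raises an error naming the ROI.
#'
#' @param volume An [image_volume()] on the analysis grid.
#' @param rois An [roi_set()] on the same grid.
#' @param catalogue A [feature_catalogue()].
#' @return A data.frame (class `feature_vector`) with columns `roi`,
#'   `image_type`, `class`, `feature`, `name` (`roi_name`-prefixed, unique
#'   across the 1,998 rows) and `value`.
#' @export
extract_case <- function(volume, rois, catalogue = feature_catalogue()) {
  stopifnot(inherits(volume, "image_volume"), inherits(rois, "roi_set"))
  if (!identical(dim(volume$intensities), dim(rois$lesion))) {
    stop("volume and ROI grids differ", call. = FALSE)
  }
  bank <- filter_bank(volume, catalogue$log_sigma_mm)
  pair_index <- glcm_pair_index(dim(volume$intensities))
  roi_names <- c("lesion", "annulus", "parenchyma")
  ent <- catalogue$entries

  out <- vector("list", length(roi_names))
  for (ri in seq_along(roi_names)) {
    rn <- roi_names[ri]
    mask <- rois[[rn]]
    if (!any(mask)) stop("ROI empty: ", rn, call. = FALSE)
    roi_pairs <- roi_pair_index(mask, pair_index)
    lev <- array(0L, dim(mask))
    vals <- numeric(nrow(ent))
    for (it in unique(ent$image_type)) {
      if (it == "mask") next
      img <- bank[[it]]
      x <- img[mask]
      fo <- first_order_features(x, catalogue$n_bins)
      sel_fo <- ent$image_type == it & ent$class == "first-order"
      vals[sel_fo] <- fo[ent$feature[sel_fo]]
      disc <- discretise(x, catalogue$n_bins)
      lev[mask] <- disc$levels
      tx <- glcm_features_pairs(lev, roi_pairs, disc$n_levels)
      sel_tx <- ent$image_type == it & ent$class == "texture"
      vals[sel_tx] <- tx[ent$feature[sel_tx]]
      if (it == "original") {
        fr <- fractal_feature_set(mask, img)
        sel_fr <- ent$class == "fractal"
        vals[sel_fr] <- fr[ent$feature[sel_fr]]
      }
    }
    sh <- shape_features(mask, rois$spacing_mm)
    sel_sh <- ent$class == "shape"
    vals[sel_sh] <- sh[ent$feature[sel_sh]]
    out[[ri]] <- data.frame(roi = rn, image_type = ent$image_type,
                            class = ent$class, feature = ent$feature,
                            name = paste(rn, ent$name, sep = "_"),
                            value = vals, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("feature_vector", "data.frame")
  res
}

#' Extract a cohort feature table
#'
#' Applies [extract_case()] to each synthetic case and assembles the wide
#' cases-by-features matrix used by the modelling stages.
#'
#' @param cases List of `synthetic_case` objects (or of
#'   `list(volume, rois)` pairs).
#' @param catalogue A [feature_catalogue()].
#' @param scan `"test"` uses each case's primary volume, `"retest"` the
#'   retest acquisition.
#' @param rater `1` uses the reference segmentation; `2` rebuilds the ROI set
#'   from the second rater's lesion mask (annulus re-derived, patch clipped
#'   to stay disjoint).
#' @return Numeric matrix, cases x 1,998 named features.
#' @export
extract_cohort <- function(cases, catalogue = feature_catalogue(),
                           scan = c("test", "retest"), rater = 1L) {
  scan <- match.arg(scan)
  rows <- lapply(cases, function(cs) {
    vol <- if (scan == "retest") cs$retest_volume else cs$volume
    rois <- case_roi_set(cs, rater)
    fv <- extract_case(vol, rois, catalogue)
    stats::setNames(fv$value, fv$name)
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- names(cases)
  mat
}

#' ROI set of a case for a given rater
#'
#' Rater 2's set is rebuilt from the perturbed lesion mask: the annulus is
#' re-derived at 5 mm and the parenchymal patch clipped so the three masks
#' stay pairwise disjoint.
#'
#' @param case A `synthetic_case`.
#' @param rater 1 or 2.
#' @return An [roi_set()].
#' @export
case_roi_set <- function(case, rater = 1L) {
  if (rater == 1L) return(case$roi_set)
  sp <- case$volume$spacing_mm
  lesion <- case$rater2_lesion
  annulus <- derive_annulus(lesion, sp, 5)
  parenchyma <- case$roi_set$parenchyma & !lesion & !annulus
  roi_set(lesion, annulus, parenchyma, sp)
}

#' Write / read a cohort feature table as CSV
#'
#' The wide matrix round-trips through a plain CSV with a `case_id` column.
#'
#' @param mat Cases-by-features matrix from [extract_cohort()].
#' @param path CSV path.
#' @return For the reader, the matrix with case ids as rownames.
#' @export
write_feature_table <- function(mat, path) {
  df <- data.frame(case_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}
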