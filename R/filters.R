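# Coiflet-1 analysis filters (decomposition low/high pass), normalised so the
# low-pass sums to 1: an undecimated ("a trous") transform then maps constants
# to themselves in LLL and to zero in every detail subband.
coif1_lo <- c(-0.015655728135791993, -0.07273261951252645, 0.3848648468648578,
              0.8525720202116004, 0.3378976624574818, -0.07273261951252645) / sqrt(2)
coif1_hi <- c(0.07273261951252645, 0.3378976624574818, -0.8525720202116004,
              0.3848648468648578, 0.07273261951252645, -0.015655728135791993) / sqrt(2)

# Single-level undecimated separable 3D wavelet decomposition.  Returns the 8
# subbands named by the per-axis filter (L = low, H = high pass), e.g. "LLH"
# = low along x and y, high along z.  All subbands keep the input grid, so
# ROI masks remain valid on every subband.
wavelet_subbands <- function(a) {
  centre <- 4L  # filter origin (even-length filter, near-centred)
  lx <- axis_convolve(a, coif1_lo, 1L, centre)
  hx <- axis_convolve(a, coif1_hi, 1L, centre)
  step2 <- list(
    LL = axis_convolve(lx, coif1_lo, 2L, centre),
    LH = axis_convolve(lx, coif1_hi, 2L, centre),
    HL = axis_convolve(hx, coif1_lo, 2L, centre),
    HH = axis_convolve(hx, coif1_hi, 2L, centre)
  )
  out <- list()
  for (nm in names(step2)) {
    out[[paste0(nm, "L")]] <- axis_convolve(step2[[nm]], coif1_lo, 3L, centre)
    out[[paste0(nm, "H")]] <- axis_convolve(step2[[nm]], coif1_hi, 3L, centre)
  }
  # reorder to the conventional LLL..HHH listing
  out[c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")]
}

# Laplacian of Gaussian at physical scale sigma_mm: separable Gaussian
# smoothing followed by the spacing-aware 6-neighbour discrete Laplacian.
log_filter <- function(a, spacing_mm, sigma_mm = 2) {
  g <- gaussian_smooth(a, sigma_mm / spacing_mm)
  out <- array(0, dim(a))
  for (ax in 1:3) {
    n <- dim(a)[ax]
    lo <- index_axis(g, ax, pmin(pmax(seq_len(n) - 1L, 1L), n))
    hi <- index_axis(g, ax, pmin(pmax(seq_len(n) + 1L, 1L), n))
    dim(lo) <- dim(a); dim(hi) <- dim(a)
    out <- out + (lo - 2 * g + hi) / spacing_mm[ax]^2
  }
  out
}

#' Filter bank for radiomic image types
#'
#' Produces the 18 co-registered image types features are computed on: the
#' original volume, the 8 subbands of a single-level undecimated coiflet-1
#' wavelet decomposition, a Laplacian-of-Gaussian response at `sigma_mm`,
#' and the 8 wavelet subbands of that LoG response.  Every output shares the
#' input voxel grid, so the ROI masks apply unchanged.
#'
#' @param volume An [image_volume()] with at least 8 voxels per axis.
#' @param log_sigma_mm LoG scale in mm (default 2).
#' @return Named list of 18 3D arrays: `original`, `wavelet_LLL` ...
#'   `wavelet_HHH`, `log`, `wavelet_log_LLL` ... `wavelet_log_HHH`.
#' @export
filter_bank <- function(volume, log_sigma_mm = 2) {
  a <- volume$intensities
  if (any(dim(a) < 8L)) stop("volume needs >= 8 voxels per axis", call. = FALSE)
  wav <- wavelet_subbands(a)
  names(wav) <- paste0("wavelet_", names(wav))
  lg <- log_filter(a, volume$spacing_mm, log_sigma_mm)
  wav_log <- wavelet_subbands(lg)
  names(wav_log) <- paste0("wavelet_log_", names(wav_log))
  c(list(original = a), wav, list(log = lg), wav_log)
}
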