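#' Phantom specification
#'
#' Parameters of the synthetic chest-CT phantom used to emulate the study
#' conditions the pipeline assumes: a roughly spherical lesion embedded in
#' textured lung background, label-dependent intensity/texture modulation,
#' per-site (scanner) batch effects, a second rater's segmentation, and a
#' test-retest rescan.
#'
#' The lesion must fit inside the grid with at least a 7 mm margin (room for
#' the 5 mm perilesional annulus) even at the maximal +20% radius jitter.
#'
#' @param grid_shape Integer length-3, voxels per axis.
#' @param voxel_spacing_mm Voxel spacing in mm (default the 1 x 1 x 2 mm
#'   analysis grid, so generated cases need no further resampling).
#' @param lesion_radius_mm Nominal lesion radius (mm); per-case radii are
#'   jittered uniformly by up to +/-20%.
#' @param lesion_mean_hu,background_mean_hu Mean intensities (HU).
#' @param label_texture_effect Amplitude (HU) of the label-dependent
#'   modulation; it enters both as a mean shift of the lesion (half of it on
#'   the annulus) and as a label-dependent lengthening of the tissue-texture
#'   correlation length, so both first-order and co-occurrence features
#'   carry signal.  Zero makes the two classes exchangeable.
#' @param case_mean_sd_hu SD (HU) of the per-patient random lesion-intensity
#'   intercept, modelling inter-patient tissue heterogeneity.
#' @param noise_sd SD (HU) of the correlated acquisition noise; redrawn (and
#'   only it) for the retest scan.
#' @param texture_corr_mm Base correlation length (mm) of the noise field.
#' @param sinusoid_amp_hu Amplitude of the low-frequency background sinusoid
#'   that gives the lung parenchyma large-scale structure.
#' @param n_sites Number of acquisition sites.
#' @param site_shift,site_scale Per-site additive / multiplicative intensity
#'   batch effects (`v -> site_scale * v + site_shift`); recycled to
#'   `n_sites`.
#' @param seed Integer base seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(60L, 40L, 20L),
                         voxel_spacing_mm = c(1, 1, 2),
                         lesion_radius_mm = 6,
                         lesion_mean_hu = -20,
                         background_mean_hu = -700,
                         label_texture_effect = 10,
                         case_mean_sd_hu = 8,
                         noise_sd = 12,
                         texture_corr_mm = 1.5,
                         sinusoid_amp_hu = 20,
                         n_sites = 2L,
                         site_shift = c(0, 25),
                         site_scale = c(1, 1.1),
                         seed = 1L) {
  spec <- list(
    grid_shape = as.integer(grid_shape),
    voxel_spacing_mm = as.numeric(voxel_spacing_mm),
    lesion_radius_mm = lesion_radius_mm,
    lesion_mean_hu = lesion_mean_hu,
    background_mean_hu = background_mean_hu,
    label_texture_effect = label_texture_effect,
    case_mean_sd_hu = case_mean_sd_hu,
    noise_sd = noise_sd,
    texture_corr_mm = texture_corr_mm,
    sinusoid_amp_hu = sinusoid_amp_hu,
    n_sites = as.integer(n_sites),
    site_shift = rep_len(as.numeric(site_shift), n_sites),
    site_scale = rep_len(as.numeric(site_scale), n_sites),
    seed = as.integer(seed)
  )
  if (any(spec$voxel_spacing_mm <= 0)) stop("voxel spacing must be positive", call. = FALSE)
  if (any(spec$site_scale <= 0)) stop("site_scale must be positive", call. = FALSE)
  if (spec$noise_sd < 0 || spec$lesion_radius_mm <= 0 || spec$n_sites < 1L) {
    stop("invalid phantom parameters", call. = FALSE)
  }
  centre <- lesion_centre_voxel(spec)
  extent <- (spec$grid_shape - 1) * spec$voxel_spacing_mm
  cw <- (centre - 1) * spec$voxel_spacing_mm
  rmax <- 1.2 * spec$lesion_radius_mm + max(spec$voxel_spacing_mm)  # + centre jitter
  margin <- min(cw - rmax, extent - cw - rmax)
  if (margin < 7) {
    stop("lesion does not fit: margin ", round(margin, 1),
         " mm < 7 mm needed for the annulus", call. = FALSE)
  }
  structure(spec, class = "phantom_spec")
}

# Nominal lesion centre: off-centre along x so a parenchymal patch fits.
lesion_centre_voxel <- function(spec) {
  c(round(0.30 * (spec$grid_shape[1] - 1)) + 1,
    round(0.50 * (spec$grid_shape[2] - 1)) + 1,
    round(0.50 * (spec$grid_shape[3] - 1)) + 1)
}

# Unit-variance smooth Gaussian random field (empirically standardised).
smooth_noise_field <- function(dims, spacing_mm, corr_mm) {
  f <- array(stats::rnorm(prod(dims)), dims)
  f <- gaussian_smooth(f, corr_mm / spacing_mm)
  (f - mean(f)) / stats::sd(f)
}

#' Generate one synthetic case
#'
#' Builds the volume, the three analysis ROIs, a second rater's lesion mask
#' (a one-voxel morphological perturbation of the first), and a retest
#' volume in which only the acquisition noise is redrawn.  Fully
#' deterministic given `seed`.
#'
#' @param spec A [phantom_spec()].
#' @param label 0/1 class label (e.g. driver-mutation positivity).
#' @param site_id Site index in `1:n_sites`.
#' @param seed Integer seed for this case.
#' @return An object of class `synthetic_case` with elements `volume`,
#'   `roi_set`, `rater2_lesion`, `retest_volume`, `site_id`, `label`.
#' @export
generate_case <- function(spec, label, site_id = 1L, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"), site_id >= 1L, site_id <= spec$n_sites)
  label <- as.integer(label)
  d <- spec$grid_shape
  sp <- spec$voxel_spacing_mm

  anatomy <- with_seed(derive_seed(seed, 1L), {
    radius <- spec$lesion_radius_mm * stats::runif(1, 0.8, 1.2)
    centre <- lesion_centre_voxel(spec) + sample(-1:1, 3, replace = TRUE)
    phases <- stats::runif(3, 0, 2 * pi)
    case_int <- stats::rnorm(1, 0, spec$case_mean_sd_hu)
    sigma_t <- spec$texture_corr_mm * (2 + label * spec$label_texture_effect / 15)
    texture <- 8 * smooth_noise_field(d, sp, sigma_t)
    list(radius = radius, centre = centre, phases = phases,
         case_int = case_int, texture = texture)
  })

  lesion <- metric_ball_mask(d, sp, anatomy$centre, anatomy$radius)
  extent <- (d - 1) * sp
  cw <- (anatomy$centre - 1) * sp
  if (min(cw - anatomy$radius, extent - cw - anatomy$radius) < 7) {
    stop("lesion does not fit inside the grid with a 7 mm margin", call. = FALSE)
  }
  annulus <- derive_annulus(lesion, sp, 5)
  patch <- place_parenchymal_patch(!lesion, lesion, sp, diameter_mm = 20,
                                   seed = derive_seed(seed, 2L))
  rois <- roi_set(lesion, annulus, patch, sp)

  # structural mean field: lung background sinusoid + lesion/annulus plateaus
  wx <- (seq_len(d[1]) - 1) * sp[1]
  wy <- (seq_len(d[2]) - 1) * sp[2]
  wz <- (seq_len(d[3]) - 1) * sp[3]
  lam <- 25
  sinus <- spec$sinusoid_amp_hu *
    outer(outer(sin(2 * pi * wx / lam + anatomy$phases[1]),
                sin(2 * pi * wy / lam + anatomy$phases[2])),
          sin(2 * pi * wz / lam + anatomy$phases[3]))
  mu <- spec$background_mean_hu + sinus
  shift <- anatomy$case_int + label * spec$label_texture_effect
  mu[lesion] <- spec$lesion_mean_hu + shift
  mu[annulus] <- mu[annulus] + 0.5 * shift
  peri <- lesion | annulus
  mu[peri] <- mu[peri] + anatomy$texture[peri]

  render <- function(noise_seed) {
    noise <- if (spec$noise_sd > 0) {
      spec$noise_sd * with_seed(noise_seed,
        smooth_noise_field(d, sp, spec$texture_corr_mm))
    } else 0
    v <- spec$site_scale[site_id] * (mu + noise) + spec$site_shift[site_id]
    image_volume(v, sp)
  }
  volume <- render(derive_seed(seed, 3L))
  retest <- render(derive_seed(seed, 4L))

  rater2 <- with_seed(derive_seed(seed, 5L), perturb_mask(lesion))

  structure(
    list(volume = volume, roi_set = rois, rater2_lesion = rater2,
         retest_volume = retest, site_id = as.integer(site_id), label = label,
         lesion_radius_mm = anatomy$radius),
    class = "synthetic_case"
  )
}

# One-voxel morphological perturbation emulating a second observer: shift the
# mask one voxel along a random axis, then randomly drop boundary voxels.
perturb_mask <- function(mask) {
  d <- dim(mask)
  ax <- sample(1:3, 1)
  dir <- sample(c(-1L, 1L), 1)
  idx <- pmin(pmax(seq_len(d[ax]) - dir, 1L), d[ax])
  out <- index_axis(mask, ax, idx)
  dim(out) <- d
  inner <- out
  for (a in 1:3) {
    n <- d[a]
    lo <- index_axis(out, a, pmin(pmax(seq_len(n) - 1L, 1L), n))
    hi <- index_axis(out, a, pmin(pmax(seq_len(n) + 1L, 1L), n))
    dim(lo) <- d; dim(hi) <- d
    inner <- inner & lo & hi
  }
  boundary <- which(out & !inner)
  drop <- boundary[stats::runif(length(boundary)) < 0.2]
  out[drop] <- FALSE
  if (!any(out)) out <- mask  # degenerate tiny lesion: keep original
  out
}

#' Cohort specification
#'
#' @param n_cases Number of cases (>= 10).
#' @param prevalence Fraction of label-positive cases in (0, 1); the
#'   positive count is exact: `round(n_cases * prevalence)`.
#' @param sex_female_prob Probability of female sex.
#' @param age_mean,age_sd Age distribution (years).
#' @param survival_hr True hazard ratio of label-positive vs negative cases.
#' @param censor_rate Target fraction of randomly censored cases.
#' @param admin_censor_months Administrative censoring horizon (months);
#'   default 36 (a three-year follow-up clock); `Inf` disables it.
#' @param median_survival_months Baseline (label-negative) median survival.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 100L, prevalence = 0.4,
                        sex_female_prob = 0.43, age_mean = 68, age_sd = 10,
                        survival_hr = 2, censor_rate = 0.2,
                        admin_censor_months = 36,
                        median_survival_months = 30, seed = 1L) {
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0,1)", call. = FALSE)
  if (n_cases < 10L) stop("n_cases must be >= 10", call. = FALSE)
  if (survival_hr <= 0) stop("survival_hr must be positive", call. = FALSE)
  structure(list(n_cases = as.integer(n_cases), prevalence = prevalence,
                 sex_female_prob = sex_female_prob, age_mean = age_mean,
                 age_sd = age_sd, survival_hr = survival_hr,
                 censor_rate = censor_rate,
                 admin_censor_months = admin_censor_months,
                 median_survival_months = median_survival_months,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Draws labels (exact positive count), sites, clinical covariates and
#' survival for `n_cases`, then renders one [generate_case()] per row.
#' Survival times are exponential with the true hazard ratio applied to the
#' latent label; random censoring is calibrated to `censor_rate` and an
#' administrative cap applied at `admin_censor_months`.
#'
#' @param spec A [phantom_spec()].
#' @param cohort A [cohort_spec()].
#' @param render Logical; `FALSE` returns the cohort table only (no images).
#' @return A list with `cases` (list of `synthetic_case`) and `cohort`
#'   (data.frame: case_id, site_id, age, sex, histology, label,
#'   survival_months, event).
#' @export
generate_cohort <- function(spec, cohort, render = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(cohort, "cohort_spec"))
  n <- cohort$n_cases
  n_pos <- round(n * cohort$prevalence)
  if (n_pos < 2 || n - n_pos < 2) {
    stop("cohort needs >= 2 cases per class", call. = FALSE)
  }
  tab <- with_seed(derive_seed(cohort$seed, 101L), {
    label <- sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
    site <- sample.int(spec$n_sites, n, replace = TRUE)
    age <- round(stats::rnorm(n, cohort$age_mean, cohort$age_sd), 1)
    sex <- ifelse(stats::runif(n) < cohort$sex_female_prob, "F", "M")
    histology <- sample(c("adenocarcinoma", "squamous", "other"), n,
                        replace = TRUE, prob = c(0.55, 0.30, 0.15))
    h0 <- log(2) / cohort$median_survival_months
    h <- h0 * cohort$survival_hr^label
    t_event <- stats::rexp(n, h)
    if (cohort$censor_rate > 0) {
      hbar <- mean(h)
      hc <- hbar * cohort$censor_rate / (1 - cohort$censor_rate)
      t_cens <- stats::rexp(n, hc)
    } else {
      t_cens <- rep(Inf, n)
    }
    horizon <- pmin(t_cens, cohort$admin_censor_months)
    data.frame(
      case_id = sprintf("case_%03d", seq_len(n)),
      site_id = site, age = age, sex = sex, histology = histology,
      label = label,
      survival_months = pmin(t_event, horizon),
      event = as.integer(t_event <= horizon),
      stringsAsFactors = FALSE
    )
  })
  cases <- NULL
  if (render) {
    cases <- lapply(seq_len(n), function(i) {
      generate_case(spec, tab$label[i], tab$site_id[i],
                    seed = derive_seed(cohort$seed, 1000L + i))
    })
    names(cases) <- tab$case_id
  }
  list(cases = cases, cohort = tab)
}

#' Write a synthetic cohort to disk
#'
#' Writes per-case NIfTI volumes and masks plus one cohort-level CSV.
#'
#' @param cohort_data Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort_data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort_data$cases)) {
    cs <- cohort_data$cases[[id]]
    sp <- cs$volume$spacing_mm
    write_volume_nifti(cs$volume, file.path(dir, paste0(id, "_image.nii.gz")))
    write_volume_nifti(cs$retest_volume, file.path(dir, paste0(id, "_retest.nii.gz")))
    write_mask_nifti(cs$roi_set$lesion, sp, file.path(dir, paste0(id, "_lesion.nii.gz")))
    write_mask_nifti(cs$roi_set$annulus, sp, file.path(dir, paste0(id, "_annulus.nii.gz")))
    write_mask_nifti(cs$roi_set$parenchyma, sp, file.path(dir, paste0(id, "_parenchyma.nii.gz")))
    write_mask_nifti(cs$rater2_lesion, sp, file.path(dir, paste0(id, "_lesion_rater2.nii.gz")))
  }
  utils::write.csv(cohort_data$cohort, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  invisible(dir)
}
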