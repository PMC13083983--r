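test_that("case generation is deterministic and label-null at zero effect", {
  ps <- phantom_spec()
  a <- generate_case(ps, 1, 1, seed = 11)
  b <- generate_case(ps, 1, 1, seed = 11)
  expect_identical(a$volume$intensities, b$volume$intensities)
  expect_identical(a$roi_set$lesion, b$roi_set$lesion)
  expect_identical(a$rater2_lesion, b$rater2_lesion)

  # zero label effect + identity site: flipping the label changes nothing
  ps0 <- phantom_spec(label_texture_effect = 0, site_shift = 0, site_scale = 1)
  pos <- generate_case(ps0, 1, 1, seed = 5)
  neg <- generate_case(ps0, 0, 1, seed = 5)
  expect_identical(pos$volume$intensities, neg$volume$intensities)
  expect_identical(pos$roi_set$lesion, neg$roi_set$lesion)

  # zero noise: retest is the same acquisition
  c0 <- generate_case(phantom_spec(noise_sd = 0), 1, 1, seed = 7)
  expect_identical(c0$volume$intensities, c0$retest_volume$intensities)
})

test_that("generated masks are valid and the second rater overlaps", {
  for (seed in c(3, 14, 15)) {
    cs <- generate_case(phantom_spec(), label = seed %% 2, site_id = 1,
                        seed = seed)
    r <- cs$roi_set
    expect_true(all(vapply(list(r$lesion, r$annulus, r$parenchyma), any, TRUE)))
    expect_false(any(r$lesion & r$annulus))
    expect_false(any(r$parenchyma & (r$lesion | r$annulus)))
    expect_gt(dice(r$lesion, cs$rater2_lesion), 0.5)
  }
})

test_that("a lesion too large for the grid is rejected", {
  expect_error(phantom_spec(lesion_radius_mm = 14), "does not fit")
})

test_that("cohort labels hit the exact count and tiny classes error", {
  g <- generate_cohort(phantom_spec(), cohort_spec(n_cases = 100,
                                                   prevalence = 0.2),
                       render = FALSE)
  expect_equal(sum(g$cohort$label), 20)
  expect_equal(nrow(g$cohort), 100)
  expect_error(
    generate_cohort(phantom_spec(), cohort_spec(n_cases = 10, prevalence = 0.05),
                    render = FALSE),
    "2 cases per class")
})

test_that("null survival generator is calibrated (log-rank type-I error)", {
  rejections <- vapply(1:500, function(s) {
    g <- generate_cohort(
      phantom_spec(),
      cohort_spec(n_cases = 80, prevalence = 0.5, survival_hr = 1,
                  censor_rate = 0, admin_censor_months = Inf, seed = s),
      render = FALSE)$cohort
    sd <- survival::survdiff(
      survival::Surv(g$survival_months, g$event) ~ g$label)
    stats::pchisq(sd$chisq, 1, lower.tail = FALSE) < 0.05
  }, TRUE)
  expect_gt(mean(rejections), 0.02)
  expect_lt(mean(rejections), 0.08)
})

test_that("cohorts round-trip through NIfTI and CSV", {
  dir <- withr::local_tempdir()
  g <- generate_cohort(phantom_spec(), cohort_spec(n_cases = 10, seed = 2))
  # keep IO light: write the first two cases only
  g$cases <- g$cases[1:2]
  write_cohort(g, dir)
  tab <- utils::read.csv(file.path(dir, "cohort.csv"))
  expect_equal(nrow(tab), 10)
  v <- read_volume_nifti(file.path(dir, "case_001_image.nii.gz"))
  expect_equal(v$intensities, g$cases[[1]]$volume$intensities,
               tolerance = 1e-6)
  expect_equal(v$spacing_mm, g$cases[[1]]$volume$spacing_mm)
  m <- read_mask_nifti(file.path(dir, "case_001_lesion.nii.gz"))
  expect_identical(array(m, dim(m)), g$cases[[1]]$roi_set$lesion)
})
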