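test_that("discretisation follows min-anchored fixed-width binning", {
  expect_equal(discretise(rep(4.2, 10))$n_levels, 1L)
  # values 0..255 with width 25: ceiling arithmetic gives 11 levels
  d <- discretise(0:255, bin_width = 25)
  expect_equal(d$n_levels, 11L)
  # shift invariance of min-anchored binning
  x <- c(0.3, 1.7, 5.2, 9.9, 2.2)
  expect_identical(discretise(x, 8)$levels, discretise(x + 137.5, 8)$levels)
  expect_error(discretise(1:5, bin_width = 0), "positive")
})

test_that("first-order features match hand computations", {
  f <- first_order_features(rep(3.5, 20))
  expect_equal(unname(f["mean"]), 3.5)
  expect_equal(unname(f["median"]), 3.5)
  expect_equal(unname(f["sd"]), 0)

  f2 <- first_order_features(c(1, 2, 3, 4))
  expect_equal(unname(f2["median"]), 2.5)
  expect_equal(unname(f2["variance"]), 1.25)  # population
  expect_equal(unname(f2["energy"]), 30)

  # permutation invariance
  set.seed(1); x <- rnorm(50)
  expect_equal(first_order_features(x), first_order_features(sample(x)))

  # single voxel: higher moments are explicit missing, not NaN garbage
  f1 <- first_order_features(2)
  expect_true(is.na(f1["skewness"]) && is.na(f1["kurtosis"]))
  expect_equal(unname(f1["sd"]), 0)
  expect_error(first_order_features(numeric(0)), "empty")
})

test_that("GLCM features agree with enumerated small cases", {
  # alternating 1D strip: only (1,2)/(2,1) co-occurrences, contrast 1
  strip <- array(rep(c(1L, 2L), 8), c(16, 1, 1))
  sm <- array(TRUE, dim(strip))
  g <- glcm_features(strip, sm, 2L, directions = rbind(c(1, 0, 0)))
  expect_equal(unname(g["contrast"]), 1)
  expect_equal(unname(g["max_probability"]), 0.5)
  expect_equal(unname(g["correlation"]), -1)

  # constant image: zero contrast; correlation defined as 1
  const <- array(1L, c(4, 4, 2))
  gc <- glcm_features(const, array(TRUE, c(4, 4, 2)), 1L)
  expect_equal(unname(gc["contrast"]), 0)
  expect_equal(unname(gc["correlation"]), 1)

  # checkerboard, axis-aligned in-plane offsets: perfectly anti-correlated
  cb <- array(0L, c(4, 4, 1))
  for (i in 1:4) for (j in 1:4) cb[i, j, 1] <- ((i + j) %% 2L) + 1L
  gcb <- glcm_features(cb, array(TRUE, c(4, 4, 1)), 2L,
                       directions = rbind(c(1, 0, 0), c(0, 1, 0)))
  expect_equal(unname(gcb["correlation"]), -1)
})

test_that("direction-averaged GLCM features are rotation invariant", {
  cs <- tiny_case()
  vol <- cs$volume$intensities
  mask <- cs$roi_set$lesion
  rot <- function(a) aperm(a, c(2, 1, 3))[, dim(a)[1]:1, , drop = FALSE]
  x <- vol[mask]
  d <- discretise(x)
  lev <- array(0L, dim(vol)); lev[mask] <- d$levels
  lev_r <- rot(lev); mask_r <- rot(mask)
  dim(lev_r) <- dim(lev)[c(2, 1, 3)]; dim(mask_r) <- dim(mask)[c(2, 1, 3)]
  g1 <- glcm_features(lev, mask, d$n_levels)
  g2 <- glcm_features(lev_r, mask_r, d$n_levels)
  expect_equal(g1, g2, tolerance = 1e-6)
})

test_that("filter bank has vanishing-moment and band-pass behaviour", {
  const <- image_volume(array(5, c(12, 12, 12)), c(1, 1, 1))
  fb <- filter_bank(const)
  expect_equal(length(fb), 18L)
  expect_true(all(abs(fb$wavelet_LLL - 5) < 1e-10))
  for (nm in c("wavelet_LLH", "wavelet_HLL", "wavelet_HHH")) {
    expect_lt(max(abs(fb[[nm]])), 1e-10)
  }
  expect_lt(max(abs(fb$log)), 1e-10)

  # low-frequency sinusoid concentrates in LLL
  d <- c(24, 24, 24)
  w <- outer(outer(sin(2 * pi * (1:24) / 24), sin(2 * pi * (1:24) / 24)),
             sin(2 * pi * (1:24) / 24))
  fs <- filter_bank(image_volume(array(w, d), c(1, 1, 1)))
  e_lll <- sum(fs$wavelet_LLL^2)
  e_detail <- sum(vapply(c("wavelet_LLH", "wavelet_LHL", "wavelet_LHH",
                           "wavelet_HLL", "wavelet_HLH", "wavelet_HHL",
                           "wavelet_HHH"),
                         function(nm) sum(fs[[nm]]^2), 0))
  expect_gt(e_lll / e_detail, 10)
  expect_error(filter_bank(image_volume(array(1, c(4, 12, 12)), c(1, 1, 1))),
               "8 voxels")
})

test_that("the catalogue emits 666 features per ROI with stable provenance", {
  cs <- tiny_case()
  fv <- extract_case(cs$volume, cs$roi_set)
  expect_equal(nrow(fv), 1998L)
  expect_equal(as.integer(table(fv$roi)), rep(666L, 3))
  expect_equal(sum(fv$class == "shape" & fv$roi == "lesion"), 14L)
  expect_equal(sum(fv$class == "fractal" & fv$roi == "lesion"), 4L)
  expect_false(anyDuplicated(fv$name) > 0)
  # determinism
  fv2 <- extract_case(cs$volume, cs$roi_set)
  expect_identical(fv, fv2)
})

test_that("intensity shift moves the mean but not min-anchored texture or shape", {
  cs <- tiny_case()
  shifted <- image_volume(cs$volume$intensities + 150, cs$volume$spacing_mm)
  a <- extract_case(cs$volume, cs$roi_set)
  b <- extract_case(shifted, cs$roi_set)
  sel_mean <- a$roi == "lesion" & a$name == "lesion_original_firstorder_mean"
  expect_equal(b$value[sel_mean] - a$value[sel_mean], 150)
  sel_tx <- a$roi == "lesion" & a$image_type == "original" & a$class == "texture"
  expect_equal(a$value[sel_tx], b$value[sel_tx], tolerance = 1e-12)
  sel_sh <- a$class == "shape"
  expect_equal(a$value[sel_sh], b$value[sel_sh])
})

test_that("feature tables round-trip through CSV", {
  cs <- tiny_case()
  m <- extract_cohort(list(case_a = cs), feature_catalogue())
  expect_equal(dim(m), c(1L, 1998L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(m, path)
  m2 <- read_feature_table(path)
  expect_equal(m, m2, tolerance = 1e-12)
})
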