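test_that("registry is large enough, unique, and covers the published feature names", {
  reg <- feature_registry()
  expect_gte(nrow(reg), 170)                         # >= 510 over three regions
  expect_false(anyDuplicated(reg$name) > 0)
  published <- c("OD-CentroidDifference", "RadCentre", "MeanRadius",
                 "ODEccentricity", "RadVarianceAngle", "RadVarAngle",
                 "RadSD-Angle", "RadKurtosis-Angle", "TotalVariance",
                 "V-Correlation", "GrayLevel6", "FFT2", "MinAxis")
  expect_true(all(published %in% reg$name))
  expect_true(all(nchar(reg$formula_doc) > 0))
})

test_that("extraction emits one finite value per registered feature, deterministically", {
  set.seed(3)
  img <- matrix(runif(64 * 64, 0.2, 0.8), 64, 64)
  msk <- disk_mask(64, 9)
  fv <- extract_features(img, msk)
  expect_setequal(names(fv), feature_registry()$name)
  expect_true(all(is.finite(fv)))
  expect_identical(fv, extract_features(img, msk))
  expect_error(extract_features(img, disk_mask(64, 1)),
               class = "perirad_mask_too_small")
})

test_that("a uniform-intensity disk has no intensity asymmetry", {
  img <- matrix(0.6, 64, 64)
  fv <- extract_features(img, disk_mask(64, 10))
  expect_lt(fv[["OD-CentroidDifference"]], 1e-9)
  # rasterized boundary keeps r(theta) constant to sub-pixel level
  expect_lt(fv[["RadSD-Angle"]], 0.5)
  expect_lt(fv[["RadVarianceAngle"]] / fv[["MeanRadius"]]^2, 2e-3)
  expect_equal(fv[["SD"]], 0)
})

test_that("centroid offset under a linear gradient matches the double-loop oracle", {
  n <- 64
  img <- matrix(rep(seq(0.2, 0.8, length.out = n), each = n), n, n)  # +x gradient
  msk <- disk_mask(n, 10)
  fv <- extract_features(img, msk)
  expect_gt(fv[["OD-CentroidDifference"]], 0)
  expect_equal(fv[["OD-CentroidDifference"]], oracle_centroid_offset(img, msk),
               tolerance = 1e-12)
})

test_that("mean boundary radius matches a fine angular-sampling oracle within 2%", {
  msk <- square_mask(64, 10)
  fv <- extract_features(matrix(0.5, 64, 64), msk)
  expect_equal(fv[["MeanRadius"]], oracle_mean_radius(msk), tolerance = 0.02)
  mskd <- disk_mask(64, 11)
  fvd <- extract_features(matrix(0.5, 64, 64), mskd)
  expect_equal(fvd[["MeanRadius"]], oracle_mean_radius(mskd), tolerance = 0.02)
})

test_that("every feature is exactly invariant to integer translation", {
  set.seed(7)
  img <- matrix(runif(96 * 96, 0.2, 0.4), 96, 96)
  msk <- disk_mask(96, 10, cy = 40, cx = 40)
  img[msk] <- img[msk] + 0.4
  img2 <- matrix(0.3, 96, 96); msk2 <- matrix(FALSE, 96, 96)
  img2[6:96, 8:96] <- img[1:91, 1:89]
  msk2[6:96, 8:96] <- msk[1:91, 1:89]
  expect_lt(max(abs(extract_features(img, msk) - extract_features(img2, msk2))),
            1e-9)
})

test_that("shape and radial families ignore a constant intensity shift; intensity families follow it", {
  set.seed(11)
  img <- matrix(runif(64 * 64, 0.1, 0.5), 64, 64)
  msk <- disk_mask(64, 9)
  f0 <- extract_features(img, msk)
  f1 <- extract_features(img + 0.2, msk)
  shape_rad <- c("Area", "Perimeter", "MinAxis", "MajorAxis", "Eccentricity",
                 "MeanRadius", "RadVarianceAngle", "RadSD-Angle",
                 "RadKurtosis-Angle", paste0("Hu", 1:7))
  expect_lt(max(abs(f0[shape_rad] - f1[shape_rad])), 1e-9)
  expect_equal(unname(f1[["Mean"]] - f0[["Mean"]]), 0.2, tolerance = 1e-12)
  expect_equal(f0[["TotalVariance"]], f1[["TotalVariance"]], tolerance = 1e-12)
})

test_that("lesion stacks yield slices x regions x features rows and skip missing masks", {
  coh <- generate_cohort(cohort_spec(n_patients = 2, seed = 21))
  ann <- coh$annotations[1, ]
  vol <- coh$volumes[[ann$patient_id]]
  seg <- segment_cohort(coh$volumes[ann$patient_id], ann)
  trips <- stats::setNames(seg$masks, seg$slice_index)
  long <- extract_lesion_stack(vol, trips)
  n_feat <- nrow(feature_registry())
  expect_equal(nrow(long), 5 * 3 * n_feat)
  wide <- features_wide(dplyr::mutate(long, lesion_id = ann$lesion_id))
  expect_equal(nrow(wide), 5)
  expect_true(all(c("OD-CentroidDifference_RING", "RadCentre_RING",
                    "TotalVariance_CORE") %in% names(wide)))
  # 2-slice lesion -> 6F values; missing slice warns, not drops silently
  keep <- as.integer(names(trips)[1:2])
  expect_warning(short <- extract_lesion_stack(vol, trips[1:2], slices = c(keep, 99L)),
                 "skipped")
  expect_equal(nrow(short), 2 * 3 * n_feat)
})
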