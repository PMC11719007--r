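test_that("cohort generation is byte-identical for a fixed seed", {
  a <- generate_cohort(cohort_spec(n_patients = 6, seed = 7))
  b <- generate_cohort(cohort_spec(n_patients = 6, seed = 7))
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$volumes[[1]]$voxels, b$volumes[[1]]$voxels)
  expect_identical(a$ground_truth$masks, b$ground_truth$masks)
  c_ <- generate_cohort(cohort_spec(n_patients = 6, seed = 8))
  expect_false(identical(a$clinical$pack_years, c_$clinical$pack_years))
})

test_that("prevalence and cohort shape follow the specification", {
  coh <- generate_cohort(cohort_spec(n_patients = 97, pd_prevalence = 0.28, seed = 7))
  n_pd <- sum(coh$clinical$response == "PD")
  expect_gt(n_pd, 16)                     # ~27 expected, binomial spread
  expect_lt(n_pd, 39)
  expect_equal(nrow(coh$clinical), 97)
  # every lesion has a reference mask per rendered slice
  for (k in seq_len(nrow(coh$annotations))) {
    ann <- coh$annotations[k, ]
    stack <- coh$ground_truth$masks[[ann$patient_id]][[ann$lesion_id]]
    expect_length(stack, ann$extent_hi - ann$extent_lo + 1)
  }
  expect_true(all(coh$annotations$extent_hi - coh$annotations$extent_lo + 1 == 5))
})

test_that("invalid cohort specifications are rejected with the field named", {
  expect_error(cohort_spec(pd_prevalence = 1.2), "pd_prevalence")
  expect_error(cohort_spec(censor_rate = -0.1), "censor_rate")
  expect_error(cohort_spec(survival_hazard_ratio = 0), "survival_hazard_ratio")
  expect_error(cohort_spec(image_shape = c(32, 32)), "image_shape")
  expect_error(cohort_spec(clinical_effects = list(pack_years = c(1, 2, -1))),
               "clinical_effects")
  expect_error(generate_feature_table(0, 5), "n_per_class")
  expect_error(generate_feature_table(10, 5, informative = 9), "informative")
})

test_that("clinical covariates shift in the planted class-conditional directions", {
  coh <- generate_cohort(cohort_spec(n_patients = 400, seed = 13))
  cl <- coh$clinical
  expect_lt(mean(cl$pack_years[cl$response == "PD"]),
            mean(cl$pack_years[cl$response == "DC"]))
  expect_gt(mean(cl$n_met_sites[cl$response == "PD"]),
            mean(cl$n_met_sites[cl$response == "DC"]))
})

test_that("feature tables match their closed-form Gaussian ROC", {
  # delta = 0: univariate AUCs hover at chance
  null_tab <- generate_feature_table(500, 6, informative = 6, delta = 0, seed = 2)
  y <- as.integer(null_tab$class == "PD")
  aucs <- vapply(paste0("f00", 1:6),
                 function(f) roc_auc(null_tab[[f]], y)$auc, numeric(1))
  expect_true(all(aucs > 0.45 & aucs < 0.55))
  # delta = 2: empirical AUC ~ pnorm(sqrt(2)) = 0.921
  tab <- generate_feature_table(1000, 3, informative = 1, delta = 2, seed = 3)
  auc <- roc_auc(tab$f001, as.integer(tab$class == "PD"))$auc
  expect_equal(auc, pnorm(sqrt(2)), tolerance = 0.02)
  # uninformative features stay at chance
  expect_lt(abs(roc_auc(tab$f002, as.integer(tab$class == "PD"))$auc - 0.5), 0.05)
})

test_that("zero ring effect removes the peritumoral class signal", {
  coh <- generate_cohort(cohort_spec(n_patients = 40, ring_contrast_effect = 0,
                                     seed = 17))
  seg <- segment_cohort(coh$volumes, coh$annotations)
  vals <- purrr::pmap_dbl(seg[c("patient_id", "slice_index", "masks")],
    function(patient_id, slice_index, masks) {
      img <- coh$volumes[[patient_id]]$voxels[slice_index + 1, , ]
      extract_features(img, masks$ring)[["OD-CentroidDifference"]]
    })
  lab <- coh$clinical$response[match(seg$patient_id, coh$clinical$patient_id)]
  expect_lt(abs(roc_auc(vals, lab)$auc - 0.5), 0.12)
})

test_that("cohorts round-trip through the disk format", {
  coh <- generate_cohort(cohort_spec(n_patients = 3, seed = 31))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$clinical$pack_years, coh$clinical$pack_years)
  expect_equal(back$annotations$seed_row, coh$annotations$seed_row)
  expect_equal(back$volumes[["P001"]]$voxels, coh$volumes[["P001"]]$voxels,
               tolerance = 1e-6)
  m0 <- coh$ground_truth$masks[["P001"]][["L1"]]
  m1 <- back$ground_truth$masks[["P001"]][["L1"]]
  expect_identical(m1[[1]], m0[[1]])
})
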