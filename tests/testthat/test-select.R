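test_that("SFS picks the perfect predictor first and respects the delta-AUC stop", {
  d <- separable_table(n = 40, n_noise = 12, seed = 1)
  pool <- setdiff(names(d), c("label", "patient"))
  sig <- sfs_select(d, d$label, d$patient, pool = pool,
                    config = selection_config(seed = 4))
  expect_identical(sig$features[1], "sep")
  # nothing can add > 0.03 AUC on top of a perfect predictor -> stops at 1
  expect_length(sig$features, 1)
  expect_equal(sig$cv_auc_mean, 1)
})

test_that("SFS honours the one-in-five cap with many strong independent features", {
  set.seed(9)
  n <- 200
  y <- rep(c(0, 1), each = n / 2)
  d <- tibble::as_tibble(stats::setNames(
    purrr::map(1:10, ~ y * 0.8 + rnorm(n)), paste0("s", 1:10)))
  # a tiny improvement threshold isolates the size cap itself
  sig <- sfs_select(d, y, sprintf("P%03d", seq_len(n)),
                    config = selection_config(seed = 2, delta_auc_threshold = 1e-4))
  expect_length(sig$features, 5)
  expect_true(all(diff(sig$auc_trace) > 0))
})

test_that("mRMR penalizes redundant copies and matches a brute-force MI oracle", {
  set.seed(4)
  n <- 200
  y <- rep(c(0, 1), each = n / 2)
  f1 <- y + rnorm(n, 0, 0.7)
  d <- tibble::tibble(f1 = f1, f2 = f1, f3 = y + rnorm(n, 0, 2.5))
  sig <- mrmr_select(d, y, k = 3)
  expect_identical(sig$features[1], "f1")
  expect_identical(sig$features[2], "f3")        # copy f2 penalized
  expect_error(mrmr_select(d, y, k = 9), "pool")

  # 12-row binary fixture: selection order equals exhaustive MI hand computation
  fx <- tibble::tibble(a = c(0, 0, 0, 0, 0, 0, 1, 1, 1, 1, 1, 1),
                       b = c(0, 1, 0, 1, 0, 1, 0, 1, 0, 1, 0, 1),
                       c = c(0, 0, 0, 0, 1, 1, 1, 1, 1, 1, 0, 0))
  yy <- c(0, 0, 0, 0, 0, 0, 1, 1, 1, 1, 1, 1)
  H <- function(x) { p <- table(x) / length(x); -sum(p * log(p)) }
  mi <- function(x, z) H(x) + H(z) - H(paste(x, z))
  rel <- vapply(fx, function(col) mi(col, yy), numeric(1))
  first <- names(which.max(rel))
  rest <- setdiff(names(fx), first)
  score2 <- vapply(rest, function(f) rel[f] - mi(fx[[f]], fx[[first]]), numeric(1))
  second <- rest[order(-score2, rest)][1]
  sig2 <- mrmr_select(fx, yy, k = 2)
  expect_identical(sig2$features, c(first, second))
  # k = 1 is the univariate MI argmax
  expect_identical(mrmr_select(fx, yy, k = 1)$features, first)
})

test_that("ReliefF ranks a separating feature on top and zeroes constant features", {
  d <- tibble::tibble(sep = c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1) + 0.01 * (1:10),
                      flat = rep(2, 10),
                      noise = c(0.3, 0.8, 0.2, 0.9, 0.5, 0.4, 0.7, 0.1, 0.6, 0.55))
  y <- rep(c(0, 1), each = 5)
  sig <- relieff_select(d, y, k = 3, config = selection_config(n_neighbors = 2))
  expect_identical(sig$features[1], "sep")
  w <- stats::setNames(sig$auc_trace, sig$features)
  expect_equal(unname(w["flat"]), 0)
  expect_gt(w["sep"], w["noise"])
  # deterministic
  expect_identical(sig$auc_trace,
                   relieff_select(d, y, k = 3,
                                  config = selection_config(n_neighbors = 2))$auc_trace)
  expect_error(relieff_select(d, y, k = 2, config = selection_config(n_neighbors = 5)),
               "n_neighbors")
})

test_that("the signature menu yields six candidates with the right pools", {
  d <- separable_table(n = 60, n_noise = 6, seed = 2)
  d$clin1 <- d$label + rnorm(60, 0, 1.5)
  radiomic <- paste0("noise", 1:6)
  d$rad_strong <- d$sep
  sigs <- build_signature_menu(d, d$label, d$patient,
                               radiomic = c("rad_strong", radiomic),
                               clinical = "clin1",
                               config = selection_config(seed = 3))
  expect_equal(nrow(sigs), 6)
  expect_setequal(unique(sigs$algorithm), c("sfs", "mrmr", "relieff"))
  without <- dplyr::filter(sigs, !include_clinical)
  expect_false(any(purrr::map_lgl(without$features, ~ "clin1" %in% .x)))
  best <- pick_signature(sigs)
  expect_s3_class(best, "pr_signature")
  expect_equal(best$cv_auc_mean, max(sigs$cv_auc_mean))
})

test_that("all three selectors recover planted informative features before noise", {
  hits <- purrr::map_lgl(1:5, function(s) {
    tab <- generate_feature_table(120, 30, informative = 3, delta = 1.5, seed = s)
    y <- as.integer(tab$class == "PD")
    feats <- dplyr::select(tab, dplyr::starts_with("f"))
    inf <- attr(tab, "informative")
    cfg <- selection_config(seed = s)
    got <- list(
      sfs_select(feats, y, tab$patient_id, config = cfg)$features,
      mrmr_select(feats, y, k = 3, config = cfg)$features,
      relieff_select(feats, y, k = 3, config = cfg)$features)
    all(purrr::map_lgl(got, ~ length(intersect(.x[1:3], inf)) >= 2))
  })
  expect_gte(mean(hits), 0.8)
})
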