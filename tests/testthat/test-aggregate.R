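test_that("AUC follows the Mann-Whitney identity and rank invariance", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0, 0, 1, 1))$auc, 1)
  sc <- c(0.1, 0.4, 0.35, 0.8); y <- c(0, 0, 1, 1)
  expect_equal(roc_auc(sc, y)$auc, oracle_pair_auc(sc, y))
  set.seed(6)
  sc2 <- runif(40); y2 <- rbinom(40, 1, 0.4)
  expect_equal(roc_auc(sc2, y2)$auc, oracle_pair_auc(sc2, y2))
  expect_equal(roc_auc(qlogis(sc2), y2)$auc, roc_auc(sc2, y2)$auc)  # monotone map
  expect_equal(roc_auc(c(sc2, sc2[1]), c(y2, 1 - y2[1]))$auc,
               oracle_pair_auc(c(sc2, sc2[1]), c(y2, 1 - y2[1])))   # ties
  expect_error(roc_auc(sc, c(1, 1, 1, 1)), "single class")
})

test_that("AUC agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(8)
  sc <- round(runif(60), 2); y <- rbinom(60, 1, 0.35)
  ref <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE, direction = "<")))
  expect_equal(roc_auc(sc, y)$auc, ref, tolerance = 1e-12)
})

test_that("Youden cutoff maximizes J and breaks ties toward the lower threshold", {
  r <- roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  thr <- youden_threshold(r)
  expect_equal(thr, 0.8)            # lowest separating cutoff among J = 1 ties
  # constructed two-maximum curve
  sc <- c(0.1, 0.3, 0.5, 0.7); y <- c(0, 1, 0, 1)
  r2 <- roc_auc(sc, y)
  js <- r2$curve$youden
  expect_equal(youden_threshold(r2), min(r2$curve$threshold[js == max(js)]))
  expect_true(all(js[r2$curve$threshold == youden_threshold(r2)] >= js - 1e-12))
})

test_that("DeLong interval matches pROC and behaves with perfect separation", {
  d <- delong_ci(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(d$auc, 1)
  expect_equal(d$ci_high, 1)        # clipped
  skip_if_not_installed("pROC")
  set.seed(9)
  sc <- rnorm(100) + rep(c(0, 1), each = 50); y <- rep(c(0, 1), each = 50)
  mine <- delong_ci(sc, y)
  ref <- pROC::ci.auc(pROC::roc(y, sc, quiet = TRUE, direction = "<"),
                      method = "delong")
  expect_equal(mine$ci_low, as.numeric(ref[1]), tolerance = 1e-9)
  expect_equal(mine$auc, as.numeric(ref[2]), tolerance = 1e-12)
  expect_equal(mine$ci_high, as.numeric(ref[3]), tolerance = 1e-9)
})

test_that("DeLong interval width shrinks with sample size", {
  width <- function(n, s) {
    set.seed(s)
    y <- rep(c(0, 1), each = n / 2)
    d <- delong_ci(rnorm(n) + 0.8 * y, y)
    d$ci_high - d$ci_low
  }
  expect_lt(mean(vapply(1:5, function(s) width(500, s), numeric(1))),
            mean(vapply(1:5, function(s) width(50, s), numeric(1))))
})

test_that("lesion frequency score counts supra-cutoff slices inclusively", {
  expect_equal(lesion_frequency_score(c(0.30, 0.25, 0.10, 0.05, 0.02), 0.22), 2)
  expect_equal(lesion_frequency_score(c(0.1, 0.1), 0.22), 0)
  expect_equal(lesion_frequency_score(c(0.1, 0.5, 0.3), 0), 3)
  expect_equal(lesion_frequency_score(c(0.22, 0.1), 0.22), 1)   # boundary inclusive
  expect_error(lesion_frequency_score(numeric(0), 0.2), "empty")
})

test_that("hierarchy classifies the documented lesion/patient example", {
  sc <- tibble::tibble(
    patient_id = "P1",
    lesion_id = rep(c("L1", "L2"), each = 5),
    score = c(rep(0.1, 5), 0.5, 0.6, 0.7, 0.1, 0.1))
  out <- classify_hierarchy(sc, threshold_set(0.22, 2, 1))
  expect_equal(out$lesions$freq_score, c(0, 3))
  expect_equal(out$lesions$label, c("DC", "PD"))
  expect_equal(out$patients$label, "PD")
  expect_equal(out$patients$patient_score, 3)
  # all below X -> DC
  low <- classify_hierarchy(dplyr::mutate(sc, score = 0.01), threshold_set(0.22, 2, 1))
  expect_equal(low$patients$label, "DC")
})

test_that("raising the slice cutoff never flips a patient from DC to PD", {
  for (s in 1:20) {
    sc <- random_score_set(s)
    a <- suppressWarnings(classify_hierarchy(sc, threshold_set(0.2, 2, 1)))$patients
    b <- suppressWarnings(classify_hierarchy(sc, threshold_set(0.5, 2, 1)))$patients
    flipped <- a$label == "DC" & b$label == "PD"
    expect_false(any(flipped))
  }
})

test_that("patient-level score is invariant to lesion ordering", {
  sc <- random_score_set(3)
  shuf <- sc[rev(seq_len(nrow(sc))), ]
  a <- suppressWarnings(classify_hierarchy(sc, threshold_set()))$patients
  b <- suppressWarnings(classify_hierarchy(shuf, threshold_set()))$patients
  expect_equal(dplyr::arrange(a, patient_id), dplyr::arrange(b, patient_id))
})

test_that("threshold optimization recovers a planted operating point", {
  set.seed(10)
  n_pat <- 150
  truth <- rbinom(n_pat, 1, 0.3)
  rows <- purrr::map(seq_len(n_pat), function(p) {
    mu <- ifelse(truth[p] == 1, 0.60, 0.30)
    tibble::tibble(patient_id = sprintf("P%03d", p), lesion_id = "L1",
                   score = pmin(pmax(rnorm(5, mu, 0.12), 0), 1),
                   label = truth[p])
  }) |> purrr::list_rbind()
  thr <- optimize_thresholds(rows)
  expect_true(thr$slice_count_cutoff %in% 1:5)
  expect_gte(thr$lesion_count_cutoff, 1)
  cls <- classify_hierarchy(rows, thr)$patients
  truth_df <- dplyr::distinct(rows, patient_id, label)
  cs <- confusion(cls$label[match(truth_df$patient_id, cls$patient_id)],
                  truth_df$label)
  expect_gte(cs$sn, 0.85)
})

test_that("threshold optimization refuses externally-tagged rows", {
  sc <- tibble::tibble(patient_id = c("P1", "P2"), lesion_id = "L1",
                       score = c(0.9, 0.1), label = c(1, 0),
                       split = c("discovery", "external"))
  expect_error(optimize_thresholds(sc), class = "perirad_leakage_error")
})

test_that("confusion reproduces the published patient-level operating points", {
  disc <- confusion_from_counts(tp = 24, fn = 3, fp = 14, tn = 56)
  expect_equal(disc$sn, 24 / 27)
  expect_equal(round(disc$sn, 3), 0.889)
  expect_equal(disc$sp, 0.800)
  ext <- confusion_from_counts(tp = 9, fn = 0, fp = 3, tn = 5)
  expect_equal(ext$sn, 1.000)
  expect_equal(ext$sp, 0.625)
  perfect <- confusion(c(1, 1, 0), c(1, 1, 0))
  expect_equal(c(perfect$sn, perfect$sp, perfect$f1), c(1, 1, 1))
  # integer identity sn * (tp + fn) = tp
  set.seed(2)
  p <- rbinom(30, 1, 0.5); t_ <- rbinom(30, 1, 0.5)
  cs <- confusion(p, t_)
  expect_equal(cs$sn * (cs$tp + cs$fn), cs$tp)
})

test_that("RECIST boundaries are inclusive and CR takes precedence", {
  expect_equal(recist_classify(100, 120), "PD")    # exactly +20%
  expect_equal(recist_classify(100, 70), "PR")     # exactly -30%
  expect_equal(recist_classify(100, 100), "SD")
  expect_equal(recist_classify(100, 119.9), "SD")
  expect_equal(recist_classify(100, 0, all_disappeared = TRUE), "CR")
  expect_equal(recist_classify(c(100, 50), c(130, 40)), c("PD", "SD"))
  expect_error(recist_classify(0, 10), "baseline")
})
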