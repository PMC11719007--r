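# Slice -> lesion -> patient frequency-threshold hierarchy, ROC machinery
# (Mann-Whitney AUC, Youden-J operating point, fast DeLong confidence
# intervals), confusion statistics with PD as the positive class, and
# RECIST response labelling.

# Mann-Whitney AUC with ties counted 0.5
mw_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) rlang::abort("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC analysis of risk scores
#'
#' AUC by the Mann-Whitney identity (ties counted 0.5) with the full
#' sensitivity/specificity curve evaluated at every distinct score (each
#' cutoff classifies `score >= cutoff` as PD).
#'
#' @param scores Numeric risk scores.
#' @param labels Binary labels (PD positive).
#' @return A `roc_result`: `auc` plus a `curve` tibble of `threshold`,
#'   `sensitivity`, `specificity`, `youden`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) rlang::abort("labels contain a single class")
  stopifnot(length(scores) == length(y))
  thr <- sort(unique(scores))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  sens <- vapply(thr, function(t) sum(scores >= t & y == 1) / n1, numeric(1))
  spec <- vapply(thr, function(t) sum(scores < t & y == 0) / n0, numeric(1))
  curve <- tibble::tibble(threshold = thr, sensitivity = sens,
                          specificity = spec, youden = sens + spec - 1)
  structure(list(auc = mw_auc(scores, y), curve = curve,
                 n_pos = n1, n_neg = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result: AUC %.3f (%d PD / %d DC), %d cutoffs>\n",
              x$auc, x$n_pos, x$n_neg, nrow(x$curve)))
  invisible(x)
}

#' Youden-J optimal cutoff
#'
#' The threshold maximizing `sensitivity + specificity - 1`; ties break
#' toward the lower threshold, favouring sensitivity — the risk-averse
#' operating point for a progression classifier.
#'
#' @param roc A `roc_result` from [roc_auc()].
#' @return The cutoff value.
#' @export
youden_threshold <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  j <- roc$curve$youden
  best <- which(j >= max(j) - 1e-12)
  roc$curve$threshold[min(best)]
}

#' Fast DeLong confidence interval for the AUC
#'
#' Nonparametric AUC variance by the DeLong placement-value estimator with a
#' normal-approximation confidence interval, clipped to `[0, 1]`.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary labels; each class needs at least 2 members.
#' @param alpha Two-sided error rate (default 0.05 for a 95% CI).
#' @return Tibble: `auc`, `ci_low`, `ci_high`, `se`.
#' @export
delong_ci <- function(scores, labels, alpha = 0.05) {
  y <- as_binary_labels(labels)
  pos <- scores[y == 1]; neg <- scores[y == 0]
  m <- length(pos); n <- length(neg)
  if (m < 2 || n < 2) rlang::abort("each class needs at least 2 members")
  # placement values via the midrank trick (fast DeLong)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n            # P(X_i > Y) w/ ties 0.5
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m    # P(X > Y_j)
  auc <- mean(v10)
  se <- sqrt(stats::var(v10) / m + stats::var(v01) / n)
  z <- stats::qnorm(1 - alpha / 2)
  tibble::tibble(auc = auc,
                 ci_low = max(0, auc - z * se),
                 ci_high = min(1, auc + z * se),
                 se = se)
}

#' Threshold set for the frequency hierarchy
#'
#' The three cutoffs of the slice -> lesion -> patient classifier. The
#' published operating point is X = 0.22 (slice-level Youden-J), Y = 2
#' supra-threshold slices for a PD lesion, and Z = 1 PD lesion for a PD
#' patient.
#'
#' @param slice_cutoff X in `[0, 1]`: a slice is high-risk when its score is
#'   `>= X`.
#' @param slice_count_cutoff Y in 1..5: a lesion is PD when at least Y of
#'   its slices are high-risk.
#' @param lesion_count_cutoff Z >= 1: a patient is PD when at least Z
#'   lesions are PD.
#' @return A `threshold_set`.
#' @export
threshold_set <- function(slice_cutoff = 0.22, slice_count_cutoff = 2L,
                          lesion_count_cutoff = 1L) {
  check_fraction(slice_cutoff, "slice_cutoff")
  y <- check_count(slice_count_cutoff, "slice_count_cutoff")
  if (y > 5) stop_field("slice_count_cutoff", "must be in 1..5")
  check_count(lesion_count_cutoff, "lesion_count_cutoff")
  structure(list(slice_cutoff = slice_cutoff,
                 slice_count_cutoff = y,
                 lesion_count_cutoff = as.integer(lesion_count_cutoff)),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("<threshold_set: X = %.3g, Y = %d slices, Z = %d lesion(s)>\n",
              x$slice_cutoff, x$slice_count_cutoff, x$lesion_count_cutoff))
  invisible(x)
}

#' Lesion frequency score
#'
#' Counts how many of a lesion's slice scores are at or above the slice
#' cutoff X (inclusive comparison).
#'
#' @param slice_scores Numeric vector of 1-5 slice risk scores.
#' @param slice_cutoff The cutoff X.
#' @return Integer count in 0..length(slice_scores).
#' @export
lesion_frequency_score <- function(slice_scores, slice_cutoff) {
  if (!length(slice_scores)) rlang::abort("empty slice score list")
  sum(slice_scores >= slice_cutoff)
}

#' Slice -> lesion -> patient frequency-threshold classification
#'
#' Applies the hierarchy: a lesion's frequency score is the number of slice
#' scores `>= X`; the lesion is PD when that count is `>= Y`; a patient is
#' PD when the number of PD lesions is `>= Z`. The patient-level continuous
#' score (for ROC construction) is the maximum lesion frequency score.
#' Lesions with fewer than Y slices can never be PD (the absolute count is
#' applied unchanged); a warning notes them.
#'
#' @param scores Tibble with `patient_id`, `lesion_id`, `score` (one row per
#'   slice).
#' @param thresholds A [threshold_set()].
#' @return List of two tibbles: `lesions` (`patient_id`, `lesion_id`,
#'   `n_slices`, `freq_score`, `label`) and `patients` (`patient_id`,
#'   `n_pd_lesions`, `patient_score`, `label`).
#' @export
classify_hierarchy <- function(scores, thresholds = threshold_set()) {
  stopifnot(inherits(thresholds, "threshold_set"))
  x <- thresholds$slice_cutoff; yc <- thresholds$slice_count_cutoff
  z <- thresholds$lesion_count_cutoff
  lesions <- scores |>
    dplyr::group_by(.data$patient_id, .data$lesion_id) |>
    dplyr::summarise(n_slices = dplyr::n(),
                     freq_score = sum(.data$score >= x), .groups = "drop") |>
    dplyr::mutate(label = ifelse(.data$freq_score >= yc, "PD", "DC"))
  short <- sum(lesions$n_slices < yc)
  if (short > 0)
    rlang::warn(paste0(short, " lesion(s) have fewer than Y = ", yc,
                       " slices and can never be classified PD"))
  patients <- lesions |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(n_pd_lesions = sum(.data$label == "PD"),
                     patient_score = max(.data$freq_score), .groups = "drop") |>
    dplyr::mutate(label = ifelse(.data$n_pd_lesions >= z, "PD", "DC"))
  list(lesions = lesions, patients = patients)
}

#' Optimize the frequency-threshold set on the discovery set
#'
#' X is the Youden-J cutoff of the slice-level ROC of the out-of-fold
#' discovery scores. Given X, (Y, Z) maximize the patient-level Youden-J of
#' the resulting binary classification, with ties toward smaller Y then
#' smaller Z (risk-averse: favours sensitivity). Refuses to run if any row
#' is tagged external — thresholds must be frozen before external
#' evaluation.
#'
#' @param scores Tibble with `patient_id`, `lesion_id`, `score`, `label`
#'   (slice rows; `label` is the patient's true class), optionally `split`.
#' @return A `threshold_set`.
#' @export
optimize_thresholds <- function(scores) {
  if ("split" %in% names(scores) && any(scores$split == "external"))
    rlang::abort("optimize_thresholds() received externally-tagged rows; thresholds must be frozen on the discovery set only",
                 class = "perirad_leakage_error")
  y <- as_binary_labels(scores$label)
  x_cut <- youden_threshold(roc_auc(scores$score, y))
  truth <- scores |>
    dplyr::distinct(.data$patient_id, .data$label)
  max_lesions <- scores |>
    dplyr::distinct(.data$patient_id, .data$lesion_id) |>
    dplyr::count(.data$patient_id) |>
    dplyr::pull(.data$n) |> max()
  best <- NULL
  for (yy in 1:5) for (zz in seq_len(max(max_lesions, 1))) {
    cls <- suppressWarnings(
      classify_hierarchy(scores, threshold_set(x_cut, yy, zz))$patients)
    pred <- cls$label[match(truth$patient_id, cls$patient_id)]
    cs <- confusion(pred, truth$label)
    j <- cs$sn + cs$sp - 1
    if (is.null(best) || j > best$j + 1e-12) best <- list(j = j, y = yy, z = zz)
  }
  threshold_set(x_cut, best$y, best$z)
}

#' Confusion statistics with PD as the positive class
#'
#' @param pred,truth Equal-length binary vectors (0/1, logical, or
#'   "PD"/"DC").
#' @return A `confusion_stats`: counts `tp`, `fn`, `fp`, `tn` and rates
#'   `sn`, `sp`, `ppv`, `f1`.
#' @export
confusion <- function(pred, truth) {
  if (length(pred) != length(truth)) rlang::abort("pred/truth length mismatch")
  p <- as_binary_labels(pred); t_ <- as_binary_labels(truth)
  tp <- sum(p == 1 & t_ == 1); fn <- sum(p == 0 & t_ == 1)
  fp <- sum(p == 1 & t_ == 0); tn <- sum(p == 0 & t_ == 0)
  confusion_from_counts(tp, fn, fp, tn)
}

#' @rdname confusion
#' @param tp,fn,fp,tn Confusion counts (PD positive).
#' @export
confusion_from_counts <- function(tp, fn, fp, tn) {
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (is.na(ppv) || is.na(sn) || ppv + sn == 0) NA_real_
        else 2 * ppv * sn / (ppv + sn)
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn,
                 sn = sn, sp = sp, ppv = ppv, f1 = f1),
            class = "confusion_stats")
}

#' @export
print.confusion_stats <- function(x, ...) {
  cat(sprintf("<confusion: TP %d FN %d FP %d TN %d | SN %.3f SP %.3f PPV %.3f F1 %.3f>\n",
              x$tp, x$fn, x$fp, x$tn, x$sn, x$sp, x$ppv, x$f1))
  invisible(x)
}

#' RECIST v1.1 response category from sums of diameters
#'
#' PD: at least a 20% increase of the sum of diameters; PR: at least a 30%
#' decrease; CR: disappearance of all target lesions; SD otherwise. Both
#' percentage boundaries are inclusive.
#'
#' @param baseline_sum_mm,followup_sum_mm Sums of target-lesion diameters
#'   (mm); baseline must be positive. Vectorized.
#' @param all_disappeared Logical: all target lesions disappeared.
#' @return Character vector in `c("CR", "PR", "SD", "PD")`.
#' @examples
#' recist_classify(100, 120) # "PD"
#' recist_classify(100, 70)  # "PR"
#' @export
recist_classify <- function(baseline_sum_mm, followup_sum_mm,
                            all_disappeared = FALSE) {
  if (any(baseline_sum_mm <= 0)) stop_field("baseline_sum_mm", "must be positive")
  n <- max(length(baseline_sum_mm), length(followup_sum_mm), length(all_disappeared))
  b <- rep_len(baseline_sum_mm, n); f <- rep_len(followup_sum_mm, n)
  cr <- rep_len(all_disappeared, n)
  change <- (f - b) / b
  dplyr::case_when(cr ~ "CR",
                   change >= 0.20 ~ "PD",
                   change <= -0.30 ~ "PR",
                   TRUE ~ "SD")
}
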