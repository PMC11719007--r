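#' Broom-style tidiers for perirad objects
#'
#' `tidy()` returns one row per estimated quantity; `glance()` returns a
#' one-row model summary.
#'
#' @param x A fitted perirad object.
#' @param ... Unused.
#' @name tidiers
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname tidiers
#' @method tidy risk_model
#' @export
tidy.risk_model <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", names(x$coefficients)),
                 estimate = c(x$intercept, unname(x$coefficients)))
}

#' @rdname tidiers
#' @method glance risk_model
#' @export
glance.risk_model <- function(x, ...) {
  tibble::tibble(n_features = length(x$coefficients),
                 cv_auc_mean = x$cv_auc_mean, cv_auc_sd = x$cv_auc_sd,
                 lambda = x$hyperparameters$lambda,
                 class_weight = x$hyperparameters$class_weight)
}

#' @rdname tidiers
#' @method tidy confusion_stats
#' @export
tidy.confusion_stats <- function(x, ...) {
  tibble::tibble(metric = c("tp", "fn", "fp", "tn", "sn", "sp", "ppv", "f1"),
                 value = c(x$tp, x$fn, x$fp, x$tn, x$sn, x$sp, x$ppv, x$f1))
}

#' @rdname tidiers
#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @rdname tidiers
#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @rdname tidiers
#' @method tidy pr_signature
#' @export
tidy.pr_signature <- function(x, ...) {
  tibble::tibble(rank = seq_along(x$features), feature = x$features,
                 auc_trace = if (length(x$auc_trace) == length(x$features))
                   x$auc_trace else NA_real_)
}

#' @rdname tidiers
#' @method glance pd_risk_run
#' @export
glance.pd_risk_run <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$metrics, names_from = "split",
                             values_from = c("auc", "sn", "sp", "f1"))
  dplyr::bind_cols(
    tibble::tibble(signature = paste(x$signature$features, collapse = " + "),
                   slice_cutoff = x$thresholds$slice_cutoff,
                   slice_count_cutoff = x$thresholds$slice_count_cutoff,
                   lesion_count_cutoff = x$thresholds$lesion_count_cutoff),
    wide)
}
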