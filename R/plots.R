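#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the main result types:
#' ROC curves, Kaplan-Meier curves, mask triplets and the signature menu.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name perirad-plots
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname perirad-plots
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  df <- object$curve |> dplyr::arrange(dplyr::desc(.data$threshold))
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_step(linewidth = 0.8, colour = "grey20") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey65") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' @rdname perirad-plots
#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- dplyr::bind_rows(tibble::tibble(time = 0, surv = 1), object["time"] |>
                           dplyr::mutate(surv = object$surv))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' @rdname perirad-plots
#' @method autoplot mask_triplet
#' @export
autoplot.mask_triplet <- function(object, ...) {
  to_df <- function(m, region) {
    idx <- which(m, arr.ind = TRUE)
    tibble::tibble(row = idx[, 1], col = idx[, 2], region = region)
  }
  df <- dplyr::bind_rows(to_df(object$ring, "Ring"),
                         to_df(object$core_plus_edge & !object$core, "Edge"),
                         to_df(object$core, "Core"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$region)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_manual(values = c(Core = "#b2182b", Edge = "#ef8a62",
                                          Ring = "#67a9cf")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Region") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier comparison of predicted risk groups
#'
#' @param comparison Output of [compare_risk_groups()].
#' @return A ggplot of the two survival curves annotated with the log-rank
#'   p-value.
#' @export
plot_risk_groups <- function(comparison) {
  base <- comparison$curves |>
    dplyr::group_by(.data$risk_group) |>
    dplyr::group_modify(~ dplyr::bind_rows(tibble::tibble(time = 0, surv = 1),
                                           .x[c("time", "surv")])) |>
    dplyr::ungroup()
  ggplot2::ggplot(base, ggplot2::aes(x = .data$time, y = .data$surv,
                                     colour = .data$risk_group)) +
    ggplot2::geom_step(linewidth = 0.9) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  colour = "Risk group",
                  subtitle = sprintf("log-rank p = %.2g", comparison$test$p_value)) +
    ggplot2::theme_minimal()
}

#' Signature menu comparison plot
#'
#' @param menu Output of [build_signature_menu()].
#' @return A ggplot of CV AUC (mean +/- SD) per candidate signature.
#' @export
plot_signature_menu <- function(menu) {
  df <- menu |>
    dplyr::mutate(label = paste0(.data$algorithm,
                                 ifelse(.data$include_clinical, " + clinical", "")))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$label, .data$cv_auc_mean),
                                   y = .data$cv_auc_mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$cv_auc_mean - .data$cv_auc_sd,
                                          ymax = .data$cv_auc_mean + .data$cv_auc_sd)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Grouped-CV AUC (mean ± SD)") +
    ggplot2::theme_minimal()
}
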