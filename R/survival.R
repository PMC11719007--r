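# Kaplan-Meier estimation and Mantel-Cox log-rank comparison of the
# predicted low- vs high-risk progression groups, as thin tidy wrappers
# around the survival package. Ties between an event and a censoring at the
# same time follow the standard KM convention (event first).

#' Kaplan-Meier product-limit estimate
#'
#' @param records Tibble with `time` (months, > 0) and `event` (1 =
#'   progression/death, 0 = censored).
#' @return A `km_curve`: tibble of `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv` (step values; survival starts at 1 and is non-increasing).
#' @export
km_estimate <- function(records) {
  records <- tibble::as_tibble(records)
  if (!nrow(records)) rlang::abort("need at least one record")
  if (any(records$time <= 0)) stop_field("time", "must be positive")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = records, conf.type = "none")
  out <- tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                        n_event = fit$n.event, n_censor = fit$n.censor,
                        surv = fit$surv)
  class(out) <- c("km_curve", class(out))
  out
}

#' Mantel-Cox log-rank test between two risk groups
#'
#' @param records Tibble with `time`, `event` and a grouping column.
#' @param group Name of the grouping column (two levels).
#' @return Tibble: `chi_square`, `df`, `p_value`, `n_a`, `n_b`,
#'   `events`.
#' @export
logrank_test <- function(records, group = "risk_group") {
  records <- tibble::as_tibble(records)
  g <- records[[group]]
  if (length(unique(g)) != 2) stop_field("group", "need exactly two nonempty groups")
  if (sum(records$event) == 0) rlang::abort("no events: log-rank test undefined")
  if (any(records$time <= 0)) stop_field("time", "must be positive")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ g, data = records)
  chi <- sd_$chisq
  tibble::tibble(chi_square = chi, df = 1L,
                 p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
                 n_a = sum(g == sort(unique(g))[1]),
                 n_b = sum(g == sort(unique(g))[2]),
                 events = sum(records$event))
}

#' Compare survival between predicted risk groups
#'
#' Runs [km_estimate()] per group and the log-rank test for one endpoint.
#'
#' @param records Tibble with `time`, `event`, `risk_group` and optionally
#'   `endpoint`.
#' @param endpoint Optional endpoint filter (e.g. `"PFS"`, `"OS"`).
#' @return List: `curves` (tibble of per-group `km_curve` rows with a
#'   `risk_group` column) and `test` (the log-rank tibble).
#' @export
compare_risk_groups <- function(records, endpoint = NULL) {
  records <- tibble::as_tibble(records)
  if (!is.null(endpoint) && "endpoint" %in% names(records))
    records <- dplyr::filter(records, .data$endpoint == !!endpoint)
  curves <- records |>
    dplyr::group_by(.data$risk_group) |>
    dplyr::group_modify(~ km_estimate(.x)) |>
    dplyr::ungroup()
  list(curves = curves, test = logrank_test(records))
}
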