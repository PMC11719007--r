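# Train/apply-asymmetric preprocessing: one-hot encoding, [-1, 1] range
# scaling learned on the discovery split only, and the first-pass feature
# filter that prunes weak, near-constant and redundant radiomic features
# before any selection algorithm runs. Clinical columns are exempt from the
# filter by contract.

#' One-hot encode categorical columns
#'
#' Each declared categorical column becomes one 0/1 indicator column per
#' level seen at fit time (`<col>_<level>`). At apply time an unseen level
#' maps to an all-zero indicator row with a warning, mirroring how a model
#' trained on the discovery set must handle out-of-distribution categories.
#'
#' @param data A data frame.
#' @param cols Character vector of categorical column names; defaults to all
#'   character/factor columns.
#' @param levels Optional named list of level sets learned at fit time (from
#'   the `one_hot_levels` attribute of a previous call).
#' @return A tibble with indicator columns in place of `cols`; the learned
#'   level sets are attached as attribute `one_hot_levels`.
#' @export
one_hot <- function(data, cols = NULL, levels = NULL) {
  data <- tibble::as_tibble(data)
  if (is.null(cols))
    cols <- names(data)[vapply(data, function(x) is.character(x) || is.factor(x),
                               logical(1))]
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop_field("cols", paste0("not present: ", paste(missing_cols, collapse = ", ")))
  learned <- list()
  for (cl in cols) {
    x <- as.character(data[[cl]])
    lv <- if (!is.null(levels) && !is.null(levels[[cl]])) levels[[cl]] else sort(unique(x))
    learned[[cl]] <- lv
    unseen <- setdiff(unique(x), lv)
    if (length(unseen))
      rlang::warn(paste0("unseen level(s) in `", cl, "`: ",
                         paste(unseen, collapse = ", "),
                         " -> all-zero indicators"))
    ind <- purrr::map(lv, function(l) as.integer(x == l)) |>
      stats::setNames(paste0(cl, "_", lv)) |> tibble::as_tibble()
    pos <- match(cl, names(data))
    data <- dplyr::bind_cols(data[seq_len(pos - 1L)], ind,
                             data[seq(pos + 1L, length.out = ncol(data) - pos)])
  }
  attr(data, "one_hot_levels") <- learned
  data
}

#' Learn [-1, 1] range-scaling parameters on the training split
#'
#' @param train Data frame of numeric feature columns (training rows only —
#'   the caller is responsible for passing the discovery split).
#' @param cols Columns to scale; defaults to all numeric columns.
#' @return A `scaler_params` object: tibble of `feature`, `min`, `max`.
#' @export
fit_scaler <- function(train, cols = NULL) {
  train <- tibble::as_tibble(train)
  if (is.null(cols)) cols <- names(train)[vapply(train, is.numeric, logical(1))]
  params <- tibble::tibble(
    feature = cols,
    min = vapply(cols, function(cl) min(train[[cl]]), numeric(1), USE.NAMES = FALSE),
    max = vapply(cols, function(cl) max(train[[cl]]), numeric(1), USE.NAMES = FALSE))
  structure(params, class = c("scaler_params", class(params)))
}

#' Apply learned range scaling
#'
#' Maps each feature by `x' = 2 (x - min) / (max - min) - 1` using the
#' training-split min/max. Training rows land in `[-1, 1]`; values outside
#' the training range (e.g. external test rows) fall outside `[-1, 1]` and
#' are deliberately NOT clamped. A constant training feature maps to 0.
#'
#' @param data Data frame containing the features.
#' @param scaler A `scaler_params` from [fit_scaler()].
#' @return Tibble with scaled feature columns (other columns untouched).
#' @export
apply_scaler <- function(data, scaler) {
  stopifnot(inherits(scaler, "scaler_params"))
  data <- tibble::as_tibble(data)
  for (k in seq_len(nrow(scaler))) {
    f <- scaler$feature[k]
    if (!f %in% names(data)) next
    rng <- scaler$max[k] - scaler$min[k]
    data[[f]] <- if (rng <= 0) rep(0, nrow(data))
                 else 2 * (data[[f]] - scaler$min[k]) / rng - 1
  }
  data
}

# univariate AUC folded to max(a, 1 - a); Mann-Whitney identity
folded_auc <- function(x, y) {
  a <- mw_auc(x, y)
  max(a, 1 - a)
}

#' First-pass feature filter
#'
#' Prunes the radiomic feature pool before selection, in a fixed order:
#' (1) near-constant features (variance below `var_tol`); (2) weak features
#' (univariate AUC for the class labels, folded as `max(a, 1 - a)`, below
#' `auc_min`); (3) redundant features (pairwise Spearman `|rho|` above
#' `rho_max`; of each such pair the member with the lower folded AUC is
#' dropped, ties dropping the lexicographically later name). Clinical
#' columns are exempt from all three rules.
#'
#' @param train Data frame of scaled training features.
#' @param labels Binary labels (PD = positive), one per row.
#' @param clinical Character vector of clinical column names to exempt.
#' @param var_tol,auc_min,rho_max The three thresholds.
#' @return A `filter_report`: list with `retained`, `removed`
#'   (tibble of `feature`, `reason`), and `parameters`.
#' @export
first_pass_filter <- function(train, labels, clinical = character(),
                              var_tol = 1e-8, auc_min = 0.55, rho_max = 0.95) {
  train <- tibble::as_tibble(train)
  y <- as_binary_labels(labels)
  if (length(y) != nrow(train)) stop_field("labels", "length must match rows")
  pool <- setdiff(names(train)[vapply(train, is.numeric, logical(1))], clinical)
  removed <- tibble::tibble(feature = character(), reason = character())

  vars <- vapply(pool, function(f) stats::var(train[[f]]), numeric(1))
  near_const <- pool[vars < var_tol]
  removed <- dplyr::bind_rows(removed,
    tibble::tibble(feature = near_const, reason = "near-constant"))
  pool <- setdiff(pool, near_const)

  aucs <- vapply(pool, function(f) folded_auc(train[[f]], y), numeric(1))
  weak <- pool[aucs < auc_min]
  removed <- dplyr::bind_rows(removed, tibble::tibble(feature = weak, reason = "weak"))
  pool <- setdiff(pool, weak)
  aucs <- aucs[pool]

  if (length(pool) > 1) {
    rho <- suppressWarnings(stats::cor(as.matrix(train[pool]), method = "spearman"))
    drop <- character()
    ord <- pool  # fixed, order-stable scan
    for (i in seq_along(ord)) for (j in seq_along(ord)) {
      if (j <= i) next
      a <- ord[i]; b <- ord[j]
      if (a %in% drop || b %in% drop) next
      if (is.na(rho[a, b]) || abs(rho[a, b]) <= rho_max) next
      loser <- if (aucs[a] < aucs[b]) a
               else if (aucs[b] < aucs[a]) b
               else max(a, b)          # tie: lexicographically later name
      drop <- c(drop, loser)
    }
    removed <- dplyr::bind_rows(removed,
      tibble::tibble(feature = drop, reason = "redundant"))
    pool <- setdiff(pool, drop)
  }

  retained <- c(pool, intersect(clinical, names(train)))
  if (length(setdiff(retained, clinical)) == 0 && length(retained) == 0)
    rlang::abort("first-pass filter removed every feature; cannot proceed to selection")
  structure(list(retained = retained, removed = removed,
                 parameters = list(var_tol = var_tol, auc_min = auc_min,
                                   rho_max = rho_max, clinical = clinical)),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  tab <- table(x$removed$reason)
  cat(sprintf("<filter_report: %d retained, %d removed (%s)>\n",
              length(x$retained), nrow(x$removed),
              paste(names(tab), tab, sep = " = ", collapse = ", ")))
  invisible(x)
}

#' @rdname tidiers
#' @method tidy filter_report
#' @export
tidy.filter_report <- function(x, ...) {
  dplyr::bind_rows(
    x$removed,
    tibble::tibble(feature = x$retained, reason = "retained"))
}
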