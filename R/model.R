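# Grouped nested-cross-validated ridge logistic regression with grid search,
# and the fixed published four-variable risk calculator.

#' Patient-grouped stratified fold plan
#'
#' Assigns every patient to exactly one outer fold, stratified by the
#' patient-level class label, so no patient (hence no lesion or slice)
#' appears on both sides of any train/test split.
#'
#' @param patient_ids Patient id per row (or one per patient).
#' @param labels Binary label per row (consistent within patient).
#' @param k Number of folds.
#' @param seed Integer seed; the plan is deterministic given the seed.
#' @return A `fold_plan`: tibble of `patient_id`, `label`, `fold`, with
#'   attributes `k` and `seed`.
#' @export
make_fold_plan <- function(patient_ids, labels, k = 5L, seed = 1L) {
  k <- check_count(k, "k")
  y <- as_binary_labels(labels)
  pat <- tibble::tibble(patient_id = as.character(patient_ids), label = y) |>
    dplyr::distinct()
  if (anyDuplicated(pat$patient_id))
    stop_field("labels", "inconsistent labels within a patient")
  n_min <- min(table(pat$label))
  if (k > n_min)
    stop_field("k", paste0("exceeds the minority-class patient count (", n_min, ")"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  plan <- pat |>
    dplyr::group_by(.data$label) |>
    dplyr::mutate(fold = sample(rep_len(seq_len(k), dplyr::n()))) |>
    dplyr::ungroup()
  attr(plan, "k") <- k
  attr(plan, "seed") <- as.integer(seed)
  class(plan) <- c("fold_plan", class(plan))
  plan
}

# save/restore RNG state so fold planning does not perturb caller randomness
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Hyperparameter grid for the ridge logistic model
#'
#' @param lambda L2 penalty strengths to search.
#' @param class_weight `"none"` and/or `"balanced"` (inverse-prevalence row
#'   weights).
#' @return Tibble of grid points.
#' @export
lr_grid <- function(lambda = c(0.01, 0.1, 1, 10, 100),
                    class_weight = c("none", "balanced")) {
  tidyr::expand_grid(lambda = lambda, class_weight = class_weight)
}

row_weights <- function(y, class_weight) {
  if (class_weight == "none") return(rep(1, length(y)))
  n <- length(y); tab <- table(y)
  as.numeric(n / (2 * tab[as.character(y)]))
}

# ridge logistic at a fixed lambda via glmnet; x may have a single column
# (a zero column is appended so glmnet always sees >= 2 predictors)
ridge_logistic <- function(x, y, lambda, class_weight) {
  pad <- ncol(x) < 2
  if (pad) x <- cbind(x, `.pad` = 0)
  w <- row_weights(y, class_weight)
  lambdas <- sort(unique(c(lambda, lambda * c(10, 100))), decreasing = TRUE)
  fit <- withCallingHandlers(
    glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                   lambda = lambdas, weights = w, standardize = FALSE),
    warning = function(cnd) {
      # small inner folds trip glmnet's small-class advisory; harmless here
      if (grepl("fewer than 8", conditionMessage(cnd)))
        rlang::cnd_muffle(cnd)
    })
  b <- as.numeric(stats::coef(fit, s = lambda, exact = FALSE))
  names(b) <- c("(Intercept)", colnames(x))
  if (pad) b <- b[names(b) != ".pad"]
  b
}

predict_logit <- function(coefs, newdata) {
  x <- as.matrix(newdata[names(coefs)[-1]])
  stats::plogis(drop(cbind(1, x) %*% coefs))
}

# inner grouped CV over the grid; returns the best grid row (max mean AUC,
# ties toward larger lambda then "none" weighting for determinism)
select_grid_point <- function(data, y, groups, features, grid, k, seed) {
  plan <- make_fold_plan(groups, y, k = k, seed = seed)
  fold_of <- plan$fold[match(groups, plan$patient_id)]
  x <- as.matrix(data[features])
  aucs <- purrr::pmap_dbl(grid, function(lambda, class_weight) {
    fa <- numeric(0)
    for (kk in sort(unique(fold_of))) {
      te <- fold_of == kk
      if (length(unique(y[!te])) < 2 || length(unique(y[te])) < 2) next
      b <- ridge_logistic(x[!te, , drop = FALSE], y[!te], lambda, class_weight)
      sc <- stats::plogis(drop(cbind(1, x[te, , drop = FALSE]) %*% b))
      fa <- c(fa, mw_auc(sc, y[te]))
    }
    mean(fa)
  })
  ord <- order(-round(aucs, 10), -grid$lambda, grid$class_weight)
  grid[ord[1], ]
}

#' Nested cross-validated logistic risk model
#'
#' For each outer fold of the patient-grouped plan, an inner grouped 5-fold
#' grid search picks the ridge penalty and class weighting, the model is fit
#' on the outer-training split and scored on the held-out fold (out-of-fold
#' slice scores). The final model re-runs the grid search on, and is refit
#' to, all discovery rows.
#'
#' @param data Data frame of scaled features (discovery rows only).
#' @param labels Binary label per row.
#' @param groups Patient id per row.
#' @param features Signature column names to use.
#' @param fold_plan A [make_fold_plan()] plan for the outer folds.
#' @param grid Hyperparameter grid from [lr_grid()].
#' @param inner_k Inner CV folds for the grid search.
#' @return A `risk_model`: intercept, coefficients, hyperparameters, CV AUC
#'   mean/SD across outer folds, and the out-of-fold scores tibble.
#' @export
fit_lr_nested <- function(data, labels, groups, features,
                          fold_plan = NULL, grid = lr_grid(), inner_k = 5L) {
  data <- tibble::as_tibble(data)
  y <- as_binary_labels(labels)
  bad <- features[!vapply(features, function(f) all(is.finite(data[[f]])), logical(1))]
  if (length(bad))
    stop_field("data", paste0("non-finite values in feature(s): ",
                              paste(bad, collapse = ", ")))
  groups <- as.character(groups)
  if (is.null(fold_plan)) fold_plan <- make_fold_plan(groups, y, k = 5L, seed = 1L)
  fold_of <- fold_plan$fold[match(groups, fold_plan$patient_id)]
  seed <- attr(fold_plan, "seed") %||% 1L
  x <- as.matrix(data[features])
  oof <- rep(NA_real_, length(y))
  fold_auc <- numeric(0)
  for (k in sort(unique(fold_of))) {
    te <- fold_of == k
    inner_kk <- min(inner_k, min(table(y[!te])))
    gp <- select_grid_point(data[!te, , drop = FALSE], y[!te], groups[!te],
                            features, grid, inner_kk, derive_seed(seed, k))
    b <- ridge_logistic(x[!te, , drop = FALSE], y[!te], gp$lambda, gp$class_weight)
    oof[te] <- stats::plogis(drop(cbind(1, x[te, , drop = FALSE]) %*% b))
    if (length(unique(y[te])) == 2) fold_auc <- c(fold_auc, mw_auc(oof[te], y[te]))
  }
  gp_final <- select_grid_point(data, y, groups, features, grid,
                                min(inner_k, min(table(y))), derive_seed(seed, 0L))
  b <- ridge_logistic(x, y, gp_final$lambda, gp_final$class_weight)
  structure(list(
    intercept = unname(b[1]),
    coefficients = b[-1],
    features = features,
    hyperparameters = as.list(gp_final),
    cv_auc_mean = mean(fold_auc), cv_auc_sd = stats::sd(fold_auc),
    oof = tibble::tibble(patient_id = groups, fold = fold_of,
                         label = y, score = oof),
    fold_plan_seed = seed),
    class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model: %d features, CV AUC %.3f +/- %.3f, lambda = %g (%s)>\n",
              length(x$coefficients), x$cv_auc_mean, x$cv_auc_sd,
              x$hyperparameters$lambda, x$hyperparameters$class_weight))
  invisible(x)
}

#' Score new data with a fitted risk model
#'
#' @param object A `risk_model`.
#' @param newdata Data frame containing the model's feature columns (scaled
#'   with the discovery-set scaler).
#' @param ... Unused.
#' @return Numeric vector of risk-of-PD scores in (0, 1).
#' @export
predict.risk_model <- function(object, newdata, ...) {
  x <- as.matrix(tibble::as_tibble(newdata)[object$features])
  stats::plogis(drop(cbind(1, x) %*% c(object$intercept, object$coefficients)))
}

# -- published risk calculator -------------------------------------------------

#' Coefficients of the published risk calculator
#'
#' The four-variable logistic risk-of-progression calculator combining two
#' clinical covariates with two peritumoral (Ring) radiomic features.
#'
#' @return Named numeric vector: intercept, pack_years, n_met_sites,
#'   odcd_ring (`OD-CentroidDifference_RING`), radcentre_ring
#'   (`RadCentre_RING`).
#' @export
eq1_coefficients <- function() {
  c(intercept = -0.282, pack_years = -0.509, n_met_sites = 0.999,
    odcd_ring = -0.816, radcentre_ring = 1.148)
}

#' Published risk-of-progression calculator
#'
#' Evaluates the published four-variable risk formula. Under the `"literal"`
#' convention the printed formula is evaluated exactly as written:
#' `risk = 1 / (1 + exp(E))` with
#' `E = -0.282 - 0.509 PY + 0.999 M - 0.816 ODCD + 1.148 RC`.
#' Read literally this makes risk *decrease* with the number of metastatic
#' sites, which contradicts the reported clinical direction (PD patients
#' carry a higher metastatic burden); the `"conventional"` flag negates `E`
#' before the exponent (the standard logistic form `1/(1+exp(-E))`), which
#' restores that direction. Inputs are assumed to be on the `[-1, 1]`
#' discovery-set scale; the calculator never rescales.
#'
#' @param pack_years_scaled,n_met_sites_scaled,odcd_ring,radcentre_ring
#'   Scaled inputs (finite; vectorized).
#' @param convention `"literal"` (the printed formula) or `"conventional"`.
#'   If not supplied explicitly, `"literal"` is used with a warning.
#' @return Tibble with `risk` in (0, 1) and the `convention` used.
#' @examples
#' eq1_risk(0, 0, 0, 0, convention = "literal")$risk # 1/(1 + exp(-0.282))
#' @export
eq1_risk <- function(pack_years_scaled, n_met_sites_scaled, odcd_ring,
                     radcentre_ring, convention = c("literal", "conventional")) {
  if (missing(convention))
    rlang::warn(paste0(
      "eq1_risk(): using the literal printed formula, under which risk ",
      "decreases with the number of metastatic sites; pass convention = ",
      "\"conventional\" for the standard logistic sign"))
  convention <- match.arg(convention)
  inputs <- cbind(pack_years_scaled, n_met_sites_scaled, odcd_ring, radcentre_ring)
  if (!all(is.finite(inputs))) stop_field("inputs", "must be finite")
  b <- eq1_coefficients()
  e <- b["intercept"] + b["pack_years"] * pack_years_scaled +
    b["n_met_sites"] * n_met_sites_scaled + b["odcd_ring"] * odcd_ring +
    b["radcentre_ring"] * radcentre_ring
  risk <- if (convention == "literal") 1 / (1 + exp(e)) else 1 / (1 + exp(-e))
  tibble::tibble(risk = unname(risk), convention = convention)
}
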