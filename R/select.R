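# Feature selection: sequential forward selection under the one-in-five and
# delta-AUC > 0.03 rules, mRMR (difference form on quantile-binned features),
# and ReliefF. All three are deterministic for fixed input; every numeric
# tie breaks lexicographically by feature name.

#' Selection configuration
#'
#' @param max_features Signature size cap (the one-in-five rule: at most
#'   minority-class count / 5 predictors; 5 for a 27-patient minority class).
#' @param delta_auc_threshold Minimum cross-validated AUC improvement an
#'   additional feature must bring to enter the signature.
#' @param include_clinical Whether clinical covariates join the pool.
#' @param algorithm One of `"sfs"`, `"mrmr"`, `"relieff"`.
#' @param cv_folds Grouped CV folds used to evaluate candidate signatures.
#' @param n_bins Quantile bins for mutual-information estimation (mRMR).
#' @param n_neighbors ReliefF hits/misses per instance.
#' @param seed Integer seed for the fold split.
#' @return A `selection_config` list.
#' @export
selection_config <- function(max_features = 5L, delta_auc_threshold = 0.03,
                             include_clinical = TRUE, algorithm = "sfs",
                             cv_folds = 5L, n_bins = 8L, n_neighbors = 10L,
                             seed = 1L) {
  check_count(max_features, "max_features")
  if (delta_auc_threshold < 0) stop_field("delta_auc_threshold", "must be >= 0")
  algorithm <- match.arg(algorithm, c("sfs", "mrmr", "relieff"))
  structure(list(max_features = as.integer(max_features),
                 delta_auc_threshold = delta_auc_threshold,
                 include_clinical = isTRUE(include_clinical),
                 algorithm = algorithm, cv_folds = as.integer(cv_folds),
                 n_bins = as.integer(n_bins),
                 n_neighbors = as.integer(n_neighbors), seed = as.integer(seed)),
            class = "selection_config")
}

# logistic fit + prediction on plain matrices (fast path used inside CV)
logistic_scores <- function(x_train, y_train, x_test) {
  fit <- suppressWarnings(stats::glm.fit(cbind(1, x_train), y_train,
                                         family = stats::binomial()))
  b <- fit$coefficients
  b[is.na(b)] <- 0
  stats::plogis(drop(cbind(1, x_test) %*% b))
}

# grouped-CV AUC of a logistic model on the given feature columns.
# Returns per-fold slice-level AUCs plus pooled out-of-fold scores.
cv_auc_logistic <- function(data, y, groups, features, plan) {
  x <- as.matrix(data[features])
  fold_of <- plan$fold[match(groups, plan$patient_id)]
  ks <- sort(unique(fold_of))
  fold_auc <- numeric(0)
  oof <- rep(NA_real_, length(y))
  for (k in ks) {
    te <- fold_of == k
    if (length(unique(y[!te])) < 2) next
    sc <- logistic_scores(x[!te, , drop = FALSE], y[!te], x[te, , drop = FALSE])
    oof[te] <- sc
    if (length(unique(y[te])) == 2) fold_auc <- c(fold_auc, mw_auc(sc, y[te]))
  }
  list(mean = mean(fold_auc), sd = stats::sd(fold_auc), fold_auc = fold_auc, oof = oof)
}

new_signature <- function(features, trace, algorithm, include_clinical, config,
                          cv_mean, cv_sd) {
  structure(list(features = features, auc_trace = trace, algorithm = algorithm,
                 include_clinical = include_clinical, config = config,
                 cv_auc_mean = cv_mean, cv_auc_sd = cv_sd),
            class = "pr_signature")
}

#' @export
print.pr_signature <- function(x, ...) {
  cat(sprintf("<signature [%s%s]: %s | CV AUC %.3f +/- %.3f>\n", x$algorithm,
              if (x$include_clinical) "+clinical" else "",
              paste(x$features, collapse = ", "),
              x$cv_auc_mean, x$cv_auc_sd))
  invisible(x)
}

#' Sequential forward feature selection
#'
#' Greedy forward selection maximizing grouped-cross-validated AUC of a
#' logistic model. The first feature is the best single predictor; each
#' further feature must improve the mean CV AUC by more than
#' `delta_auc_threshold` (default 0.03), and the signature is capped at
#' `max_features` (default 5, the one-in-five rule).
#'
#' @param data Data frame of candidate feature columns (scaled).
#' @param labels Binary labels, one per row (PD positive).
#' @param groups Patient id per row; CV folds never split a patient.
#' @param pool Candidate feature names (default: all numeric columns).
#' @param config A [selection_config()].
#' @return A `pr_signature` with the ordered features and per-step AUC trace.
#' @export
sfs_select <- function(data, labels, groups, pool = NULL,
                       config = selection_config()) {
  data <- tibble::as_tibble(data)
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) stop_field("labels", "both classes must be present")
  if (is.null(pool)) pool <- names(data)[vapply(data, is.numeric, logical(1))]
  if (length(pool) < 2) stop_field("pool", "need at least 2 candidate features")
  plan <- make_fold_plan(groups, y, k = config$cv_folds, seed = config$seed)
  selected <- character()
  trace <- numeric()
  current <- 0.5
  last_sd <- NA_real_
  repeat {
    if (length(selected) >= config$max_features) break
    cand <- setdiff(pool, selected)
    if (!length(cand)) break
    res <- purrr::map(cand, function(f)
      cv_auc_logistic(data, y, groups, c(selected, f), plan))
    means <- vapply(res, `[[`, numeric(1), "mean")
    best <- order(-means, cand)[1]        # ties: lexicographically first name
    if (length(selected) > 0 && means[best] - current <= config$delta_auc_threshold)
      break
    selected <- c(selected, cand[best])
    current <- means[best]
    last_sd <- res[[best]]$sd
    trace <- c(trace, current)
  }
  new_signature(selected, trace, "sfs", config$include_clinical, config,
                current, last_sd)
}

# -- mutual information on discretized features --------------------------------

quantile_bin <- function(x, n_bins) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                               names = FALSE, type = 7))
  if (length(br) < 2) return(rep(1L, length(x)))
  as.integer(cut(x, br, include.lowest = TRUE))
}

discrete_mi <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' Minimum-redundancy maximum-relevance feature ranking
#'
#' Greedy difference-form mRMR: the first feature maximizes mutual
#' information with the labels; each next feature maximizes
#' `MI(f; y) - mean(MI(f; selected))`. MI is estimated on quantile-binned
#' features (8 bins by default).
#'
#' @inheritParams sfs_select
#' @param k Number of features to rank.
#' @return A `pr_signature` with the ranked features (trimmed to a model
#'   signature by [build_signature_menu()]; here `auc_trace` is the mRMR
#'   objective at each step).
#' @export
mrmr_select <- function(data, labels, k, pool = NULL,
                        config = selection_config(algorithm = "mrmr")) {
  data <- tibble::as_tibble(data)
  y <- as_binary_labels(labels)
  if (is.null(pool)) pool <- names(data)[vapply(data, is.numeric, logical(1))]
  k <- check_count(k, "k")
  if (k > length(pool)) stop_field("k", "exceeds the candidate pool size")
  binned <- purrr::map(stats::setNames(pool, pool),
                       function(f) quantile_bin(data[[f]], config$n_bins))
  rel <- vapply(pool, function(f) discrete_mi(binned[[f]], y), numeric(1))
  selected <- character(); obj <- numeric()
  red_sum <- stats::setNames(numeric(length(pool)), pool)
  for (step in seq_len(k)) {
    cand <- setdiff(pool, selected)
    score <- rel[cand] - if (step == 1) 0 else red_sum[cand] / (step - 1)
    best <- cand[order(-score, cand)[1]]
    selected <- c(selected, best)
    obj <- c(obj, score[[best]])
    if (step < k)
      for (f in setdiff(pool, selected))
        red_sum[f] <- red_sum[f] + discrete_mi(binned[[f]], binned[[best]])
  }
  new_signature(selected, obj, "mrmr", config$include_clinical, config,
                NA_real_, NA_real_)
}

#' ReliefF feature weighting
#'
#' Deterministic ReliefF over all instances: for each row, the
#' `n_neighbors` nearest hits and nearest misses (Manhattan distance on
#' range-normalized features) decrease and increase each feature's weight by
#' its normalized difference; miss contributions are weighted by class
#' priors. Top-`k` features by weight are returned (ties lexicographic).
#'
#' @inheritParams mrmr_select
#' @return A `pr_signature`; `auc_trace` holds the ReliefF weights of the
#'   ranked features.
#' @export
relieff_select <- function(data, labels, k, pool = NULL,
                           config = selection_config(algorithm = "relieff")) {
  data <- tibble::as_tibble(data)
  y <- as_binary_labels(labels)
  if (is.null(pool)) pool <- names(data)[vapply(data, is.numeric, logical(1))]
  k <- check_count(k, "k")
  if (k > length(pool)) stop_field("k", "exceeds the candidate pool size")
  nn <- config$n_neighbors
  if (nn >= min(table(y))) stop_field("n_neighbors", "must be below the smallest class size")
  x <- as.matrix(data[pool])
  rng <- apply(x, 2, function(cc) diff(range(cc)))
  rng[rng <= 0] <- 1
  xs <- sweep(x, 2, rng, "/")
  m <- nrow(xs)
  dmat <- as.matrix(stats::dist(xs, method = "manhattan"))
  diag(dmat) <- Inf
  prior <- table(y) / m
  w <- stats::setNames(numeric(length(pool)), pool)
  for (i in seq_len(m)) {
    same <- which(y == y[i]); same <- same[same != i]
    diff_ <- which(y != y[i])
    hits <- same[order(dmat[i, same])][seq_len(min(nn, length(same)))]
    miss <- diff_[order(dmat[i, diff_])][seq_len(min(nn, length(diff_)))]
    dh <- abs(sweep(xs[hits, , drop = FALSE], 2, xs[i, ]))
    dm <- abs(sweep(xs[miss, , drop = FALSE], 2, xs[i, ]))
    pm <- prior[as.character(y[miss[1]])] / (1 - prior[as.character(y[i])])
    w <- w - colMeans(dh) / m + as.numeric(pm) * colMeans(dm) / m
  }
  ord <- order(-w, pool)
  ranked <- pool[ord][seq_len(k)]
  new_signature(ranked, unname(w[ranked]), "relieff", config$include_clinical,
                config, NA_real_, NA_real_)
}

# trim a ranked feature list to a model signature: keep adding in rank order
# while the grouped-CV AUC improves by more than the delta-AUC threshold
trim_ranked <- function(sig, data, y, groups, config) {
  plan <- make_fold_plan(groups, y, k = config$cv_folds, seed = config$seed)
  kept <- character(); trace <- numeric(); current <- 0.5; last_sd <- NA_real_
  for (f in sig$features) {
    if (length(kept) >= config$max_features) break
    res <- cv_auc_logistic(data, y, groups, c(kept, f), plan)
    if (length(kept) > 0 && res$mean - current <= config$delta_auc_threshold) break
    kept <- c(kept, f); current <- res$mean; last_sd <- res$sd
    trace <- c(trace, current)
  }
  new_signature(kept, trace, sig$algorithm, config$include_clinical, config,
                current, last_sd)
}

#' Build the six candidate radiomic signatures
#'
#' Runs SFS, mRMR and ReliefF each with and without the clinical covariates
#' in the pool, yielding six candidate signatures. mRMR and ReliefF rankings
#' are trimmed to model signatures by the same delta-AUC > 0.03 /
#' max-5-features rules used by SFS. Each signature carries its grouped-CV
#' AUC mean and SD; the best signature is the highest mean with ties broken
#' toward the lower SD.
#'
#' @param data Data frame of scaled features (radiomic + clinical columns).
#' @param labels Binary labels per row.
#' @param groups Patient id per row.
#' @param radiomic,clinical Column names of the two pools.
#' @param config A [selection_config()]; `algorithm`/`include_clinical` are
#'   set per menu entry.
#' @return A tibble with one row per signature: `algorithm`,
#'   `include_clinical`, `n_features`, `cv_auc_mean`, `cv_auc_sd`, and a
#'   `signature` list-column of `pr_signature` objects.
#' @export
build_signature_menu <- function(data, labels, groups, radiomic, clinical,
                                 config = selection_config()) {
  y <- as_binary_labels(labels)
  entries <- tidyr::expand_grid(algorithm = c("sfs", "mrmr", "relieff"),
                                include_clinical = c(TRUE, FALSE))
  sigs <- purrr::pmap(entries, function(algorithm, include_clinical) {
    cfg <- config
    cfg$algorithm <- algorithm
    cfg$include_clinical <- include_clinical
    pool <- if (include_clinical) c(radiomic, clinical) else radiomic
    sig <- switch(algorithm,
      sfs = sfs_select(data, y, groups, pool = pool, config = cfg),
      mrmr = trim_ranked(mrmr_select(data, y, min(cfg$max_features * 2, length(pool)),
                                     pool = pool, config = cfg),
                         data, y, groups, cfg),
      relieff = trim_ranked(relieff_select(data, y, min(cfg$max_features * 2, length(pool)),
                                           pool = pool, config = cfg),
                            data, y, groups, cfg))
    sig
  })
  entries |>
    dplyr::mutate(
      n_features = vapply(sigs, function(s) length(s$features), integer(1)),
      cv_auc_mean = vapply(sigs, `[[`, numeric(1), "cv_auc_mean"),
      cv_auc_sd = vapply(sigs, `[[`, numeric(1), "cv_auc_sd"),
      features = purrr::map(sigs, "features"),
      signature = sigs)
}

#' Pick the best signature from a menu
#'
#' Highest grouped-CV mean AUC; ties break toward the lower CV SD.
#'
#' @param menu Output of [build_signature_menu()].
#' @return The winning `pr_signature`.
#' @export
pick_signature <- function(menu) {
  ord <- order(-menu$cv_auc_mean, menu$cv_auc_sd)
  menu$signature[[ord[1]]]
}
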