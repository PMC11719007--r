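# End-to-end orchestration: simulate/ingest -> segment -> extract ->
# preprocess -> select -> train -> optimize thresholds -> evaluate ->
# survival. The discovery/external split tags every row; externally-tagged
# rows are structurally excluded from every fit and threshold optimization
# and a runtime guard re-checks this before each fitting stage.

CLINICAL_NUMERIC <- c("age", "pack_years", "n_met_sites")
CLINICAL_CATEGORICAL <- c("sex", "smoking", "ecog")

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run. Defaults are the published
#' operating conventions: soft-tissue handling of already-normalized
#' synthetic volumes (no re-windowing), 2 px edge, 6 mm ring, the
#' var/AUC/Spearman first-pass filter, six-signature menu (3 algorithms x
#' with/without clinical), ridge logistic grid, and threshold optimization
#' on the discovery out-of-fold scores.
#'
#' @param cohort A [cohort_spec()] describing the synthetic cohort to run
#'   on, or `NULL` when `cohort_data` is supplied to [run_pipeline()].
#' @param external_fraction Fraction of patients held out as the external
#'   test set (class-stratified).
#' @param window A [window_spec()] applied to raw HU volumes, or `NULL` for
#'   volumes already normalized to `[0, 1]`.
#' @param edge_px,ring_mm Mask geometry.
#' @param filter_params List of [first_pass_filter()] thresholds.
#' @param selection A [selection_config()].
#' @param algorithms Selection algorithms to include in the menu.
#' @param grid Hyperparameter grid from [lr_grid()].
#' @param thresholds A fixed [threshold_set()], or `NULL` to optimize X, Y,
#'   Z on the discovery set.
#' @param seed Master seed for the split and fold plans.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            external_fraction = 0.15,
                            window = NULL,
                            edge_px = 2L, ring_mm = 6,
                            filter_params = list(var_tol = 1e-8, auc_min = 0.55,
                                                 rho_max = 0.95),
                            selection = selection_config(),
                            algorithms = c("sfs", "mrmr", "relieff"),
                            grid = lr_grid(),
                            thresholds = NULL,
                            seed = 1L) {
  check_fraction(external_fraction, "external_fraction")
  structure(list(cohort = cohort, external_fraction = external_fraction,
                 window = window, edge_px = edge_px, ring_mm = ring_mm,
                 filter_params = filter_params, selection = selection,
                 algorithms = match.arg(algorithms, c("sfs", "mrmr", "relieff"),
                                        several.ok = TRUE),
                 grid = grid, thresholds = thresholds, seed = as.integer(seed)),
            class = "pipeline_config")
}

assert_discovery_only <- function(split, stage) {
  if (any(split == "external"))
    rlang::abort(paste0("leakage guard: externally-tagged rows reached the ",
                        stage, " stage"), class = "perirad_leakage_error")
  invisible(TRUE)
}

# stratified patient-level discovery/external split
split_patients <- function(clinical, external_fraction, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  clinical |>
    dplyr::group_by(.data$response) |>
    dplyr::mutate(split = ifelse(
      seq_len(dplyr::n()) %in%
        sample(dplyr::n(), round(dplyr::n() * external_fraction)),
      "external", "discovery")) |>
    dplyr::ungroup() |>
    dplyr::select("patient_id", "split")
}

#' Run the full risk-modelling pipeline
#'
#' Executes every stage on a synthetic cohort (or a pre-built `ct_cohort`):
#' segmentation from seed annotations, mask-triplet construction, feature
#' extraction over up to five slices x three regions, one-hot encoding and
#' discovery-learned scaling, first-pass filtering, the signature menu,
#' nested-CV logistic training of the winning signature, frequency-threshold
#' optimization on discovery out-of-fold scores, external evaluation at the
#' frozen thresholds, and survival comparison of the predicted risk groups.
#'
#' @param config A [pipeline_config()].
#' @param cohort_data Optional `ct_cohort` (overrides `config$cohort`).
#' @return A `pd_risk_run` with the fitted artifacts and a `metrics` tibble.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort_data = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- cohort_data %||% generate_cohort(config$cohort)

  ## -- split ------------------------------------------------------------------
  split <- split_patients(cohort$clinical, config$external_fraction,
                          derive_seed(config$seed, 101L))
  clinical <- dplyr::left_join(cohort$clinical, split, by = "patient_id")

  ## -- window/normalize, segment, extract ------------------------------------
  volumes <- cohort$volumes
  if (!is.null(config$window))
    volumes <- purrr::map(volumes, window_normalize, window = config$window)
  seg <- segment_cohort(volumes, cohort$annotations,
                        edge_width_px = config$edge_px, ring_mm = config$ring_mm)
  feats_long <- seg |>
    dplyr::group_by(.data$patient_id, .data$lesion_id) |>
    dplyr::group_modify(function(df, key) {
      trips <- stats::setNames(df$masks, df$slice_index)
      extract_lesion_stack(volumes[[key$patient_id]], trips)
    }) |>
    dplyr::ungroup()
  wide <- features_wide(feats_long)

  ## -- join clinical, one-hot, scale ------------------------------------------
  enc <- one_hot(clinical, cols = CLINICAL_CATEGORICAL)
  data_all <- dplyr::inner_join(wide, enc, by = "patient_id")
  radiomic_cols <- setdiff(names(wide), c("patient_id", "lesion_id", "slice_index"))
  clinical_cols <- c(CLINICAL_NUMERIC,
                     grep(paste0("^(", paste(CLINICAL_CATEGORICAL, collapse = "|"), ")_"),
                          names(enc), value = TRUE))
  feature_cols <- c(radiomic_cols, clinical_cols)
  disc <- dplyr::filter(data_all, .data$split == "discovery")
  assert_discovery_only(disc$split, "scaler fit")
  scaler <- fit_scaler(disc, cols = feature_cols)
  data_all <- apply_scaler(data_all, scaler)
  disc <- dplyr::filter(data_all, .data$split == "discovery")
  ext <- dplyr::filter(data_all, .data$split == "external")

  ## -- first-pass filter -------------------------------------------------------
  fp <- config$filter_params
  filt <- first_pass_filter(disc[feature_cols], disc$response,
                            clinical = clinical_cols,
                            var_tol = fp$var_tol, auc_min = fp$auc_min,
                            rho_max = fp$rho_max)
  radiomic_pool <- setdiff(filt$retained, clinical_cols)

  ## -- signature menu ----------------------------------------------------------
  sel_cfg <- config$selection
  sel_cfg$seed <- derive_seed(config$seed, 202L)
  menu <- build_signature_menu(disc, disc$response, disc$patient_id,
                               radiomic = radiomic_pool, clinical = clinical_cols,
                               config = sel_cfg) |>
    dplyr::filter(.data$algorithm %in% config$algorithms)
  best_sig <- pick_signature(menu)

  ## -- nested-CV model ---------------------------------------------------------
  plan <- make_fold_plan(disc$patient_id, disc$response, k = 5L,
                         seed = derive_seed(config$seed, 303L))
  model <- fit_lr_nested(disc, disc$response, disc$patient_id,
                         features = best_sig$features,
                         fold_plan = plan, grid = config$grid)

  ## -- thresholds on discovery out-of-fold scores ------------------------------
  disc_scores <- tibble::tibble(patient_id = disc$patient_id,
                                lesion_id = disc$lesion_id,
                                score = model$oof$score,
                                label = disc$response,
                                split = disc$split)
  thresholds <- config$thresholds %||% optimize_thresholds(disc_scores)

  ## -- evaluate both splits at the frozen thresholds ---------------------------
  eval_split <- function(df, scores) {
    sc <- tibble::tibble(patient_id = df$patient_id, lesion_id = df$lesion_id,
                         score = scores)
    cls <- suppressWarnings(classify_hierarchy(sc, thresholds))
    truth <- dplyr::distinct(df, .data$patient_id, .data$response)
    pat <- dplyr::left_join(cls$patients, truth, by = "patient_id")
    list(cls = cls, pat = pat,
         confusion = confusion(pat$label, pat$response),
         auc = if (length(unique(pat$response)) == 2)
           roc_auc(pat$patient_score, pat$response)$auc else NA_real_)
  }
  disc_eval <- eval_split(disc, model$oof$score)
  ext_eval <- if (nrow(ext)) eval_split(ext, predict(model, ext)) else NULL

  ## -- survival by predicted risk group ----------------------------------------
  risk_groups <- dplyr::bind_rows(
    disc_eval$pat |> dplyr::mutate(split = "discovery"),
    if (!is.null(ext_eval)) ext_eval$pat |> dplyr::mutate(split = "external")) |>
    dplyr::transmute(.data$patient_id, .data$split,
                     risk_group = ifelse(.data$label == "PD", "high", "low"))
  surv_records <- clinical |>
    dplyr::inner_join(risk_groups, by = c("patient_id", "split")) |>
    tidyr::pivot_longer(cols = c("pfs_months", "os_months"),
                        names_to = "endpoint", values_to = "time") |>
    dplyr::mutate(endpoint = toupper(sub("_months", "", .data$endpoint)),
                  event = ifelse(.data$endpoint == "PFS", .data$pfs_event,
                                 .data$os_event)) |>
    dplyr::select("patient_id", "split", "risk_group", "endpoint", "time", "event")
  surv_tests <- surv_records |>
    dplyr::group_by(.data$split, .data$endpoint) |>
    dplyr::group_modify(function(df, key) {
      if (length(unique(df$risk_group)) < 2 || sum(df$event) == 0)
        return(tibble::tibble(chi_square = NA_real_, p_value = NA_real_))
      logrank_test(df)[c("chi_square", "p_value")]
    }) |>
    dplyr::ungroup()

  metrics <- dplyr::bind_rows(
    tibble::tibble(split = "discovery", auc = disc_eval$auc,
                   sn = disc_eval$confusion$sn, sp = disc_eval$confusion$sp,
                   f1 = disc_eval$confusion$f1),
    if (!is.null(ext_eval))
      tibble::tibble(split = "external", auc = ext_eval$auc,
                     sn = ext_eval$confusion$sn, sp = ext_eval$confusion$sp,
                     f1 = ext_eval$confusion$f1))

  structure(list(config = config, cohort = cohort, split = split,
                 scaler = scaler, filter_report = filt, menu = menu,
                 signature = best_sig, model = model, thresholds = thresholds,
                 discovery = disc_eval, external = ext_eval,
                 survival = list(records = surv_records, tests = surv_tests),
                 metrics = metrics),
            class = "pd_risk_run")
}

#' @export
print.pd_risk_run <- function(x, ...) {
  cat("<pd_risk_run>\n")
  cat("  signature:", paste(x$signature$features, collapse = ", "), "\n")
  cat(sprintf("  thresholds: X = %.3f, Y = %d, Z = %d\n",
              x$thresholds$slice_cutoff, x$thresholds$slice_count_cutoff,
              x$thresholds$lesion_count_cutoff))
  print(x$metrics)
  invisible(x)
}
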