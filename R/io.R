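# Disk interfaces: NIfTI volumes, CSV annotation/clinical/feature tables,
# JSON ground truth, thresholds and models. Masks are stored in JSON as
# run-length encodings of the column-major pixel vector.

rle_encode_mask <- function(mask) {
  r <- rle(as.logical(mask))
  list(dim = dim(mask), first = r$values[1], lengths = r$lengths)
}

rle_decode_mask <- function(enc) {
  vals <- rep(rep(c(enc$first, !enc$first), length.out = length(enc$lengths)),
              enc$lengths)
  matrix(vals, enc$dim[1], enc$dim[2])
}

#' Write a synthetic cohort to disk
#'
#' Volumes as gzipped NIfTI, annotations and clinical table as CSV, ground
#' truth (true classes + run-length-encoded reference masks) as JSON.
#'
#' @param cohort A `ct_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "volumes"), recursive = TRUE, showWarnings = FALSE)
  for (pid in names(cohort$volumes)) {
    vol <- cohort$volumes[[pid]]
    img <- aperm(vol$voxels, c(3, 2, 1))   # NIfTI x, y, z
    RNifti::writeNifti(RNifti::asNifti(img, pixdim = rev(vol$spacing_mm)),
                       file.path(dir, "volumes", paste0(pid, ".nii.gz")))
  }
  readr::write_csv(cohort$annotations, file.path(dir, "annotations.csv"))
  readr::write_csv(cohort$clinical, file.path(dir, "clinical.csv"))
  gt <- cohort$ground_truth
  json <- list(truth = gt$truth,
               masks = purrr::map(gt$masks, function(les)
                 purrr::map(les, function(stack)
                   purrr::map(stack, rle_encode_mask))))
  jsonlite::write_json(json, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory produced by [write_cohort()].
#' @return A `ct_cohort`.
#' @export
read_cohort <- function(dir) {
  files <- list.files(file.path(dir, "volumes"), pattern = "\\.nii(\\.gz)?$",
                      full.names = TRUE)
  volumes <- stats::setNames(purrr::map(files, function(f) {
    img <- RNifti::readNifti(f)
    pd <- RNifti::pixdim(img)
    ct_volume(aperm(array(as.numeric(img), dim(img)), c(3, 2, 1)),
              spacing_mm = rev(pd[seq_len(3)]),
              patient_id = sub("\\.nii(\\.gz)?$", "", basename(f)),
              normalized = TRUE)
  }), sub("\\.nii(\\.gz)?$", "", basename(files)))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE, simplifyDataFrame = TRUE,
                            simplifyMatrix = FALSE)
  masks <- purrr::map(gt$masks, function(les)
    purrr::map(les, function(stack) purrr::map(stack, function(enc)
      rle_decode_mask(list(dim = unlist(enc$dim), first = enc$first,
                           lengths = unlist(enc$lengths))))))
  structure(list(volumes = volumes,
                 annotations = readr::read_csv(file.path(dir, "annotations.csv"),
                                               show_col_types = FALSE),
                 clinical = readr::read_csv(file.path(dir, "clinical.csv"),
                                            show_col_types = FALSE),
                 ground_truth = list(truth = tibble::as_tibble(gt$truth),
                                     masks = masks, spec = NULL)),
            class = "ct_cohort")
}

#' Serialize / restore a threshold set
#'
#' @param thresholds A [threshold_set()].
#' @param path JSON file path.
#' @return [write_thresholds()] returns `path`; [read_thresholds()] a
#'   `threshold_set`.
#' @export
write_thresholds <- function(thresholds, path) {
  jsonlite::write_json(unclass(thresholds), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  threshold_set(x$slice_cutoff, x$slice_count_cutoff, x$lesion_count_cutoff)
}

#' Serialize / restore a fitted risk model
#'
#' @param model A `risk_model`.
#' @param path JSON file path.
#' @return [write_risk_model()] returns `path`; [read_risk_model()] a
#'   `risk_model` (without the out-of-fold table).
#' @export
write_risk_model <- function(model, path) {
  jsonlite::write_json(list(intercept = model$intercept,
                            coefficients = as.list(model$coefficients),
                            features = model$features,
                            hyperparameters = model$hyperparameters,
                            cv_auc_mean = model$cv_auc_mean,
                            cv_auc_sd = model$cv_auc_sd,
                            fold_plan_seed = model$fold_plan_seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_risk_model
#' @export
read_risk_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(intercept = x$intercept,
                 coefficients = unlist(x$coefficients),
                 features = x$features,
                 hyperparameters = as.list(x$hyperparameters),
                 cv_auc_mean = x$cv_auc_mean, cv_auc_sd = x$cv_auc_sd,
                 oof = NULL, fold_plan_seed = x$fold_plan_seed),
            class = "risk_model")
}
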