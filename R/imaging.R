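#' CT display window specification
#'
#' A display window in Hounsfield units, used to clip and normalize raw CT
#' intensities to `[0, 1]` before feature extraction. The default is the
#' soft-tissue window (centre 40 HU, width 400 HU) conventionally used when
#' annotating lung lesions.
#'
#' @param center_hu Window centre in HU.
#' @param width_hu Window width in HU; must be positive.
#' @return An object of class `window_spec`.
#' @examples
#' window_spec()           # soft tissue: C = 40, W = 400
#' window_spec(-600, 1500) # lung window
#' @export
window_spec <- function(center_hu = 40, width_hu = 400) {
  if (!is.numeric(center_hu) || length(center_hu) != 1 || !is.finite(center_hu))
    stop_field("center_hu", "must be a single finite number")
  check_positive(width_hu, "width_hu")
  structure(list(center_hu = center_hu, width_hu = width_hu), class = "window_spec")
}

#' Window and normalize a CT volume
#'
#' Clips intensities to the display window and rescales linearly to
#' `[0, 1]`: `x' = clip((hu - (C - W/2)) / W, 0, 1)`. Shape and spacing
#' metadata are preserved. The map is monotone non-decreasing in HU.
#'
#' @param volume A numeric array (2-D slice or 3-D volume) of HU values, or a
#'   `ct_volume` built by [ct_volume()].
#' @param window A [window_spec()].
#' @return Same container as the input with voxels in `[0, 1]`.
#' @export
window_normalize <- function(volume, window = window_spec()) {
  stopifnot(inherits(window, "window_spec"))
  vox <- if (inherits(volume, "ct_volume")) volume$voxels else volume
  if (!all(is.finite(vox))) stop_field("volume", "voxel values must be finite")
  lo <- window$center_hu - window$width_hu / 2
  out <- pmin(pmax((vox - lo) / window$width_hu, 0), 1)
  dim(out) <- dim(vox)
  if (inherits(volume, "ct_volume")) {
    volume$voxels <- out
    volume$normalized <- TRUE
    volume
  } else out
}

#' CT volume container
#'
#' @param voxels 3-D numeric array indexed `[slice, row, col]` (or a 2-D
#'   matrix, promoted to a single-slice volume).
#' @param spacing_mm Numeric length-3 `(z, y, x)` voxel spacing in mm.
#' @param patient_id Identifier string.
#' @param normalized Whether voxels are already on the `[0, 1]` scale.
#' @return A `ct_volume` object.
#' @export
ct_volume <- function(voxels, spacing_mm = c(5, 0.75, 0.75), patient_id = "P000",
                      normalized = FALSE) {
  if (is.matrix(voxels)) voxels <- array(voxels, c(1L, dim(voxels)))
  stopifnot(length(dim(voxels)) == 3)
  if (!all(is.finite(voxels))) stop_field("voxels", "must be finite")
  if (length(spacing_mm) != 3 || any(spacing_mm <= 0))
    stop_field("spacing_mm", "must be three positive numbers (z, y, x)")
  structure(list(voxels = voxels, spacing_mm = as.numeric(spacing_mm),
                 patient_id = patient_id, normalized = isTRUE(normalized)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume %s: %d slices x %d x %d px, spacing %.2f/%.2f/%.2f mm%s>\n",
              x$patient_id, d[1], d[2], d[3],
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3],
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

# Otsu threshold on a vector of [0,1] intensities; 256-bin histogram,
# ties resolved toward the lower threshold.
otsu_threshold <- function(x, n_bins = 256L) {
  h <- tabulate(pmin(pmax(floor(x * n_bins) + 1L, 1L), n_bins), nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(n_bins) - 0.5) / n_bins)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)          # which.max returns the FIRST max: lower tie
  k / n_bins
}

#' Segment one lesion slice from a seed point
#'
#' Computes an Otsu threshold inside a square region of interest around the
#' seed, keeps the 8-connected supra-threshold component containing the seed,
#' and fills interior holes. Operating locally (not on the whole slice) keeps
#' the threshold from being dominated by air and bone.
#'
#' @param image 2-D numeric matrix, normalized intensities in `[0, 1]`.
#' @param seed `(row, col)` 0-based seed coordinates inside the lesion.
#' @param roi_halfwidth_px Half-width of the square ROI around the seed, px.
#' @param variance_tol ROIs with intensity variance below this are rejected
#'   as degenerate (no bimodal structure to threshold).
#' @return Logical matrix of the image's shape: the Core mask.
#' @export
segment_lesion_slice <- function(image, seed, roi_halfwidth_px = 20L,
                                 variance_tol = 1e-6) {
  stopifnot(is.matrix(image))
  nr <- nrow(image); nc <- ncol(image)
  sr <- seed[1] + 1L; sc <- seed[2] + 1L  # to 1-based
  if (sr < 1 || sr > nr || sc < 1 || sc > nc)
    stop_field("seed", "must lie inside the image")
  hw <- check_count(roi_halfwidth_px, "roi_halfwidth_px")
  r0 <- max(1L, sr - hw); r1 <- min(nr, sr + hw)
  c0 <- max(1L, sc - hw); c1 <- min(nc, sc + hw)
  roi <- image[r0:r1, c0:c1]
  if (stats::var(as.vector(roi)) < variance_tol)
    rlang::abort("degenerate ROI: intensity variance below tolerance",
                 class = "perirad_degenerate_roi")
  thr <- otsu_threshold(as.vector(roi))
  if (image[sr, sc] <= thr)
    rlang::abort("seed outside lesion: seed intensity falls below the Otsu threshold",
                 class = "perirad_seed_outside")
  fg <- matrix(0, nr, nc)
  fg[r0:r1, c0:c1] <- (roi > thr) * 1
  lab <- EBImage::bwlabel(fg)
  comp <- lab[sr, sc]
  mask <- (lab == comp) * 1
  mask <- EBImage::fillHull(mask)
  mask <- matrix(as.numeric(mask) > 0, nr, nc)
  if (!any(mask)) rlang::abort("empty mask after segmentation")
  mask
}

# Euclidean distance (px) of every pixel to the nearest TRUE pixel of `mask`.
dist_to_mask <- function(mask) {
  d <- EBImage::distmap(1 - mask, metric = "euclidean")
  matrix(as.numeric(d), nrow(mask), ncol(mask))
}

# dilation as distance-transform thresholding: pixels within `w` px of mask
dilate_mask <- function(mask, w) {
  if (w <= 0) return(mask)
  mask | (dist_to_mask(mask) <= w + 1e-9)
}

#' Ring width in pixels for a physical target
#'
#' Converts a physical peritumoral ring width (default 6 mm) into pixels for
#' the given in-plane spacing; with no spacing the conventional 8 px is used
#' (6 mm at 0.75 mm/px).
#'
#' @param spacing_mm In-plane pixel spacing (mm/px), or `NULL`.
#' @param target_mm Physical ring width in mm.
#' @return Integer pixel width.
#' @examples
#' ring_width_px(0.75) # 8
#' @export
ring_width_px <- function(spacing_mm = NULL, target_mm = 6) {
  if (is.null(spacing_mm)) return(8L)
  check_positive(spacing_mm, "spacing_mm")
  max(1L, as.integer(round(target_mm / spacing_mm)))
}

#' Build the Core / Core-Plus-Edge / Ring mask triplet
#'
#' From a binary Core mask, Core-Plus-Edge is the morphological dilation of
#' the core by `edge_width_px` and Ring is the dilation of Core-Plus-Edge by
#' `ring_width_px` minus Core-Plus-Edge, i.e. an annulus of surrounding
#' parenchyma. Dilation is Euclidean distance-transform thresholding with a
#' disk structuring element, so
#' `|core_plus_edge| + |ring| = |dilate(core, edge + ring)|` holds exactly
#' when no border clipping occurs. An optional lung mask restricts the ring
#' to parenchyma.
#'
#' @param core Logical matrix, nonempty lesion core.
#' @param edge_width_px Width of the edge transition band, px.
#' @param ring_width_px Width of the peritumoral ring, px (8 px is about
#'   6 mm at typical in-plane spacing).
#' @param lung_mask Optional logical matrix; when given, the ring is
#'   intersected with it.
#' @return A `mask_triplet`: list with `core`, `core_plus_edge`, `ring`
#'   logical matrices plus the widths used.
#' @export
build_mask_triplet <- function(core, edge_width_px = 2L, ring_width_px = 8L,
                               lung_mask = NULL) {
  stopifnot(is.matrix(core))
  core <- core > 0
  if (!any(core)) stop_field("core", "mask must be nonempty")
  edge_width_px <- check_count(edge_width_px, "edge_width_px", min = 0L)
  ring_width_px <- check_count(ring_width_px, "ring_width_px", min = 1L)
  d <- dist_to_mask(core)
  cpe <- core | (d <= edge_width_px + 1e-9)
  ring <- !cpe & (d <= edge_width_px + ring_width_px + 1e-9)
  if (!is.null(lung_mask)) ring <- ring & (lung_mask > 0)
  if (!any(ring))
    rlang::abort("lesion at image border: ring is empty after clipping",
                 class = "perirad_border_lesion")
  structure(list(core = core, core_plus_edge = cpe, ring = ring,
                 edge_width_px = edge_width_px, ring_width_px = ring_width_px),
            class = "mask_triplet")
}

#' @export
print.mask_triplet <- function(x, ...) {
  cat(sprintf("<mask_triplet: core %d px, core+edge %d px, ring %d px (edge %d, ring %d px wide)>\n",
              sum(x$core), sum(x$core_plus_edge), sum(x$ring),
              x$edge_width_px, x$ring_width_px))
  invisible(x)
}

#' Select up to five axial slices around the central slice
#'
#' Returns the central slice plus up to two cranial and two caudal steps,
#' intersected with the lesion's slice extent (and the volume bounds), so a
#' lesion contributes at most five axial slices of pseudo-volumetric data.
#'
#' @param extent Integer length-2: first and last slice index of the lesion
#'   (0-based, inclusive).
#' @param central Central slice index (largest tumour area), 0-based.
#' @param n_slices Optional total number of slices in the volume, for bounds.
#' @return Sorted integer vector of 0-based slice indices, length 1-5.
#' @examples
#' select_slices(c(10, 20), 15) # 13:17
#' @export
select_slices <- function(extent, central, n_slices = NULL) {
  stopifnot(length(extent) == 2, extent[1] <= extent[2])
  if (central < extent[1] || central > extent[2])
    stop_field("central", "must lie within the lesion extent")
  idx <- (central - 2L):(central + 2L)
  idx <- idx[idx >= extent[1] & idx <= extent[2] & idx >= 0L]
  if (!is.null(n_slices)) idx <- idx[idx <= n_slices - 1L]
  sort(as.integer(idx))
}

#' Segment a cohort's lesions and build mask triplets
#'
#' Convenience driver over [segment_lesion_slice()], [select_slices()] and
#' [build_mask_triplet()]: for every annotated lesion, selects the axial
#' slices and produces one mask triplet per slice.
#'
#' @param volumes Named list of `ct_volume` objects (names = patient ids),
#'   voxels on the normalized `[0, 1]` scale.
#' @param annotations Tibble with columns `patient_id`, `lesion_id`,
#'   `central_slice`, `seed_row`, `seed_col`, `approx_diam_mm`,
#'   `extent_lo`, `extent_hi`.
#' @param edge_width_px,ring_mm Mask geometry; ring width in px is derived
#'   from the volume's in-plane spacing via [ring_width_px()].
#' @return A tibble with one row per (lesion, slice): ids, `slice_index`, and
#'   a `masks` list-column of `mask_triplet` objects.
#' @export
segment_cohort <- function(volumes, annotations, edge_width_px = 2L, ring_mm = 6) {
  rows <- purrr::pmap(annotations, function(patient_id, lesion_id, central_slice,
                                            seed_row, seed_col, approx_diam_mm,
                                            extent_lo, extent_hi, ...) {
    vol <- volumes[[patient_id]]
    if (is.null(vol)) rlang::abort(paste0("no volume for patient ", patient_id))
    sp <- vol$spacing_mm[3]
    slices <- select_slices(c(extent_lo, extent_hi), central_slice,
                            n_slices = dim(vol$voxels)[1])
    hw <- max(8L, as.integer(round(0.75 * approx_diam_mm / sp)))
    purrr::map(slices, function(s) {
      img <- vol$voxels[s + 1L, , ]
      core <- segment_lesion_slice(img, c(seed_row, seed_col), roi_halfwidth_px = hw)
      trip <- build_mask_triplet(core, edge_width_px = edge_width_px,
                                 ring_width_px = ring_width_px(sp, ring_mm))
      tibble::tibble(patient_id = patient_id, lesion_id = lesion_id,
                     slice_index = s, masks = list(trip))
    }) |> purrr::list_rbind()
  })
  purrr::list_rbind(rows)
}
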