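test_that("window normalization maps the window linearly onto [0, 1]", {
  w <- window_spec(40, 400)
  expect_equal(window_normalize(matrix(40), w)[1], 0.5)
  expect_equal(window_normalize(matrix(-160), w)[1], 0)
  expect_equal(window_normalize(matrix(-500), w)[1], 0)
  expect_equal(window_normalize(matrix(240), w)[1], 1)
  hu <- matrix(seq(-400, 400, by = 7), nrow = 1)
  out <- window_normalize(hu, w)
  expect_true(all(diff(as.vector(out)) >= 0))        # monotone in HU
  expect_true(all(out >= 0 & out <= 1))
  expect_error(window_spec(40, -1), "width")
})

test_that("seed-based Otsu segmentation recovers a bimodal disk exactly", {
  img <- matrix(0.2, 64, 64)
  d <- disk_mask(64, 10)
  img[d] <- 0.8
  m <- segment_lesion_slice(img, c(31, 31), roi_halfwidth_px = 20)
  expect_identical(m, d)
  # idempotent
  expect_identical(segment_lesion_slice(img, c(31, 31), roi_halfwidth_px = 20), m)
})

test_that("segmentation rejects degenerate ROIs and off-lesion seeds", {
  expect_error(segment_lesion_slice(matrix(0.5, 32, 32), c(15, 15)),
               class = "perirad_degenerate_roi")
  img <- matrix(0.2, 64, 64); img[disk_mask(64, 8)] <- 0.8
  expect_error(segment_lesion_slice(img, c(2, 2), roi_halfwidth_px = 31),
               class = "perirad_seed_outside")
})

test_that("segmentation overlaps generator ground truth (IoU >= 0.90)", {
  coh <- generate_cohort(cohort_spec(n_patients = 8, seed = 11))
  ious <- purrr::pmap_dbl(coh$annotations,
    function(patient_id, lesion_id, central_slice, seed_row, seed_col,
             approx_diam_mm, ...) {
      img <- coh$volumes[[patient_id]]$voxels[central_slice + 1, , ]
      m <- segment_lesion_slice(img, c(seed_row, seed_col),
                                roi_halfwidth_px = max(8, round(approx_diam_mm)))
      tr <- coh$ground_truth$masks[[patient_id]][[lesion_id]][[as.character(central_slice)]]
      sum(m & tr) / sum(m | tr)
    })
  expect_true(all(ious >= 0.90))
})

test_that("mask triplet satisfies containment, disjointness and the area identity", {
  core <- disk_mask(64, 10)
  trip <- build_mask_triplet(core, edge_width_px = 2, ring_width_px = 8)
  expect_true(all(trip$core_plus_edge[trip$core]))          # core within core+edge
  expect_false(any(trip$ring & trip$core_plus_edge))        # ring disjoint
  expect_identical(dim(trip$ring), dim(core))
  # area identity: |cpe| + |ring| = |dilate(core, edge + ring)|
  full <- build_mask_triplet(core, edge_width_px = 10, ring_width_px = 1)
  expect_equal(sum(trip$core_plus_edge) + sum(trip$ring), sum(full$core_plus_edge))
  # irregular core keeps the invariants
  set.seed(5)
  blob <- disk_mask(64, 7) | disk_mask(64, 5, cy = 25, cx = 40)
  tb <- build_mask_triplet(blob, 2, 8)
  expect_true(all(tb$core_plus_edge[tb$core]))
  expect_false(any(tb$ring & tb$core_plus_edge))
})

test_that("ring pixel count matches the analytic annulus within 5%", {
  trip <- build_mask_triplet(disk_mask(64, 10), edge_width_px = 2, ring_width_px = 8)
  analytic <- pi * ((10 + 2 + 8)^2 - (10 + 2)^2)
  expect_lt(abs(sum(trip$ring) / analytic - 1), 0.05)
})

test_that("ring width follows the 6 mm physical target", {
  expect_identical(ring_width_px(0.75), 8L)
  expect_identical(ring_width_px(NULL), 8L)
  expect_identical(ring_width_px(1.0), 6L)
  expect_identical(ring_width_px(0.6, 6), 10L)
})

test_that("lesions touching the border raise an informative error", {
  core <- matrix(TRUE, 20, 20)     # lesion fills the field: no room for a ring
  expect_error(build_mask_triplet(core, 2, 8), class = "perirad_border_lesion")
})

test_that("slice selection returns central +/- 2 clipped to extent and volume", {
  expect_identical(select_slices(c(10, 20), 15), 13:17)
  expect_identical(select_slices(c(15, 16), 15), 15:16)
  expect_identical(select_slices(c(0, 30), 0), 0:2)
  expect_identical(select_slices(c(0, 30), 29, n_slices = 30), 27:29)
  expect_error(select_slices(c(10, 20), 9), "central")
})
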