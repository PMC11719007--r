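# Feature bank: 2-D shape, intensity, radial, texture and spectral features
# computed per (slice, region) mask. All statistics operate on normalized
# [0,1] intensities; quantization grids are fixed over [0,1] (16 levels for
# histogram features, 32 for co-occurrence / gray-tone features) so values
# are comparable across slices, lesions and runs.

N_GRAY_BINS <- 16L   # GrayLevelK histogram
N_GLCM_LEVELS <- 32L # co-occurrence / NGTDM quantization

moments_sk <- function(x) {
  # Pearson skewness m3/m2^1.5 and kurtosis m4/m2^2 (normal = 3); 0 for
  # degenerate (constant) input so every feature stays finite.
  m <- mean(x); d <- x - m
  m2 <- mean(d^2)
  if (m2 < 1e-12) return(c(0, 0))
  c(mean(d^3) / m2^1.5, mean(d^4) / m2^2)
}

shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# crop image+mask to the mask bounding box with a fixed margin, zero-padding
# beyond the image border so results are exactly translation invariant
crop_bbox <- function(image, mask, margin = 2L) {
  rr <- range(which(rowSums(mask) > 0)); cc <- range(which(colSums(mask) > 0))
  r_idx <- (rr[1] - margin):(rr[2] + margin)
  c_idx <- (cc[1] - margin):(cc[2] + margin)
  nr <- length(r_idx); nc <- length(c_idx)
  img <- matrix(0, nr, nc); msk <- matrix(FALSE, nr, nc)
  ok_r <- r_idx >= 1 & r_idx <= nrow(image)
  ok_c <- c_idx >= 1 & c_idx <= ncol(image)
  img[ok_r, ok_c] <- image[r_idx[ok_r], c_idx[ok_c]]
  msk[ok_r, ok_c] <- mask[r_idx[ok_r], c_idx[ok_c]]
  list(image = img, mask = msk)
}

shift_mat <- function(m, dr, dc, fill = 0) {
  # value of m at (r + dr, c + dc), `fill` outside
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
  ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

glcm_stats <- function(q, msk, dr, dc) {
  a <- q; a[!msk] <- NA_integer_
  b <- shift_mat(a, dr, dc, fill = NA_integer_)
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) return(rep(0, 8))
  L <- N_GLCM_LEVELS
  cnt <- tabulate((a[keep] - 1L) * L + b[keep], nbins = L * L)
  P <- matrix(cnt, L, L, byrow = TRUE)
  P <- P + t(P)                     # symmetric GLCM
  P <- P / sum(P)
  i <- matrix(seq_len(L), L, L); j <- t(i)
  px <- rowSums(P)
  mu <- sum(seq_len(L) * px)        # symmetric: mux = muy
  sig2 <- sum((seq_len(L) - mu)^2 * px)
  contrast <- sum(P * (i - j)^2)
  dissim <- sum(P * abs(i - j))
  energy <- sum(P^2)
  homog <- sum(P / (1 + (i - j)^2))
  entr <- shannon_entropy(as.vector(P))
  correl <- if (sig2 < 1e-12) 0 else sum(P * (i - mu) * (j - mu)) / sig2
  shade <- sum(P * (i + j - 2 * mu)^3)
  promin <- sum(P * (i + j - 2 * mu)^4)
  c(contrast, dissim, energy, homog, entr, correl, shade, promin)
}

GLCM_STAT_NAMES <- c("Contrast", "Dissimilarity", "Energy", "Homogeneity",
                     "Entropy", "Correlation", "ClusterShade", "ClusterProminence")
GLCM_DIRS <- list(H = c(0L, 1L), V = c(1L, 0L), D1 = c(1L, 1L), D2 = c(1L, -1L))

ngtdm_stats <- function(q, msk) {
  # gray-tone difference over 3x3 neighbourhoods restricted to the mask
  qm <- q; qm[!msk] <- 0
  mm <- msk * 1
  sum_q <- matrix(0, nrow(q), ncol(q)); sum_m <- sum_q
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    sum_q <- sum_q + shift_mat(qm, dr, dc)
    sum_m <- sum_m + shift_mat(mm, dr, dc)
  }
  valid <- msk & sum_m > 0
  if (!any(valid)) return(rep(0, 5))
  abar <- sum_q[valid] / sum_m[valid]
  lev <- q[valid]
  N <- sum(valid); L <- N_GLCM_LEVELS
  s <- vapply(seq_len(L), function(k) sum(abs(k - abar[lev == k])), numeric(1))
  n_i <- tabulate(lev, nbins = L)
  p <- n_i / N
  nz <- which(p > 0); Ng <- length(nz)
  eps <- 1e-12
  coarse <- 1 / (sum(p * s) + eps)
  if (Ng < 2) return(c(coarse, 0, 0, 0, 0))
  pi_ <- p[nz]; si <- s[nz]; iv <- nz
  dif2 <- outer(iv, iv, function(a, b) (a - b)^2)
  pp <- outer(pi_, pi_)
  contrast <- (sum(pp * dif2) / (Ng * (Ng - 1))) * (sum(s) / N)
  busy_den <- sum(abs(outer(iv * pi_, iv * pi_, "-")))
  busy <- if (busy_den < eps) 0 else sum(pi_ * si) / busy_den
  psum <- outer(pi_, pi_, "+")
  complexity <- sum(abs(outer(iv, iv, "-")) * (outer(pi_ * si, pi_ * si, "+")) / psum) / N
  strength <- sum(psum * dif2) / (sum(s) + eps)
  c(coarse, contrast, busy, complexity, strength)
}

# outermost boundary crossing r(theta) at 360 equal angles, ray-marched from
# the geometric centroid in steps of 0.25 px
radial_signature <- function(msk, cy, cx, n_angles = 360L, step = 0.25) {
  rmax_bound <- 0
  idx <- which(msk, arr.ind = TRUE)
  rmax_bound <- sqrt(max((idx[, 1] - cy)^2 + (idx[, 2] - cx)^2)) + 1
  theta <- (seq_len(n_angles) - 1) * 2 * pi / n_angles
  t_steps <- seq(0, rmax_bound, by = step)
  ry <- outer(sin(theta), t_steps)     # angle x step
  rx <- outer(cos(theta), t_steps)
  rr <- round(cy + ry); cc <- round(cx + rx)
  nr <- nrow(msk); nc <- ncol(msk)
  inside <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
  hit <- matrix(FALSE, n_angles, length(t_steps))
  hit[inside] <- msk[cbind(rr[inside], cc[inside])]
  # outermost crossing: largest step index still inside the mask
  last <- apply(hit, 1, function(h) { w <- which(h); if (length(w)) max(w) else NA_integer_ })
  r <- t_steps[last]
  r[is.na(r)] <- 0
  r
}

perimeter_px <- function(msk) {
  # number of exposed pixel edges (mask/background adjacencies, 4-neighbour)
  m <- msk * 1
  4 * sum(m) - 2 * (sum(m[-1, ] * m[-nrow(m), ]) + sum(m[, -1] * m[, -ncol(m)]))
}

hu_moments <- function(msk) {
  idx <- which(msk, arr.ind = TRUE)
  y <- idx[, 1]; x <- idx[, 2]
  m00 <- length(x); xb <- mean(x); yb <- mean(y)
  mu <- function(p, q) sum((x - xb)^p * (y - yb)^q)
  eta <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  h1 <- n20 + n02
  h2 <- (n20 - n02)^2 + 4 * n11^2
  h3 <- (n30 - 3 * n12)^2 + (3 * n21 - n03)^2
  h4 <- (n30 + n12)^2 + (n21 + n03)^2
  h5 <- (n30 - 3 * n12) * (n30 + n12) * ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
    (3 * n21 - n03) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2)
  h6 <- (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
    4 * n11 * (n30 + n12) * (n21 + n03)
  h7 <- (3 * n21 - n03) * (n30 + n12) * ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
    (n30 - 3 * n12) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2)
  c(h1, h2, h3, h4, h5, h6, h7)
}

ellipse_axes <- function(sxx, syy, sxy) {
  # major/minor axis lengths and eccentricity of the 2nd-moment ellipse
  tr <- sxx + syy
  det_ <- sqrt(pmax((sxx - syy)^2 / 4 + sxy^2, 0))
  l1 <- tr / 2 + det_; l2 <- pmax(tr / 2 - det_, 0)
  major <- 4 * sqrt(pmax(l1, 0)); minor <- 4 * sqrt(l2)
  ecc <- if (l1 < 1e-12) 0 else sqrt(pmax(1 - l2 / l1, 0))
  c(major = major, minor = minor, ecc = ecc)
}

#' Extract the full radiomic feature bank from one masked slice
#'
#' Computes every feature in [feature_registry()] for a single region mask on
#' a normalized axial slice: first-order intensity statistics, a 16-bin gray
#' level histogram, binary shape and Hu moments, the 360-angle radial
#' boundary signature, intensity-weighted geometric density features
#' (`OD-CentroidDifference`, `RadCentre`, `ODEccentricity`, ...), gray-level
#' co-occurrence statistics at 8 offsets, gray-tone difference statistics,
#' Sobel gradient statistics, and radial/angular spectral energy fractions
#' of the mask-cropped 2-D FFT.
#'
#' All features are deterministic, finite, and exactly invariant to integer
#' translation of the image and mask.
#'
#' @param image Numeric matrix, intensities normalized to `[0, 1]`.
#' @param mask Logical (or 0/1) matrix of the same shape; at least 8 pixels.
#' @return Named numeric vector, names matching `feature_registry()$name`.
#' @export
extract_features <- function(image, mask) {
  stopifnot(is.matrix(image), all(dim(image) == dim(mask)))
  mask <- mask > 0
  n <- sum(mask)
  if (n < 8) rlang::abort("mask too small: radial statistics need >= 8 pixels",
                          class = "perirad_mask_too_small")
  cb <- crop_bbox(image, mask)
  img <- cb$image; msk <- cb$mask
  v <- img[msk]

  out <- numeric(0)

  ## -- first-order intensity ------------------------------------------------
  m <- mean(v); s <- stats::sd(v)
  sk <- moments_sk(v)
  qs <- stats::quantile(v, c(.05, .10, .20, .25, .40, .60, .75, .90, .95),
                        names = FALSE, type = 7)
  hist16 <- tabulate(pmin(pmax(floor(v * N_GRAY_BINS) + 1L, 1L), N_GRAY_BINS),
                     nbins = N_GRAY_BINS) / n
  out <- c(out,
    Mean = m, SD = s, TotalVariance = stats::var(v) * (n - 1) / n,
    Skewness = sk[1], Kurtosis = sk[2],
    Entropy = shannon_entropy(hist16), Uniformity = sum(hist16^2),
    Energy = mean(v^2), RMS = sqrt(mean(v^2)),
    Min = min(v), Max = max(v), Range = max(v) - min(v),
    Median = stats::median(v), MAD = stats::mad(v),
    IQR = qs[7] - qs[4],
    CV = if (abs(m) < 1e-12) 0 else s / m,
    P5 = qs[1], P10 = qs[2], P20 = qs[3], P25 = qs[4], P40 = qs[5],
    P60 = qs[6], P75 = qs[7], P90 = qs[8], P95 = qs[9])

  ## -- gray-level histogram fractions --------------------------------------
  out <- c(out, stats::setNames(hist16, paste0("GrayLevel", seq_len(N_GRAY_BINS))))

  ## -- binary shape ---------------------------------------------------------
  idx <- which(msk, arr.ind = TRUE)
  y <- idx[, 1]; x <- idx[, 2]
  cy <- mean(y); cx <- mean(x)
  per <- perimeter_px(msk)
  area <- n
  eqd <- 2 * sqrt(area / pi)
  sxx <- mean((x - cx)^2) + 1 / 12; syy <- mean((y - cy)^2) + 1 / 12
  sxy <- mean((x - cx) * (y - cy))
  ax <- ellipse_axes(sxx, syy, sxy)
  hull <- grDevices::chull(x, y)
  hx <- x[hull]; hy <- y[hull]
  conv_area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2 + per / 4
  bbox_area <- (diff(range(y)) + 1) * (diff(range(x)) + 1)
  out <- c(out,
    Area = area, Perimeter = per,
    Circularity = 4 * pi * area / per^2,
    Compactness = per^2 / area,
    EquivDiameter = eqd,
    Solidity = min(area / max(conv_area, 1), 1),
    Extent = area / bbox_area,
    MajorAxis = ax[["major"]], MinAxis = ax[["minor"]],
    Eccentricity = ax[["ecc"]],
    AspectRatio = if (ax[["minor"]] < 1e-9) 1 else ax[["major"]] / ax[["minor"]],
    ConvexArea = conv_area)
  out <- c(out, stats::setNames(hu_moments(msk), paste0("Hu", 1:7)))

  ## -- radial boundary signature r(theta) -----------------------------------
  r <- radial_signature(msk, cy, cx)
  rm_ <- mean(r); rs <- stats::sd(r)
  rsk <- moments_sk(r)
  rmax <- max(r, 1e-9)
  rhist <- tabulate(pmin(floor(r / rmax * 16) + 1L, 16L), nbins = 16L) / length(r)
  out <- c(out,
    MeanRadius = rm_, "RadSD-Angle" = rs,
    RadVarianceAngle = stats::var(r) * (length(r) - 1) / length(r),
    RadVarAngle = stats::var(r) * (length(r) - 1) / length(r),
    "RadSkew-Angle" = rsk[1], "RadKurtosis-Angle" = rsk[2],
    RadMin = min(r), RadMax = max(r),
    RadCV = if (rm_ < 1e-9) 0 else rs / rm_,
    RadEntropy = shannon_entropy(rhist))

  ## -- intensity-weighted geometric density (OD family) ---------------------
  w <- v; W <- sum(w)
  if (W < 1e-12) w <- rep(1, n)
  W <- sum(w)
  wcx <- sum(w * x) / W; wcy <- sum(w * y) / W
  rpix <- sqrt((x - cx)^2 + (y - cy)^2)
  rpix_max <- max(rpix, 1e-9)
  rn <- rpix / rpix_max
  rad_centre <- sum(w * rn) / W
  rc_var <- sum(w * (rn - rad_centre)^2) / W
  rc_m3 <- sum(w * (rn - rad_centre)^3) / W
  wsxx <- sum(w * (x - wcx)^2) / W + 1 / 12
  wsyy <- sum(w * (y - wcy)^2) / W + 1 / 12
  wsxy <- sum(w * (x - wcx) * (y - wcy)) / W
  wax <- ellipse_axes(wsxx, wsyy, wsxy)
  out <- c(out,
    "OD-CentroidDifference" = sqrt((wcx - cx)^2 + (wcy - cy)^2) / (eqd / 2),
    RadCentre = rad_centre,
    "RadCentre-SD" = sqrt(rc_var),
    "RadCentre-Skew" = if (rc_var < 1e-12) 0 else rc_m3 / rc_var^1.5,
    ODEccentricity = wax[["ecc"]],
    ODMajorAxis = wax[["major"]], ODMinorAxis = wax[["minor"]],
    ODAxisRatio = if (wax[["minor"]] < 1e-9) 1 else wax[["major"]] / wax[["minor"]])

  ## -- radial zone intensity profile ----------------------------------------
  zone <- pmin(floor(rn * 4) + 1L, 4L)
  zmeans <- vapply(1:4, function(k) if (any(zone == k)) mean(v[zone == k]) else m,
                   numeric(1))
  slope <- {
    dz <- rn - mean(rn)
    den <- sum(dz^2)
    if (den < 1e-12) 0 else sum(dz * (v - m)) / den
  }
  out <- c(out, stats::setNames(zmeans, paste0("RadZoneMean", 1:4)),
           RadZoneSlope = slope)

  ## -- gray-level co-occurrence ----------------------------------------------
  q <- matrix(pmin(pmax(floor(img * N_GLCM_LEVELS) + 1L, 1L), N_GLCM_LEVELS),
              nrow(img), ncol(img))
  glcm_all <- list()
  for (d in c(1L, 2L)) for (dn in names(GLCM_DIRS)) {
    off <- GLCM_DIRS[[dn]] * d
    st <- glcm_stats(q, msk, off[1], off[2])
    nm <- ifelse(GLCM_STAT_NAMES == "Correlation" & d == 1L,
                 paste0(dn, "-Correlation"),
                 paste0("GLCM-", GLCM_STAT_NAMES, "-d", d, "-", dn))
    names(st) <- nm
    glcm_all[[paste0(d, dn)]] <- st
  }
  glcm_vec <- unlist(glcm_all, use.names = TRUE)
  names(glcm_vec) <- sub("^[12](H|V|D1|D2)\\.", "", names(glcm_vec))
  out <- c(out, glcm_vec)
  # direction-averaged d=1 statistics (reuse the per-offset results)
  d1 <- vapply(names(GLCM_DIRS), function(dn) unname(glcm_all[[paste0(1L, dn)]]),
               numeric(8))
  out <- c(out, stats::setNames(rowMeans(d1), paste0("GLCM-", GLCM_STAT_NAMES, "-mean")))
  # spec alias: V-Correlation is the canonical co-occurrence correlation at
  # offset (1,0); already emitted above under that name

  ## -- gray-tone difference (NGTDM) ------------------------------------------
  ng <- ngtdm_stats(q, msk)
  out <- c(out, NGCoarseness = ng[1], NGContrast = ng[2], NGBusyness = ng[3],
           NGComplexity = ng[4], NGStrength = ng[5])

  ## -- Sobel gradient ----------------------------------------------------------
  gx <- (shift_mat(img, 0, 1) - shift_mat(img, 0, -1)) * 2 +
    shift_mat(img, 1, 1) - shift_mat(img, 1, -1) +
    shift_mat(img, -1, 1) - shift_mat(img, -1, -1)
  gy <- (shift_mat(img, 1, 0) - shift_mat(img, -1, 0)) * 2 +
    shift_mat(img, 1, 1) - shift_mat(img, -1, 1) +
    shift_mat(img, 1, -1) - shift_mat(img, -1, -1)
  gmag <- sqrt(gx^2 + gy^2)[msk]
  gsk <- moments_sk(gmag)
  ghist <- tabulate(pmin(floor(gmag / max(max(gmag), 1e-9) * 16) + 1L, 16L),
                    nbins = 16L) / n
  out <- c(out, GradMean = mean(gmag), GradSD = stats::sd(gmag),
           GradSkew = gsk[1], GradKurt = gsk[2], GradMax = max(gmag),
           GradEntropy = shannon_entropy(ghist))

  ## -- spectral (2-D FFT of the mask-cropped patch) ---------------------------
  patch <- img * msk
  P <- max(64L, 2^ceiling(log2(max(dim(patch)))))
  pad <- matrix(0, P, P)
  pad[seq_len(nrow(patch)), seq_len(ncol(patch))] <- patch
  pw <- Mod(stats::fft(pad))^2
  fr <- c(seq(0, P / 2), seq(-P / 2 + 1, -1)) / P
  FY <- matrix(fr, P, P); FX <- t(FY)
  rfreq <- sqrt(FX^2 + FY^2)
  pw[1, 1] <- 0                      # drop DC
  tot <- sum(pw)
  if (tot < 1e-12) tot <- 1
  rmax_f <- max(rfreq)
  band <- pmin(floor(rfreq / rmax_f * 4) + 1L, 4L)
  fftr <- vapply(1:4, function(k) sum(pw[band == k]) / tot, numeric(1))
  ang <- atan2(FY, FX) %% pi
  aband <- pmin(floor(ang / pi * 4) + 1L, 4L)
  ffta <- vapply(1:4, function(k) sum(pw[aband == k]) / tot, numeric(1))
  rband8 <- pmin(floor(rfreq / rmax_f * 8) + 1L, 8L)
  p8 <- vapply(1:8, function(k) sum(pw[rband8 == k]) / tot, numeric(1))
  out <- c(out, stats::setNames(fftr, paste0("FFT", 1:4)),
           stats::setNames(ffta, paste0("FFTAng", 1:4)),
           SpectralCentroid = sum(pw * rfreq) / tot / rmax_f,
           SpectralEntropy = shannon_entropy(p8 / sum(p8)))

  if (!all(is.finite(out))) {
    bad <- names(out)[!is.finite(out)]
    rlang::abort(paste0("non-finite feature(s): ", paste(bad, collapse = ", ")))
  }
  out
}

#' The radiomic feature registry
#'
#' One row per feature computed by [extract_features()], with its family and
#' a human-readable formula. The registry is the documentation of record for
#' the feature bank; extraction output names match it exactly.
#'
#' @return A tibble with columns `name`, `family`, `formula_doc`.
#' @export
feature_registry <- function() {
  reg <- registry_env$registry
  if (!is.null(reg)) return(reg)
  doc <- function(name, family, formula_doc) tibble::tibble(
    name = name, family = family, formula_doc = formula_doc)
  rows <- list(
    doc(c("Mean", "SD", "TotalVariance", "Skewness", "Kurtosis", "Entropy",
          "Uniformity", "Energy", "RMS", "Min", "Max", "Range", "Median",
          "MAD", "IQR", "CV",
          paste0("P", c(5, 10, 20, 25, 40, 60, 75, 90, 95))),
        "intensity",
        c("mean of masked intensities", "standard deviation", "population variance",
          "Pearson skewness m3/m2^1.5", "Pearson kurtosis m4/m2^2 (normal = 3)",
          "Shannon entropy (bits) of the 16-bin histogram over [0,1]",
          "sum of squared 16-bin histogram fractions", "mean squared intensity",
          "root mean square", "minimum", "maximum", "max - min", "median",
          "median absolute deviation (scaled)", "P75 - P25",
          "SD / mean (0 when mean ~ 0)",
          paste0(c(5, 10, 20, 25, 40, 60, 75, 90, 95), "th percentile"))),
    doc(paste0("GrayLevel", 1:16), "intensity",
        paste0("fraction of masked pixels in bin ", 1:16,
               " of a 16-bin equal-width histogram over [0,1]")),
    doc(c("Area", "Perimeter", "Circularity", "Compactness", "EquivDiameter",
          "Solidity", "Extent", "MajorAxis", "MinAxis", "Eccentricity",
          "AspectRatio", "ConvexArea"),
        "shape",
        c("pixel count", "exposed pixel-edge count (4-neighbour)",
          "4*pi*Area/Perimeter^2", "Perimeter^2/Area",
          "2*sqrt(Area/pi)", "Area / convex hull area", "Area / bounding-box area",
          "major axis of the 2nd-moment ellipse fit (px)",
          "minor axis of the 2nd-moment ellipse fit (px)",
          "eccentricity of the 2nd-moment ellipse",
          "MajorAxis / MinAxis", "convex hull area (px)")),
    doc(paste0("Hu", 1:7), "shape", "Hu invariant moment of the binary mask"),
    doc(c("MeanRadius", "RadSD-Angle", "RadVarianceAngle", "RadVarAngle",
          "RadSkew-Angle", "RadKurtosis-Angle", "RadMin", "RadMax", "RadCV",
          "RadEntropy"),
        "radial",
        c("mean boundary distance r(theta) from the geometric centroid, 360 equal angles, outermost crossing",
          "SD of r(theta)", "population variance of r(theta)",
          "population variance of r(theta) (alias of RadVarianceAngle)",
          "skewness of r(theta)", "Pearson kurtosis of r(theta)",
          "min of r(theta)", "max of r(theta)", "SD/mean of r(theta)",
          "entropy of the 16-bin histogram of r/rmax")),
    doc(c("OD-CentroidDifference", "RadCentre", "RadCentre-SD", "RadCentre-Skew",
          "ODEccentricity", "ODMajorAxis", "ODMinorAxis", "ODAxisRatio"),
        "radial",
        c("||intensity-weighted centroid - geometric centroid|| / equivalent radius",
          "intensity-weighted mean of normalized radial position r/rmax (0 = mass at centre, 1 = rim)",
          "intensity-weighted SD of r/rmax",
          "intensity-weighted skewness of r/rmax",
          "eccentricity of the intensity-weighted 2nd-moment ellipse",
          "major axis of the intensity-weighted ellipse (px)",
          "minor axis of the intensity-weighted ellipse (px)",
          "ODMajorAxis / ODMinorAxis")),
    doc(c(paste0("RadZoneMean", 1:4), "RadZoneSlope"), "radial",
        c(paste0("mean intensity in radial zone ", 1:4, " (r/rmax quartile bands)"),
          "least-squares slope of intensity on r/rmax")))
  glcm_names <- unlist(lapply(c(1L, 2L), function(d) lapply(names(GLCM_DIRS), function(dn)
    ifelse(GLCM_STAT_NAMES == "Correlation" & d == 1L,
           paste0(dn, "-Correlation"),
           paste0("GLCM-", GLCM_STAT_NAMES, "-d", d, "-", dn)))))
  rows <- c(rows, list(
    doc(glcm_names, "texture",
        "gray-level co-occurrence statistic, 32-level quantization over [0,1], symmetric GLCM at the named offset (H/V/D1/D2, distance d); X-Correlation names the d=1 correlation in direction X"),
    doc(paste0("GLCM-", GLCM_STAT_NAMES, "-mean"), "texture",
        "direction-averaged d=1 co-occurrence statistic"),
    doc(c("NGCoarseness", "NGContrast", "NGBusyness", "NGComplexity", "NGStrength"),
        "texture",
        "neighbourhood gray-tone difference statistic (3x3 in-mask neighbourhood, 32 levels)"),
    doc(c("GradMean", "GradSD", "GradSkew", "GradKurt", "GradMax", "GradEntropy"),
        "texture", "statistic of the Sobel gradient magnitude over the mask"),
    doc(c(paste0("FFT", 1:4), paste0("FFTAng", 1:4),
          "SpectralCentroid", "SpectralEntropy"),
        "spectral",
        c(paste0("fractional spectral energy in radial frequency band ", 1:4,
                 " of 4 (2-D FFT of the mask-cropped, zero-padded patch, DC excluded)"),
          paste0("fractional spectral energy in angular band ", 1:4, " of 4"),
          "power-weighted mean radial frequency / Nyquist radius",
          "entropy of the 8-band radial power spectrum"))))
  reg <- dplyr::bind_rows(rows)
  stopifnot(!anyDuplicated(reg$name))
  registry_env$registry <- reg
  reg
}

registry_env <- new.env(parent = emptyenv())

REGIONS <- c("CORE", "COREEDGE", "RING")

#' Extract features for every selected slice and region of a lesion stack
#'
#' @param volume A `ct_volume` with normalized voxels, or a 3-D array.
#' @param triplets Named list (or list) of `mask_triplet` objects, one per
#'   selected slice; names are 0-based slice indices.
#' @param slices Integer vector of 0-based slice indices to extract
#'   (defaults to the names of `triplets`).
#' @return Long tibble: `slice_index`, `region`, `feature`, `value`. Slices
#'   without a mask are skipped with a warning.
#' @export
extract_lesion_stack <- function(volume, triplets, slices = NULL) {
  vox <- if (inherits(volume, "ct_volume")) volume$voxels else volume
  if (is.null(slices)) slices <- as.integer(names(triplets))
  rows <- purrr::map(slices, function(s) {
    trip <- triplets[[as.character(s)]]
    if (is.null(trip)) {
      rlang::warn(paste0("no mask for slice ", s, "; skipped"))
      return(NULL)
    }
    img <- vox[s + 1L, , ]
    purrr::map(stats::setNames(REGIONS, REGIONS), function(reg) {
      msk <- switch(reg, CORE = trip$core, COREEDGE = trip$core_plus_edge,
                    RING = trip$ring)
      fv <- extract_features(img, msk)
      tibble::tibble(slice_index = s, region = reg,
                     feature = names(fv), value = unname(fv))
    }) |> purrr::list_rbind()
  })
  purrr::list_rbind(rows)
}

#' Pivot a long feature table to the wide `<feature>_<REGION>` layout
#'
#' @param long Long tibble from [extract_lesion_stack()] (any id columns are
#'   kept); must contain `region`, `feature`, `value`.
#' @return Wide tibble, one row per remaining id combination, columns
#'   `<feature>_<REGION>`.
#' @export
features_wide <- function(long) {
  long |>
    dplyr::mutate(colname = paste0(.data$feature, "_", .data$region)) |>
    dplyr::select(-"feature", -"region") |>
    tidyr::pivot_wider(names_from = "colname", values_from = "value")
}
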