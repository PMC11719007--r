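# Shared fixtures and independent brute-force oracles. Oracles are written
# as straight-line reference implementations, independent of the package
# code paths they check.

# centered binary disk / ellipse mask
disk_mask <- function(n, r, cy = (n + 1) / 2, cx = (n + 1) / 2) {
  ys <- matrix(seq_len(n), n, n); xs <- t(ys)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

square_mask <- function(n, half) {
  m <- matrix(FALSE, n, n)
  c0 <- round(n / 2)
  m[(c0 - half):(c0 + half), (c0 - half):(c0 + half)] <- TRUE
  m
}

# brute-force intensity-weighted centroid offset, double loop
oracle_centroid_offset <- function(image, mask) {
  sw <- 0; swx <- 0; swy <- 0; sx <- 0; sy <- 0; np <- 0
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (!mask[i, j]) next
    w <- image[i, j]
    sw <- sw + w; swy <- swy + w * i; swx <- swx + w * j
    sy <- sy + i; sx <- sx + j; np <- np + 1
  }
  sqrt((swx / sw - sx / np)^2 + (swy / sw - sy / np)^2) / sqrt(np / pi)
}

# fine ray-marched mean boundary radius over 360 angles (step 0.05 px)
oracle_mean_radius <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
  rmax <- sqrt(max((idx[, 1] - cy)^2 + (idx[, 2] - cx)^2)) + 1
  rs <- vapply(seq(0, 359) * pi / 180, function(th) {
    t_ <- seq(0, rmax, by = 0.05)
    rr <- round(cy + t_ * sin(th)); cc <- round(cx + t_ * cos(th))
    ok <- rr >= 1 & rr <= nrow(mask) & cc >= 1 & cc <= ncol(mask)
    inside <- rep(FALSE, length(t_))
    inside[ok] <- mask[cbind(rr[ok], cc[ok])]
    if (any(inside)) t_[max(which(inside))] else 0
  }, numeric(1))
  mean(rs)
}

# brute-force AUC by exhaustive pair counting
oracle_pair_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# independent straight-line implementation of the frequency hierarchy rules
oracle_hierarchy <- function(scores, x, y, z) {
  les <- unique(scores[c("patient_id", "lesion_id")])
  les$freq <- NA_integer_
  for (k in seq_len(nrow(les))) {
    s <- scores$score[scores$patient_id == les$patient_id[k] &
                        scores$lesion_id == les$lesion_id[k]]
    les$freq[k] <- sum(s >= x)
  }
  les$pd <- les$freq >= y
  pats <- unique(les$patient_id)
  data.frame(patient_id = pats,
             pd = vapply(pats, function(p) sum(les$pd[les$patient_id == p]) >= z,
                         logical(1)))
}

# random grouped slice-score sets for hierarchy property tests
random_score_set <- function(seed) {
  set.seed(seed)
  n_pat <- sample(3:8, 1)
  rows <- list()
  for (p in seq_len(n_pat)) {
    for (l in seq_len(sample(1:3, 1))) {
      ns <- sample(1:5, 1)
      sc <- round(runif(ns), 2)
      # plant exact-boundary scores to exercise the inclusive comparison
      if (runif(1) < 0.3) sc[1] <- 0.22
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = sprintf("P%02d", p), lesion_id = paste0("L", l), score = sc)
    }
  }
  do.call(rbind, rows)
}

# tiny labelled table with a perfectly separating feature among noise
separable_table <- function(n = 40, n_noise = 8, seed = 1) {
  set.seed(seed)
  y <- rep(c(0, 1), each = n / 2)
  d <- tibble::tibble(sep = y + rnorm(n, 0, 0.05))
  for (k in seq_len(n_noise)) d[[paste0("noise", k)]] <- rnorm(n)
  d$label <- y
  d$patient <- sprintf("P%03d", seq_len(n))
  d
}
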