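test_that("one-hot encoding produces complete indicator sets", {
  df <- tibble::tibble(sex = c("F", "M", "F"), x = 1:3)
  enc <- one_hot(df, "sex")
  expect_true(all(c("sex_F", "sex_M") %in% names(enc)))
  expect_true(all(enc$sex_F + enc$sex_M == 1))
  smoke <- tibble::tibble(smoking = c("never", "ex", "current", "unknown"))
  enc2 <- one_hot(smoke, "smoking")
  expect_equal(sum(grepl("^smoking_", names(enc2))), 4)
})

test_that("unseen levels at apply time become zero indicators with a warning", {
  lv <- attr(one_hot(tibble::tibble(sex = c("F", "M")), "sex"), "one_hot_levels")
  expect_warning(enc <- one_hot(tibble::tibble(sex = c("F", "X")), "sex", levels = lv),
                 "unseen")
  expect_equal(unlist(enc[2, c("sex_F", "sex_M")], use.names = FALSE), c(0L, 0L))
})

test_that("range scaler maps training extremes to [-1, 1] and never clamps new data", {
  train <- tibble::tibble(a = c(2, 4, 6), b = c(1, 1, 1))
  sc <- fit_scaler(train)
  scaled <- apply_scaler(train, sc)
  expect_equal(scaled$a, c(-1, 0, 1))
  expect_equal(scaled$b, c(0, 0, 0))                  # constant feature -> 0
  test <- apply_scaler(tibble::tibble(a = 8, b = 3), sc)
  expect_equal(test$a, 2)                             # outside, preserved
  set.seed(1)
  x <- tibble::tibble(v = rnorm(50))
  expect_true(all(abs(apply_scaler(x, fit_scaler(x))$v) <= 1))
})

test_that("first-pass filter removes constant, weak and redundant features in order", {
  set.seed(2)
  n <- 120
  y <- rep(c(0, 1), each = n / 2)
  strong <- y + rnorm(n, 0, 0.6)
  df <- tibble::tibble(const = rep(0.3, n),
                       strong = strong,
                       dup = strong,                  # exact duplicate
                       weak = rnorm(n),
                       clin = rnorm(n))
  rep_ <- first_pass_filter(df, y, clinical = "clin")
  expect_true("const" %in% rep_$removed$feature[rep_$removed$reason == "near-constant"])
  expect_true("weak" %in% rep_$removed$feature[rep_$removed$reason == "weak"])
  red <- rep_$removed$feature[rep_$removed$reason == "redundant"]
  expect_length(intersect(c("strong", "dup"), red), 1)   # exactly one of the pair
  expect_true("clin" %in% rep_$retained)                 # clinical exempt
  expect_setequal(c(rep_$retained, rep_$removed$feature), names(df))
})

test_that("filter agrees with an independent re-implementation of the three rules", {
  tab <- generate_feature_table(200, 60, informative = 10, delta = 1.5, seed = 1)
  y <- as.integer(tab$class == "PD")
  feats <- dplyr::select(tab, dplyr::starts_with("f"))
  rep_ <- first_pass_filter(feats, y)
  # oracle: straight-line version of the rules
  pool <- names(feats)
  pool <- pool[vapply(pool, function(f) var(feats[[f]]) >= 1e-8, logical(1))]
  fa <- vapply(pool, function(f) {
    r <- rank(feats[[f]]); n1 <- sum(y == 1); n0 <- sum(y == 0)
    a <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    max(a, 1 - a)
  }, numeric(1))
  pool <- pool[fa >= 0.55]
  rho <- cor(as.matrix(feats[pool]), method = "spearman")
  drop <- character()
  for (i in seq_along(pool)) for (j in seq_along(pool)) {
    if (j <= i || pool[i] %in% drop || pool[j] %in% drop) next
    if (abs(rho[i, j]) > 0.95) {
      a <- pool[i]; b <- pool[j]
      loser <- if (fa[a] < fa[b]) a else if (fa[b] < fa[a]) b else max(a, b)
      drop <- c(drop, loser)
    }
  }
  oracle_retained <- setdiff(pool, drop)
  expect_setequal(rep_$retained, oracle_retained)
  expect_true(all(attr(tab, "informative") %in% rep_$retained))
})

test_that("filter and scaler are deterministic and depend only on the training rows", {
  tab <- generate_feature_table(80, 20, informative = 4, delta = 1.2, seed = 3)
  y <- as.integer(tab$class == "PD")
  feats <- dplyr::select(tab, dplyr::starts_with("f"))
  r1 <- first_pass_filter(feats, y)
  r2 <- first_pass_filter(feats, y)
  expect_identical(r1$retained, r2$retained)
  expect_identical(fit_scaler(feats)$min, fit_scaler(feats)$min)
})
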