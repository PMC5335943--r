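# naive re-implementation straight from the variance definitions
hjorth_naive <- function(y) {
  pvar <- function(v) sum((v - mean(v))^2) / length(v)
  mob <- function(v) sqrt(pvar(diff(v)) / pvar(v))
  c(
    activity = pvar(y),
    mobility = mob(y),
    complexity = mob(diff(y)) / mob(y)
  )
}

test_that("Hjorth parameters match their closed forms", {
  alt <- rep(c(1, -1), 100)
  h <- hjorth_params(alt)
  expect_equal(unname(h["activity"]), 1)
  expect_equal(unname(h["mobility"]), 2, tolerance = 1e-4)
  expect_equal(unname(h["complexity"]), 1, tolerance = 1e-4)

  fs <- 128
  s <- sin(2 * pi * 10 * (0:511) / fs) # 4 s unit sine
  hs <- hjorth_params(s)
  expect_equal(unname(hs["activity"]), 0.5, tolerance = 0.01)
  expect_equal(unname(hs["mobility"]), 2 * sin(pi * 10 / fs), tolerance = 0.01)
  expect_equal(unname(hs["complexity"]), 1, tolerance = 0.01)
})

test_that("Hjorth parameters equal the brute-force definitions on random vectors", {
  set.seed(5)
  for (n in c(3, 5, 17, 50)) {
    y <- rnorm(n)
    expect_equal(hjorth_params(y), hjorth_naive(y), tolerance = 1e-12)
  }
})

test_that("Hjorth parameters obey the scale and shift laws", {
  set.seed(6)
  y <- rnorm(100)
  h <- hjorth_params(y)
  for (a in c(-3, 0.01, 7)) {
    ha <- hjorth_params(a * y)
    expect_equal(unname(ha["activity"]), unname(a^2 * h["activity"]), tolerance = 1e-9)
    expect_equal(unname(ha["mobility"]), unname(h["mobility"]), tolerance = 1e-9)
    expect_equal(unname(ha["complexity"]), unname(h["complexity"]), tolerance = 1e-9)
  }
  for (c0 in c(-100, 5)) {
    expect_equal(hjorth_params(y + c0), h, tolerance = 1e-9)
  }
})

test_that("degenerate signals error singly and warn to a sentinel in batch", {
  expect_error(hjorth_params(rep(5, 100)), "degenerate")
  expect_error(hjorth_params(c(1, 2)), "at least 3")

  flat <- make_rec(192, value = 0)
  w <- capture_warnings(hf <- hjorth_features(segment_epochs(flat)))
  expect_gte(length(w), 1)
  expect_true(all(grepl("sentinel", w)))
  expect_true(all(affectr:::feature_matrix(hf) == 0))
  expect_equal(ncol(hf) - 2, 168)
})

test_that("feature families have the documented lengths and layout", {
  rec <- simulate_recording("happy", 3, seed = 9)
  ep <- segment_epochs(rec)

  ff <- filtered_features(ep)
  expect_equal(ncol(ff) - 2, 2688) # 14 channels x 192 samples
  expect_equal(attr(ff, "family"), "filtered")
  # channel-major: first 192 columns belong to AF3
  expect_true(all(startsWith(names(ff)[3:194], "AF3_")))

  half <- segment_epochs(rec, epoch_length = 96)
  expect_equal(ncol(filtered_features(half)) - 2, 14 * 96)

  hf <- hjorth_features(ep)
  expect_equal(ncol(hf) - 2, 168) # 14 x 4 x 3
  expect_equal(attr(hf, "family"), "hjorth14")
  expect_equal(
    names(hf)[3:5],
    c("AF3_delta_activity", "AF3_delta_mobility", "AF3_delta_complexity")
  )

  h6 <- hjorth_features(ep, frontal_channels())
  expect_equal(ncol(h6) - 2, 72) # 6 x 4 x 3
  expect_equal(attr(h6, "family"), "hjorth6")

  expect_error(hjorth_features(ep, c("AF3", "Cz")), "Cz")
})

test_that("a zero epoch gives a zero filtered-feature vector", {
  rec <- make_rec(192, value = 0)
  ff <- filtered_features(segment_epochs(rec))
  expect_equal(sum(abs(affectr:::feature_matrix(ff))), 0)
  expect_equal(ncol(ff) - 2, 2688)
})

test_that("mutual information ranks a class-copy feature above pure noise", {
  set.seed(31)
  n <- 200
  labels <- rep(emotion_labels(), each = n / 4)
  x <- matrix(rnorm(n * 50), n, 50)
  colnames(x) <- sprintf("noise_%02d", 1:50)
  feats <- tibble::as_tibble(x)
  feats$class_copy <- as.numeric(factor(labels))
  r <- mi_rank(feats, labels = labels)
  expect_equal(r$feature[1], "class_copy")
  expect_gt(r$mi[1], 1.9) # two bits of label information
})

test_that("mutual-information ties break by original feature index", {
  n <- 40
  labels <- rep(c("happy", "sad"), each = n / 2)
  feats <- tibble::tibble(
    a = rep(1, n), b = rep(2, n), c = rep(3, n)
  )
  r <- mi_rank(feats, labels = labels)
  expect_equal(r$mi, c(0, 0, 0))
  expect_equal(r$feature, c("a", "b", "c")) # index order on all-zero MI

  code <- as.numeric(factor(labels))
  dup <- tibble::tibble(n1 = rnorm(n), info_a = code, n2 = rnorm(n), info_b = code)
  rd <- mi_rank(dup, labels = labels)
  expect_equal(rd$feature[1:2], c("info_a", "info_b")) # equal MI, index order
})

test_that("mi_rank is invariant to sample permutation and validates inputs", {
  set.seed(41)
  n <- 60
  labels <- rep(emotion_labels(), each = n / 4)
  feats <- tibble::as_tibble(matrix(rnorm(n * 6), n,
    dimnames = list(NULL, letters[1:6])
  ))
  feats$good <- as.numeric(factor(labels)) + rnorm(n, sd = 0.1)
  r1 <- mi_rank(feats, labels = labels)
  perm <- sample(n)
  r2 <- mi_rank(feats[perm, ], labels = labels[perm])
  expect_equal(r1, r2)

  expect_error(mi_rank(feats, labels = rep("happy", n)), "single class")
  expect_error(mi_rank(feats[1:5, ], labels = labels[1:5]), "at least 10")
})
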